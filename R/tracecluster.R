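#' Affinity score bandwidths and gates
#'
#' Tunable parameters of the three pairwise trace relations. Frequency
#' bandwidths `sigma_m`, `sigma_c` and the gate `delta_f` are in frequency
#' bins; `gamma`, `max_delay`, `max_gap` are in seconds; `sigma_h`,
#' `sigma_int` act on the dimensionless harmonic frequency ratio.
#'
#' @param sigma_h Bandwidth of the harmonic ratio variance term.
#' @param sigma_int Bandwidth of the distance-to-integer term.
#' @param sigma_m Multipath contour-difference bandwidth (bins).
#' @param sigma_c Continuation frequency-jump bandwidth (bins).
#' @param gamma Continuation gap decay constant (s).
#' @param delta_f Multipath mean-frequency gate (bins).
#' @param max_delay Maximum multipath delay (s).
#' @param max_gap Maximum continuation gap (s).
#' @param min_overlap Minimum temporal overlap fraction (of the shorter
#'   trace) for the harmonic relation.
#' @return An `affinity_params` list.
#' @export
affinity_params <- function(sigma_h = 0.05, sigma_int = 0.1, sigma_m = 2,
                            sigma_c = 3, gamma = 0.05, delta_f = 4,
                            max_delay = 0.2, max_gap = 0.15,
                            min_overlap = 0.7) {
  structure(as.list(environment()), class = "affinity_params")
}

trace_times <- function(tr, axes) {
  list(start = axes$time_axis[min(tr$columns) + 1L],
       end = axes$time_axis[max(tr$columns) + 1L])
}

#' Harmonic affinity between two traces
#'
#' Zero unless the traces overlap in time for at least `min_overlap` of the
#' shorter one. Over the overlap, with `r_j` the per-column ratio of the
#' higher to the lower contour frequency and `m = round(mean(r))` the
#' candidate harmonic number (`m >= 2` required), the score is
#' `exp(-var(r) / sigma_h^2) * exp(-(mean(r) - m)^2 / sigma_int^2)`.
#'
#' @param a,b `whistle_trace` objects from the same spectrogram.
#' @param axes The `spectrogram` (or list with `freq_axis`, `time_axis`).
#' @param params An [affinity_params()].
#' @return Score in `[0, 1]`.
#' @export
harmonic_affinity <- function(a, b, axes, params = affinity_params()) {
  cols <- intersect(a$columns, b$columns)
  if (length(cols) == 0L) return(0)
  if (length(cols) < params$min_overlap * min(length(a$columns), length(b$columns)))
    return(0)
  fa <- axes$freq_axis[a$bins[match(cols, a$columns)] + 1L]
  fb <- axes$freq_axis[b$bins[match(cols, b$columns)] + 1L]
  if (mean(fa) >= mean(fb)) { hi <- fa; lo <- fb } else { hi <- fb; lo <- fa }
  r <- hi / lo
  m <- round(mean(r))
  if (m < 2) return(0)
  v <- if (length(r) > 1L) stats::var(r) else 0
  exp(-v / params$sigma_h^2) * exp(-(mean(r) - m)^2 / params$sigma_int^2)
}

#' Multipath affinity between two traces
#'
#' Zero unless the later trace starts within `(0, max_delay]` seconds of the
#' earlier one and their mean frequencies differ by less than `delta_f` bins.
#' Otherwise the contours are aligned at the start-time lag and the score is
#' `exp(-mean squared bin difference / sigma_m^2)`.
#'
#' @inheritParams harmonic_affinity
#' @return Score in `[0, 1]`.
#' @export
multipath_affinity <- function(a, b, axes, params = affinity_params()) {
  if (min(a$columns) <= min(b$columns)) { e <- a; l <- b } else { e <- b; l <- a }
  hop_s <- axes$time_axis[2] - axes$time_axis[1]
  dt <- (min(l$columns) - min(e$columns)) * hop_s
  if (dt <= 0 || dt > params$max_delay) return(0)
  binw <- axes$freq_axis[2] - axes$freq_axis[1]
  fmean_e <- mean(axes$freq_axis[e$bins + 1L])
  fmean_l <- mean(axes$freq_axis[l$bins + 1L])
  if (abs(fmean_e - fmean_l) >= params$delta_f * binw) return(0)
  lag <- min(l$columns) - min(e$columns)
  shifted <- l$columns - lag
  cols <- intersect(e$columns, shifted)
  if (length(cols) == 0L) return(0)
  be <- e$bins[match(cols, e$columns)]
  bl <- l$bins[match(cols, shifted)]
  exp(-mean((bl - be)^2) / params$sigma_m^2)
}

#' Continuation affinity between two traces
#'
#' Zero unless the time supports are disjoint with a gap of at most
#' `max_gap` seconds. Otherwise, with `df` the bin jump between the earlier
#' trace's end and the later trace's start, the score is
#' `exp(-df^2 / sigma_c^2) * exp(-gap / gamma)`.
#'
#' @inheritParams harmonic_affinity
#' @return Score in `[0, 1]`.
#' @export
continuum_affinity <- function(a, b, axes, params = affinity_params()) {
  if (min(a$columns) <= min(b$columns)) { e <- a; l <- b } else { e <- b; l <- a }
  if (max(e$columns) >= min(l$columns)) return(0) # supports overlap
  hop_s <- axes$time_axis[2] - axes$time_axis[1]
  gap <- (min(l$columns) - max(e$columns) - 1L) * hop_s
  if (gap > params$max_gap) return(0)
  df <- l$bins[1] - e$bins[length(e$bins)]
  exp(-df^2 / params$sigma_c^2) * exp(-gap / params$gamma)
}

#' Build the trace affinity matrix
#'
#' For every trace pair, evaluates the harmonic, multipath and continuation
#' affinities and keeps the largest (two traces cannot simultaneously stand
#' in two of the three relations); the winning relation type is stored. The
#' result is symmetric with a zero diagonal and entries in `[0, 1]`.
#'
#' @param traces List of `whistle_trace` objects.
#' @param axes The source `spectrogram` (or axes list).
#' @param params An [affinity_params()].
#' @return An `affinity_matrix`: `W` (numeric), `relation` (character matrix
#'   in `{harmonic, multipath, continuum, none}`), and `params`.
#' @export
build_affinity <- function(traces, axes, params = affinity_params()) {
  N <- length(traces)
  if (N < 1L) stop("build_affinity: need at least one trace")
  W <- matrix(0, N, N)
  rel <- matrix("none", N, N)
  if (N > 1L) {
    for (i in 1:(N - 1L)) {
      for (j in (i + 1L):N) {
        s <- c(
          harmonic = harmonic_affinity(traces[[i]], traces[[j]], axes, params),
          multipath = multipath_affinity(traces[[i]], traces[[j]], axes, params),
          continuum = continuum_affinity(traces[[i]], traces[[j]], axes, params)
        )
        k <- which.max(s)
        if (s[k] > 0) {
          W[i, j] <- W[j, i] <- s[k]
          rel[i, j] <- rel[j, i] <- names(s)[k]
        }
      }
    }
  }
  structure(list(W = W, relation = rel, params = params, n = N),
            class = "affinity_matrix")
}

#' @export
print.affinity_matrix <- function(x, ...) {
  cat(sprintf("<affinity_matrix> %d traces, %d nonzero pairs\n",
              x$n, sum(x$W > 0) / 2))
  invisible(x)
}

#' Tidy an affinity matrix into a pair table
#' @param x An `affinity_matrix`.
#' @param ... Unused.
#' @return Tibble with `i`, `j`, `w`, `relation` for the upper triangle.
#' @export
tidy.affinity_matrix <- function(x, ...) {
  ut <- which(upper.tri(x$W), arr.ind = TRUE)
  tibble::tibble(i = ut[, 1], j = ut[, 2], w = x$W[ut],
                 relation = x$relation[ut])
}

as_W <- function(W) {
  if (inherits(W, "affinity_matrix")) W$W else W
}

#' Degree matrix of an affinity matrix
#'
#' Diagonal matrix with `d_ii = sum_j w_ij` (exact row sums).
#'
#' @param W An `affinity_matrix` or symmetric numeric matrix.
#' @return Diagonal numeric matrix.
#' @export
degree_matrix <- function(W) {
  W <- as_W(W)
  if (!isSymmetric(unname(W), tol = 0)) stop("degree_matrix: W must be symmetric")
  diag(rowSums(W), nrow = nrow(W))
}

#' Cluster-stability objective
#'
#' Evaluates `sum_k c_k' (W - D) c_k` for a hard assignment of traces to
#' clusters: within-cluster affinity rewarded, total degree penalizing large
#' clusters. Clusters must be disjoint (orthogonal indicator vectors).
#'
#' @param W An `affinity_matrix` or symmetric matrix.
#' @param D Degree matrix (defaults to `degree_matrix(W)`).
#' @param assignment Integer membership vector (one entry per trace) or a
#'   `cluster_assignment`.
#' @return Scalar objective value.
#' @export
cluster_objective <- function(W, assignment, D = NULL) {
  W <- as_W(W)
  if (is.null(D)) D <- degree_matrix(W)
  if (inherits(assignment, "cluster_assignment")) {
    member <- assignment$membership
  } else if (is.list(assignment)) {
    # list of per-cluster index vectors
    ids <- unlist(assignment)
    if (anyDuplicated(ids))
      stop("cluster_objective: overlapping clusters (orthogonality violated)")
    member <- rep(NA_integer_, nrow(W))
    for (k in seq_along(assignment)) member[assignment[[k]]] <- k
  } else {
    member <- as.integer(assignment)
  }
  if (length(member) != nrow(W))
    stop("cluster_objective: assignment length must match W")
  if (anyNA(member)) stop("cluster_objective: every trace must be assigned")
  M <- W - D
  total <- 0
  for (k in unique(member)) {
    c_k <- as.numeric(member == k)
    total <- total + drop(t(c_k) %*% M %*% c_k)
  }
  total
}

#' Cluster assignment of traces into whistles
#'
#' @param membership Integer vector: cluster id per trace.
#' @param roles Character vector per trace in
#'   `{basic, harmonic, multipath, continuation}`.
#' @param objective Objective value attained.
#' @param K Number of clusters.
#' @return A `cluster_assignment` object.
#' @export
cluster_assignment <- function(membership, roles = NULL, objective = NA_real_,
                               K = length(unique(membership))) {
  membership <- as.integer(membership)
  if (is.null(roles)) roles <- rep(NA_character_, length(membership))
  structure(list(membership = membership, roles = roles,
                 objective = objective, K = K),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d traces in %d clusters (objective %.4f)\n",
              length(x$membership), x$K, x$objective))
  invisible(x)
}

#' Tidy a cluster assignment
#' @param x A `cluster_assignment`.
#' @param ... Unused.
#' @return Tibble with `trace`, `cluster`, `role`.
#' @export
tidy.cluster_assignment <- function(x, ...) {
  tibble::tibble(trace = seq_along(x$membership), cluster = x$membership,
                 role = x$roles)
}

#' Solve the trace-association clustering
#'
#' Implements the association objective with the degeneracy-breaking design:
#' (1) entries below `theta_w` are pruned to zero; (2) the cluster count `K`
#' is fixed to the number of connected components of the pruned affinity
#' graph; (3) starting from the components, single-trace moves between
#' clusters are accepted while they strictly improve the objective (on the
#' pruned affinity) at fixed `K`; (4) each cluster's basic trace is its
#' earliest-starting, lowest-band member and the others are labelled by
#' their strongest relation to it.
#'
#' @param W An `affinity_matrix` (roles need its relation labels) or plain
#'   symmetric matrix (roles then default to `continuation`).
#' @param traces Optional list of `whistle_trace`s used to pick each
#'   cluster's basic trace by start time; defaults to trace order.
#' @param theta_w Pruning threshold (default 0.2).
#' @param max_iter Local-search sweep cap.
#' @return A [cluster_assignment()].
#' @export
solve_clustering <- function(W, traces = NULL, theta_w = 0.2, max_iter = 100L) {
  rel <- if (inherits(W, "affinity_matrix")) W$relation else NULL
  Wm <- as_W(W)
  N <- nrow(Wm)
  if (N < 1L) stop("solve_clustering: N must be >= 1")
  Wp <- Wm
  Wp[Wp < theta_w] <- 0
  g <- igraph::graph_from_adjacency_matrix(Wp > 0, mode = "undirected",
                                           diag = FALSE)
  member <- as.integer(igraph::components(g)$membership)
  K <- length(unique(member))
  D <- degree_matrix(Wp)
  obj <- cluster_objective(Wp, member, D)
  if (K > 1L && N > 1L) {
    for (it in seq_len(max_iter)) {
      improved <- FALSE
      for (i in seq_len(N)) {
        cur <- member[i]
        if (sum(member == cur) == 1L) next # moving would drop K
        for (k in setdiff(unique(member), cur)) {
          cand <- member
          cand[i] <- k
          val <- cluster_objective(Wp, cand, D)
          if (val > obj + 1e-12) {
            member <- cand
            obj <- val
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
  }
  roles <- assign_roles(member, Wm, rel, traces)
  cluster_assignment(member, roles, objective = obj, K = K)
}

assign_roles <- function(member, Wm, rel, traces) {
  N <- length(member)
  roles <- rep(NA_character_, N)
  starts <- if (!is.null(traces))
    vapply(traces, function(t) min(t$columns), numeric(1)) else seq_len(N)
  bands <- if (!is.null(traces))
    vapply(traces, function(t) mean(t$bins), numeric(1)) else seq_len(N)
  for (k in unique(member)) {
    idx <- which(member == k)
    basic <- idx[order(starts[idx], bands[idx])][1]
    roles[basic] <- "basic"
    for (i in setdiff(idx, basic)) {
      r <- if (!is.null(rel)) rel[i, basic] else "none"
      roles[i] <- switch(r,
        harmonic = "harmonic",
        multipath = "multipath",
        continuum = "continuation",
        none = {
          # no direct relation to the basic: inherit the strongest in-cluster link
          others <- setdiff(idx, i)
          j <- others[which.max(Wm[i, others])]
          if (!is.null(rel) && rel[i, j] == "harmonic") "harmonic"
          else if (!is.null(rel) && rel[i, j] == "multipath") "multipath"
          else "continuation"
        }
      )
    }
  }
  roles
}
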