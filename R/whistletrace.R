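#' Whistle trace container
#'
#' A trace is one tonal ridge through a spectrogram: consecutive 0-based
#' column indices, one 0-based frequency bin per column, and an accumulated
#' log-likelihood score. The package-wide coordinate convention is 0-based
#' bin/column indices and half-open column ranges.
#'
#' @param columns Integer vector of consecutive 0-based column indices.
#' @param bins Integer vector of 0-based frequency bins, one per column.
#' @param score Accumulated log-likelihood of the path.
#' @param id Optional trace id.
#' @param rho Steepness bound used (per-step `|delta bin| < rho`).
#' @param mean_lik Mean per-column likelihood along the path.
#' @return A `whistle_trace` object.
#' @export
whistle_trace <- function(columns, bins, score = NA_real_, id = NA_integer_,
                          rho = 3L, mean_lik = NA_real_) {
  columns <- as.integer(columns)
  bins <- as.integer(bins)
  if (length(columns) != length(bins)) stop("whistle_trace: length mismatch")
  if (length(columns) > 1L && any(diff(columns) != 1L))
    stop("whistle_trace: columns must be consecutive")
  if (length(bins) > 1L && any(abs(diff(bins)) >= rho))
    stop("whistle_trace: per-step bin jump must be < rho")
  structure(
    list(columns = columns, bins = bins, score = score, id = id,
         rho = as.integer(rho), mean_lik = mean_lik),
    class = "whistle_trace"
  )
}

#' @export
print.whistle_trace <- function(x, ...) {
  cat(sprintf("<whistle_trace #%s> cols [%d, %d), bins %d-%d, score %.3f\n",
              x$id, min(x$columns), max(x$columns) + 1L,
              min(x$bins), max(x$bins), x$score))
  invisible(x)
}

#' @export
length.whistle_trace <- function(x) length(x$columns)

#' Convert a trace to a time-frequency contour table
#'
#' @param trace A `whistle_trace`.
#' @param spec The `spectrogram` (or an axes list with `time_axis` and
#'   `freq_axis`) the trace indexes into.
#' @return A tibble with `time_s` and `freq_hz`.
#' @export
trace_contour <- function(trace, spec) {
  tibble::tibble(
    time_s = spec$time_axis[trace$columns + 1L],
    freq_hz = spec$freq_axis[trace$bins + 1L]
  )
}

#' Per-pixel whistle-likelihood map
#'
#' Scores every spectrogram pixel in `[0, 1]` by its likelihood of lying on a
#' whistle ridge. The default `energy` backend first whitens each frequency
#' row by its own background level (the 25% quantile over time, robust to a
#' whistle occupying part of the row and to stationary vessel tonals), then
#' normalizes each column by its robust contrast range, so a column with no
#' evidence maps near 0.5 and a bright ridge approaches 1. The `learned`
#' backend applies a logistic patch scorer trained on synthetic ground truth
#' (see [train_likelihood_backend()]); it obeys the same output contract.
#'
#' @param spec A `spectrogram`.
#' @param backend `"energy"` or `"learned"`.
#' @param model Fitted model object (required for `"learned"`).
#' @return A `likelihood_map`: `values` in `[0, 1]` with the source axes.
#' @export
likelihood_map <- function(spec, backend = c("energy", "learned"),
                           model = NULL) {
  stopifnot(inherits(spec, "spectrogram"))
  backend <- match.arg(backend)
  v <- spec$values
  if (backend == "energy") {
    p <- energy_likelihood(v)
  } else {
    if (is.null(model)) stop("likelihood_map: learned backend needs a model")
    p <- predict_likelihood_backend(model, v)
  }
  structure(
    list(values = p, backend_id = backend,
         freq_axis = spec$freq_axis, time_axis = spec$time_axis,
         stft_params = spec$stft_params, sample_rate = spec$sample_rate),
    class = "likelihood_map"
  )
}

energy_likelihood <- function(v, scale = 5) {
  # whiten each row by its own background level; background pixels sit near 1
  bg <- apply(v, 1, stats::quantile, probs = 0.25, names = FALSE)
  floor_bg <- stats::quantile(bg[bg > 0], probs = 0.5, names = FALSE)
  if (!is.finite(floor_bg) || length(floor_bg) == 0L || floor_bg <= 0)
    floor_bg <- 1e-12
  w <- v / pmax(bg, 0.05 * floor_bg, 1e-300)
  # fixed-scale contrast map: p = 1 - exp(-1.3 x) of the whitened contrast
  # x = (w - column baseline) / scale -- strictly increasing (no plateau
  # ties), ~0.9 at a 20 dB pixel power contrast, ~0.65 at 15 dB; columns
  # with no dynamic range carry no evidence and map to 0.5
  p <- matrix(0.5, nrow(v), ncol(v))
  lo <- apply(w, 2, stats::quantile, probs = 0.05, names = FALSE)
  rng <- apply(w, 2, max) - apply(w, 2, min)
  ok <- which(rng > 1e-9)
  for (j in ok) {
    x <- pmax(0, (w[, j] - lo[j]) / scale)
    # the second term keeps the map strictly increasing in double precision
    # even where the exponential has saturated (very bright ridges), so the
    # tracker still lands on the true peak rather than a plateau edge
    p[, j] <- (1 - exp(-1.3 * x)) * (1 - 1e-3) + 1e-3 * x / (x + 50)
  }
  p
}

#' @export
print.likelihood_map <- function(x, ...) {
  cat(sprintf("<likelihood_map> %d x %d (%s backend)\n",
              nrow(x$values), ncol(x$values), x$backend_id))
  invisible(x)
}

#' Train the learned likelihood backend
#'
#' Fits a regularized logistic scorer on local spectrogram patch features
#' (whitened magnitude, local ridge contrast) against synthetic ground-truth
#' pixel labels. A lightweight stand-in for a convolutional detector that
#' keeps the same output contract as the energy backend.
#'
#' @param specs List of `spectrogram`s.
#' @param masks List of logical matrices marking true ridge pixels (same
#'   dimensions as the corresponding spectrogram).
#' @param n_sample Pixels sampled per class for the fit.
#' @return A model usable via `likelihood_map(backend = "learned")`.
#' @export
train_likelihood_backend <- function(specs, masks, n_sample = 4000) {
  if (!requireNamespace("glmnet", quietly = TRUE))
    stop("train_likelihood_backend requires glmnet")
  feats <- list(); labs <- list()
  for (k in seq_along(specs)) {
    f <- patch_features(specs[[k]]$values)
    m <- as.vector(masks[[k]])
    pos <- which(m); neg <- which(!m)
    pos <- pos[sample.int(length(pos), min(length(pos), n_sample))]
    neg <- neg[sample.int(length(neg), min(length(neg), n_sample))]
    feats[[k]] <- f[c(pos, neg), , drop = FALSE]
    labs[[k]] <- c(rep(1L, length(pos)), rep(0L, length(neg)))
  }
  X <- do.call(rbind, feats)
  y <- unlist(labs)
  fit <- glmnet::glmnet(X, y, family = "binomial", lambda = 1e-4)
  structure(list(fit = fit), class = "wv_likelihood_model")
}

predict_likelihood_backend <- function(model, v) {
  f <- patch_features(v)
  p <- stats::predict(model$fit, newx = f, type = "response")[, 1]
  matrix(pmin(1, pmax(0, p)), nrow(v), ncol(v))
}

patch_features <- function(v) {
  p <- energy_likelihood(v)
  I <- nrow(v); J <- ncol(v)
  up <- rbind(p[1, , drop = FALSE], p[-I, , drop = FALSE])
  dn <- rbind(p[-1, , drop = FALSE], p[I, , drop = FALSE])
  lf <- cbind(p[, 1, drop = FALSE], p[, -J, drop = FALSE])
  rt <- cbind(p[, -1, drop = FALSE], p[, J, drop = FALSE])
  cbind(as.vector(p), as.vector((up + dn) / 2), as.vector((lf + rt) / 2),
        as.vector(p - (up + dn) / 2))
}

#' Region-of-interest rectangle
#'
#' Half-open 0-based row range `[i0, i1)` and column range `[j0, j1)` into a
#' likelihood map, with a detection score.
#'
#' @param i0,i1,j0,j1 Half-open 0-based bounds.
#' @param score Detection score (mean supra-threshold likelihood).
#' @return An `roi` object.
#' @export
roi <- function(i0, i1, j0, j1, score = NA_real_) {
  stopifnot(i1 > i0, j1 > j0, i0 >= 0, j0 >= 0)
  structure(list(i0 = as.integer(i0), i1 = as.integer(i1),
                 j0 = as.integer(j0), j1 = as.integer(j1), score = score),
            class = "roi")
}

#' Extract regions of interest from a likelihood map
#'
#' Finds 8-connected supra-threshold pixel regions, dilates each bounding
#' rectangle by a margin, merges overlapping rectangles to a fixpoint, and
#' returns the rectangles sorted by start column.
#'
#' @param map A `likelihood_map`.
#' @param threshold Likelihood threshold in (0, 1).
#' @param min_area Minimum number of supra-threshold pixels per region.
#' @param margin Dilation margin in bins/columns.
#' @return A list of [roi()] objects.
#' @export
extract_rois <- function(map, threshold = 0.8, min_area = 20, margin = 2L) {
  stopifnot(inherits(map, "likelihood_map"))
  if (!(threshold > 0 && threshold < 1))
    stop("extract_rois: threshold must be in (0,1)")
  v <- map$values
  I <- nrow(v); J <- ncol(v)
  idx <- which(v >= threshold)
  if (length(idx) == 0L) return(list())
  ri <- (idx - 1L) %% I
  rj <- (idx - 1L) %/% I
  comp <- label_components(ri, rj, I)
  out <- list()
  for (cid in unique(comp)) {
    sel <- comp == cid
    if (sum(sel) < min_area) next
    i0 <- max(0L, min(ri[sel]) - margin)
    i1 <- min(I, max(ri[sel]) + 1L + margin)
    j0 <- max(0L, min(rj[sel]) - margin)
    j1 <- min(J, max(rj[sel]) + 1L + margin)
    out[[length(out) + 1L]] <- roi(i0, i1, j0, j1,
                                   score = mean(v[idx[sel]]))
  }
  out <- merge_rois(out)
  out[order(vapply(out, function(r) r$j0, integer(1)))]
}

# 8-connected component labels for a sparse pixel set
label_components <- function(ri, rj, I) {
  key <- ri + rj * I
  edges <- integer(0)
  offs <- list(c(1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L))
  for (o in offs) {
    ni <- ri + o[1]
    nk <- ni + (rj + o[2]) * I
    valid <- ni >= 0L & ni < I
    hit <- match(nk, key)
    ok <- valid & !is.na(hit)
    if (any(ok)) edges <- c(edges, rbind(which(ok), hit[ok]))
  }
  g <- igraph::make_graph(edges = edges, n = length(key), directed = FALSE)
  igraph::components(g)$membership
}

merge_rois <- function(rois) {
  if (length(rois) <= 1L) return(rois)
  repeat {
    merged <- FALSE
    out <- list()
    used <- rep(FALSE, length(rois))
    for (a in seq_along(rois)) {
      if (used[a]) next
      ra <- rois[[a]]
      for (b in seq_along(rois)) {
        if (b <= a || used[b]) next
        rb <- rois[[b]]
        if (ra$i0 < rb$i1 && rb$i0 < ra$i1 && ra$j0 < rb$j1 && rb$j0 < ra$j1) {
          ra <- roi(min(ra$i0, rb$i0), max(ra$i1, rb$i1),
                    min(ra$j0, rb$j0), max(ra$j1, rb$j1),
                    score = max(ra$score, rb$score, na.rm = TRUE))
          used[b] <- TRUE
          merged <- TRUE
        }
      }
      used[a] <- TRUE
      out[[length(out) + 1L]] <- ra
    }
    rois <- out
    if (!merged) return(rois)
  }
}

#' Constrained Viterbi ridge extraction
#'
#' Finds the frequency-bin path through a likelihood submatrix maximizing the
#' summed log emissions under the steepness constraint `|bin[j+1] - bin[j]| <
#' rho`. Transitions are uniform inside the allowed neighbourhood and zero
#' outside; zero emissions are floored at `eps` rather than erroring. Ties
#' are broken toward the lowest frequency bin, then the earliest divergence
#' (the lexicographically smallest bin sequence).
#'
#' @param lik Numeric matrix of likelihood values in `[0, 1]` (bins x
#'   columns), e.g. an ROI submatrix of a [likelihood_map()].
#' @param rho Steepness bound in bins (default 3, i.e. jumps of at most 2).
#' @param transition_penalty Per-step log-transition term added to the score;
#'   defaults to `-log(2 * rho - 1)` (uniform neighbourhood).
#' @param eps Emission floor.
#' @param offset Optional c(i0, j0) 0-based offset of `lik` inside its parent
#'   map, applied to the returned coordinates.
#' @return A [whistle_trace()].
#' @export
viterbi_trace <- function(lik, rho = 3L, transition_penalty = NULL,
                          eps = 1e-12, offset = c(0L, 0L)) {
  if (!is.matrix(lik) || nrow(lik) == 0L || ncol(lik) == 0L)
    stop("viterbi_trace: non-empty matrix required")
  if (rho < 1L) stop("viterbi_trace: rho must be >= 1")
  if (is.null(transition_penalty)) transition_penalty <- -log(2 * rho - 1)
  logE <- log(pmax(lik, eps))
  res <- .viterbi_path(logE, as.integer(rho))
  bins <- res$bins
  J <- ncol(lik)
  lik_path <- lik[cbind(bins + 1L, seq_len(J))]
  whistle_trace(
    columns = (0:(J - 1L)) + offset[2],
    bins = bins + offset[1],
    score = res$score + (J - 1L) * transition_penalty,
    rho = rho,
    mean_lik = mean(lik_path)
  )
}

#' Iteratively extract ranked whistle traces from an ROI
#'
#' Repeats: run [viterbi_trace()], trim suppressed/blank path ends, accept
#' the path if its mean per-column likelihood reaches `accept_threshold` and
#' it spans at least `min_length` columns, then suppress the accepted path
#' and one bin either side (emission floored) and search again. Accepted
#' traces are pairwise pixel-disjoint and returned sorted by score.
#'
#' @param map A `likelihood_map` or plain likelihood matrix.
#' @param roi Optional [roi()] restricting the search; default whole map.
#' @param rho Steepness bound in bins.
#' @param accept_threshold Minimum mean path likelihood (default 0.6).
#' @param max_traces Maximum number of traces extracted.
#' @param min_length Minimum trace length in columns (default 10).
#' @param eps Suppression/emission floor.
#' @return List of [whistle_trace()] objects.
#' @export
extract_traces <- function(map, roi = NULL, rho = 3L, accept_threshold = 0.6,
                           max_traces = 50L, min_length = 10L, eps = 1e-12) {
  if (max_traces < 1L) stop("extract_traces: max_traces must be >= 1")
  v <- if (inherits(map, "likelihood_map")) map$values else map
  if (!is.null(roi)) {
    sub <- v[(roi$i0 + 1L):roi$i1, (roi$j0 + 1L):roi$j1, drop = FALSE]
    off <- c(roi$i0, roi$j0)
  } else {
    sub <- v
    off <- c(0L, 0L)
  }
  if (length(sub) == 0L || ncol(sub) < min_length) return(list())
  claimed <- matrix(FALSE, nrow(sub), ncol(sub))
  traces <- list()
  for (iter in seq_len(max_traces)) {
    tr <- viterbi_trace(sub, rho = rho, eps = eps)
    cols <- tr$columns + 1L
    bins <- tr$bins + 1L
    lik_path <- sub[cbind(bins, cols)]
    # trim ends sitting on suppressed/blank pixels
    good <- lik_path > 10 * eps & lik_path > 0.05
    if (!any(good)) break
    a <- which(good)[1]; b <- tail(which(good), 1)
    keep <- a:b
    if (length(keep) < min_length) break
    if (mean(lik_path[keep]) < accept_threshold) break
    shared <- any(claimed[cbind(bins[keep], cols[keep])])
    if (!shared) {
      traces[[length(traces) + 1L]] <- whistle_trace(
        columns = tr$columns[keep] + off[2],
        bins = tr$bins[keep] + off[1],
        score = sum(log(pmax(lik_path[keep], eps))) +
          (length(keep) - 1L) * -log(2 * rho - 1),
        id = length(traces) + 1L,
        rho = rho,
        mean_lik = mean(lik_path[keep])
      )
      claimed[cbind(bins[keep], cols[keep])] <- TRUE
    }
    # suppress the path, one bin either side, and the contiguous bright
    # cross-section around it (window mainlobe leakage of the same ridge)
    supp_floor <- 0.5 * accept_threshold
    I_sub <- nrow(sub)
    for (k in keep) {
      up <- bins[k] + 1L
      while (up < I_sub && sub[up + 1L, cols[k]] >= supp_floor) up <- up + 1L
      dn <- bins[k] - 1L
      while (dn > 1L && sub[dn - 1L, cols[k]] >= supp_floor) dn <- dn - 1L
      sub[max(1L, dn):min(I_sub, up), cols[k]] <- eps
    }
    if (shared) next
  }
  ord <- order(vapply(traces, function(t) t$score, numeric(1)),
               decreasing = TRUE)
  traces <- traces[ord]
  for (k in seq_along(traces)) traces[[k]]$id <- k
  traces
}

#' Detect whistle traces across a whole spectrogram
#'
#' Convenience wrapper: likelihood map -> ROI extraction -> per-ROI trace
#' extraction, returning all accepted traces with unique ids.
#'
#' @param spec A `spectrogram`.
#' @param backend Likelihood backend passed to [likelihood_map()].
#' @param model Optional learned-backend model.
#' @param threshold,min_area ROI parameters, see [extract_rois()].
#' @param rho,accept_threshold,max_traces,min_length Trace parameters, see
#'   [extract_traces()].
#' @return List with `traces`, `rois`, and the `map`.
#' @export
detect_traces <- function(spec, backend = "energy", model = NULL,
                          threshold = 0.8, min_area = 20, rho = 3L,
                          accept_threshold = 0.6, max_traces = 50L,
                          min_length = 10L) {
  map <- likelihood_map(spec, backend = backend, model = model)
  rois <- extract_rois(map, threshold = threshold, min_area = min_area)
  traces <- list()
  for (r in rois) {
    tt <- extract_traces(map, roi = r, rho = rho,
                         accept_threshold = accept_threshold,
                         max_traces = max_traces, min_length = min_length)
    traces <- c(traces, tt)
  }
  for (k in seq_along(traces)) traces[[k]]$id <- k
  list(traces = traces, rois = rois, map = map)
}

#' Tidy a list of traces into a long contour table
#'
#' @param traces List of `whistle_trace` objects.
#' @param spec Spectrogram (for axes); optional.
#' @return A tibble with trace id, column, bin and (if axes given) time/freq.
#' @export
traces_tbl <- function(traces, spec = NULL) {
  if (length(traces) == 0L)
    return(tibble::tibble(id = integer(), column = integer(), bin = integer()))
  out <- purrr::map_dfr(traces, function(t) {
    tibble::tibble(id = t$id, column = t$columns, bin = t$bins)
  })
  if (!is.null(spec)) {
    out$time_s <- spec$time_axis[out$column + 1L]
    out$freq_hz <- spec$freq_axis[out$bin + 1L]
  }
  out
}
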