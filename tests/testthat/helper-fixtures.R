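# Shared fixture builders. Everything is generated in code at test time.

fs_test <- 48000

tone_segment <- function(freq, dur = 1, fs = fs_test, amp = 1, ramp = TRUE) {
  t <- (0:(round(dur * fs) - 1)) / fs
  x <- amp * sin(2 * pi * freq * t)
  if (ramp) {
    nr <- round(0.01 * fs)
    env <- c(seq(0, 1, length.out = nr), rep(1, length(x) - 2 * nr),
             seq(1, 0, length.out = nr))
    x <- x * env
  }
  audio_segment(x, fs)
}

# steady-state power, excluding filter edge transients
core_power <- function(seg, trim = 0.1) {
  n <- length(seg$samples)
  i <- max(1, round(trim * n)):round((1 - trim) * n)
  mean(seg$samples[i]^2)
}

# a likelihood-map-like matrix holding one ridge (row path) at `level`
# against a flat `background`
ridge_matrix <- function(I, J, path, level = 0.95, background = 0.01) {
  m <- matrix(background, I, J)
  m[cbind(path, seq_len(J))] <- level
  m
}

# wrap a plain matrix as a likelihood_map for ROI tests
as_likelihood_map <- function(m, hop_s = 1 / 187.5, binw = 46.875) {
  structure(
    list(values = m, backend_id = "energy",
         freq_axis = 5000 + (seq_len(nrow(m)) - 1) * binw,
         time_axis = (seq_len(ncol(m)) - 1) * hop_s,
         stft_params = NULL, sample_rate = 48000),
    class = "likelihood_map"
  )
}

# build a whistle_trace quickly (0-based columns/bins)
mk_trace <- function(cols, bins, rho = 3L) {
  whistle_trace(cols, bins, rho = rho)
}

# axes stand-in for affinity tests: uniform grids
mk_axes <- function(binw = 46.875, hop_s = 1 / 187.5, f0 = 5000,
                    I = 400, J = 4000) {
  list(freq_axis = f0 + (0:(I - 1)) * binw, time_axis = (0:(J - 1)) * hop_s)
}

# brute-force Viterbi oracle: enumerate all admissible paths
brute_viterbi <- function(lik, rho, eps = 1e-12) {
  I <- nrow(lik); J <- ncol(lik)
  logE <- log(pmax(lik, eps))
  best <- -Inf; bestp <- NULL
  rec <- function(path) {
    j <- length(path)
    if (j == J) {
      sc <- sum(logE[cbind(path, seq_len(J))])
      if (sc > best + 1e-12) { best <<- sc; bestp <<- path }
      return()
    }
    lo <- max(1, path[j] - rho + 1); hi <- min(I, path[j] + rho - 1)
    for (n in lo:hi) rec(c(path, n))
  }
  for (i in seq_len(I)) rec(i)
  list(bins = bestp - 1L, score = best)
}

# enumerate all partitions of 1..n into exactly K non-empty blocks
partitions_k <- function(n, K) {
  out <- list()
  rec <- function(i, member, used) {
    if (i > n) {
      if (used == K) out[[length(out) + 1L]] <<- member
      return()
    }
    for (k in seq_len(min(used + 1L, K))) {
      member[i] <- k
      rec(i + 1L, member, max(used, k))
    }
  }
  rec(1L, integer(n), 0L)
  out
}

# random symmetric affinity with zero diagonal
random_affinity <- function(n, density = 0.5) {
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  vals <- ifelse(stats::runif(sum(ut)) < density, stats::runif(sum(ut)), 0)
  W[ut] <- vals
  W + t(W)
}

# adjusted Rand index between two labelings
adj_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  ex <- sa * sb / choose(n, 2)
  (sij - ex) / ((sa + sb) / 2 - ex)
}

# match ground-truth pixel paths against extracted traces:
# fraction of the gt path covered within +-1 bin by one trace
gt_coverage <- function(gt, traces) {
  vapply(seq_len(nrow(gt)), function(i) {
    g_cols <- gt$columns[[i]]; g_bins <- gt$bins[[i]]
    best <- 0
    for (tr in traces) {
      common <- intersect(g_cols, tr$columns)
      if (length(common) == 0L) next
      gb <- g_bins[match(common, g_cols)]
      tb <- tr$bins[match(common, tr$columns)]
      best <- max(best, sum(abs(gb - tb) <= 1) / length(g_cols))
    }
    best
  }, numeric(1))
}

# match each trace to the gt path it covers best (NA if < 50%)
trace_gt_match <- function(gt, traces) {
  vapply(traces, function(tr) {
    best <- NA_integer_; bestf <- 0
    for (i in seq_len(nrow(gt))) {
      common <- intersect(gt$columns[[i]], tr$columns)
      if (length(common) == 0L) next
      gb <- gt$bins[[i]][match(common, gt$columns[[i]])]
      tb <- tr$bins[match(common, tr$columns)]
      f <- sum(abs(gb - tb) <= 1) /
        max(length(gt$columns[[i]]), length(tr$columns))
      if (f > bestf) { bestf <- f; best <- i }
    }
    if (bestf >= 0.5) best else NA_integer_
  }, integer(1))
}

# labelled records with planted class difference on one feature
toy_records <- function(n_per_class_day, days, delta = 2, seed = 1) {
  whistlevessel:::with_local_seed(seed, {
    recs <- list()
    for (d in seq_len(days)) {
      for (cls in c("with_vessel", "no_vessel")) {
        n <- n_per_class_day
        mu <- if (cls == "with_vessel") delta else 0
        recs[[length(recs) + 1L]] <- tibble::tibble(
          timestamp = (d - 1) * 86400 + seq_len(n) * 10,
          day_index = d,
          is_daytime = seq_len(n) %% 3 != 0,
          duration = stats::rlnorm(n, log(0.4), 0.5),
          whistle_number = 1 + stats::rpois(n, 2.5 + mu),
          number_of_overlaps = stats::rpois(n, 0.5),
          number_of_clusters = 1 + stats::rpois(n, 0.45),
          harmonic_rate = stats::rnorm(n, 1, 0.02),
          snr = stats::runif(n, 16, 30),
          label = factor(cls, levels = c("with_vessel", "no_vessel", "excluded"))
        )
      }
    }
    dplyr::bind_rows(recs)
  })
}
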