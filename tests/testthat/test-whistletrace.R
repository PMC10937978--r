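test_that("likelihood map honors its output contract", {
  # constant spectrogram: no evidence anywhere -> 0.5
  sp <- structure(
    list(values = matrix(3, 40, 50), freq_axis = 5000 + (0:39) * 46.875,
         time_axis = (0:49) / 187.5, stft_params = NULL, sample_rate = 96000),
    class = "spectrogram"
  )
  m <- likelihood_map(sp)
  expect_true(all(abs(m$values - 0.5) < 0.01))

  # single bright ridge at 20 dB pixel contrast over a flat background
  v <- matrix(1, 40, 50)
  path <- 10 + ((seq_len(50) - 1) %/% 10)
  v[cbind(path + 1L, 1:50)] <- 10 # 20 dB in power
  sp$values <- v
  m2 <- likelihood_map(sp)
  on_ridge <- m2$values[cbind(path + 1L, 1:50)]
  off <- m2$values
  off[cbind(path + 1L, 1:50)] <- NA
  expect_true(all(on_ridge >= 0.9))
  expect_true(all(off[!is.na(off)] <= 0.2))

  # bounded in [0, 1] for random input
  set.seed(8)
  sp$values <- matrix(stats::rexp(40 * 50), 40, 50)
  m3 <- likelihood_map(sp)
  expect_true(all(m3$values >= 0 & m3$values <= 1))

  expect_error(likelihood_map(sp, backend = "learned"), "model")
})

test_that("ROI extraction finds, separates and covers ridges", {
  # all-zero map -> no ROIs
  empty <- as_likelihood_map(matrix(0, 30, 60))
  expect_length(extract_rois(empty, threshold = 0.8, min_area = 5), 0)

  # two ridges separated by a wide gap -> exactly 2 ROIs
  m <- matrix(0, 30, 100)
  m[10, 5:30] <- 0.95
  m[20, 60:90] <- 0.95
  rois <- extract_rois(as_likelihood_map(m), threshold = 0.8, min_area = 5)
  expect_length(rois, 2)
  expect_lt(rois[[1]]$j0, rois[[2]]$j0)

  # one sloped ridge: ROI covers >= 95% of its pixels
  m2 <- matrix(0, 40, 60)
  path <- round(seq(5, 35, length.out = 50))
  m2[cbind(path, 6:55)] <- 0.9
  rois2 <- extract_rois(as_likelihood_map(m2), threshold = 0.8, min_area = 5)
  expect_length(rois2, 1)
  r <- rois2[[1]]
  inside <- sum(path - 1 >= r$i0 & path - 1 < r$i1 &
                (6:55) - 1 >= r$j0 & (6:55) - 1 < r$j1)
  expect_gte(inside / length(path), 0.95)

  expect_error(extract_rois(empty, threshold = 1.5), "threshold")
})

test_that("Viterbi tracker matches its contracts on degenerate inputs", {
  # single column: argmax bin
  lik <- matrix(c(0.1, 0.7, 0.3), ncol = 1)
  tr <- viterbi_trace(lik)
  expect_equal(tr$bins, 1L)
  expect_equal(tr$columns, 0L)

  # uniform map: constant path at the lowest bin (tie-break contract)
  u <- matrix(0.4, 6, 8)
  tru <- viterbi_trace(u)
  expect_equal(tru$bins, rep(0L, 8))

  # all-zero column is floored, not an error
  z <- matrix(c(0.9, 0.9, 0, 0, 0.9, 0.9), nrow = 2)
  expect_no_error(viterbi_trace(z))

  expect_error(viterbi_trace(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(viterbi_trace(matrix(1, 2, 2), rho = 0), "rho")
})

test_that("Viterbi equals brute-force enumeration on random instances", {
  set.seed(2024)
  for (rep in 1:200) {
    I <- sample(2:8, 1)
    J <- sample(2:6, 1)
    lik <- matrix(stats::runif(I * J), I, J)
    got <- viterbi_trace(lik, rho = 3L)
    want <- brute_viterbi(lik, 3L)
    expect_identical(got$bins, want$bins)
    expect_equal(got$score - (J - 1) * -log(5), want$score, tolerance = 1e-9)
  }
})

test_that("raising an on-path emission never lowers the optimal score", {
  set.seed(77)
  for (rep in 1:40) {
    lik <- matrix(stats::runif(30), 5, 6)
    tr <- viterbi_trace(lik)
    j <- sample(6, 1)
    lik2 <- lik
    lik2[tr$bins[j] + 1L, j] <- min(1, lik2[tr$bins[j] + 1L, j] * 1.5)
    tr2 <- viterbi_trace(lik2)
    expect_gte(tr2$score, tr$score - 1e-12)
  }
})

test_that("iterative extraction separates ridges and stays pixel-disjoint", {
  # empty map -> no traces
  expect_length(extract_traces(matrix(0, 20, 30)), 0)

  # one ridge -> exactly one accepted trace
  m <- matrix(0.01, 30, 40)
  path <- round(seq(5, 25, length.out = 40))
  m[cbind(path, 1:40)] <- 0.95
  tr <- extract_traces(m, min_length = 10)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$bins, path - 1L)

  # ridge + its 2x-harmonic ridge -> 2 pixel-disjoint traces
  m2 <- matrix(0.01, 60, 40)
  base <- round(seq(8, 14, length.out = 40))
  harm <- 2 * base
  m2[cbind(base, 1:40)] <- 0.95
  m2[cbind(harm, 1:40)] <- 0.85
  tr2 <- extract_traces(m2, min_length = 10)
  expect_length(tr2, 2)
  px <- lapply(tr2, function(t) paste(t$columns, t$bins))
  expect_length(intersect(px[[1]], px[[2]]), 0)

  # short ridge below min_length is rejected
  m3 <- matrix(0.01, 20, 8)
  m3[10, 1:8] <- 0.95
  expect_length(extract_traces(m3, min_length = 10), 0)
})

test_that("pairwise pixel-disjointness holds across random maps", {
  set.seed(55)
  for (rep in 1:20) {
    m <- matrix(stats::runif(40 * 60), 40, 60)
    trs <- extract_traces(m, accept_threshold = 0.5, min_length = 5,
                          max_traces = 10)
    if (length(trs) < 2) next
    px <- unlist(lapply(trs, function(t) paste(t$columns, t$bins)))
    expect_false(anyDuplicated(px) > 0)
  }
})

test_that("detector recalls ground-truth paths on a clean synthetic scene", {
  cfg <- scene_config(day_length = 12, sample_rate = 48000, whistle_rate = 15,
                      overlap_prob = 0.2, transient_rate = 10,
                      ambient_level = -40, harmonic_prob = 0.5,
                      multipath_prob = 0.4, seed = 7)
  sc <- synth_scene(cfg)
  seg <- wavelet_denoise(bandpass(sc$waveform, 5000, 20000))
  sp <- make_spectrogram(seg)
  det <- detect_traces(sp)
  gt <- gt_pixel_paths(sc$ground_truth, sp)
  snrs <- vapply(seq_len(nrow(gt)), function(i) {
    tr <- whistle_trace(gt$columns[[i]], gt$bins[[i]], rho = 99L)
    trace_snr(sp, tr)
  }, numeric(1))
  cov <- gt_coverage(gt, det$traces)
  strong <- snrs >= 15
  expect_gte(mean(cov[strong] >= 0.8), 0.9)
})

test_that("learned likelihood backend meets the same output contract", {
  skip_if_not_installed("glmnet")
  cfg <- scene_config(day_length = 6, sample_rate = 48000, whistle_rate = 20,
                      transient_rate = 0, ambient_level = -40, seed = 3,
                      harmonic_prob = 0, multipath_prob = 0)
  sc <- synth_scene(cfg)
  sp <- make_spectrogram(bandpass(sc$waveform, 5000, 20000))
  gt <- gt_pixel_paths(sc$ground_truth, sp)
  mask <- matrix(FALSE, nrow(sp$values), ncol(sp$values))
  for (i in seq_len(nrow(gt)))
    mask[cbind(gt$bins[[i]] + 1L, gt$columns[[i]] + 1L)] <- TRUE
  set.seed(1)
  model <- train_likelihood_backend(list(sp), list(mask), n_sample = 1500)
  m <- likelihood_map(sp, backend = "learned", model = model)
  expect_true(all(m$values >= 0 & m$values <= 1))
  # ridge pixels score clearly above background on average
  expect_gt(mean(m$values[mask]), mean(m$values[!mask]) + 0.3)
})
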