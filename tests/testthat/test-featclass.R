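to_spec <- function(I = 400, J = 4000, hop_s = 1 / 187.5, binw = 46.875) {
  structure(
    list(values = matrix(1, I, J), freq_axis = 5000 + (0:(I - 1)) * binw,
         time_axis = (0:(J - 1)) * hop_s, stft_params = NULL,
         sample_rate = 96000),
    class = "spectrogram"
  )
}

test_that("harmonic rate follows its normalization", {
  axes <- to_spec()
  basic <- mk_trace(0:49, rep(100L, 50)) # ~9.7 kHz
  f0 <- axes$freq_axis[101]

  # perfect 2x harmonic -> 1
  h2 <- mk_trace(0:49, rep(round((2 * f0 - 5000) / 46.875), 50))
  expect_equal(harmonic_rate(list(basic, h2), c("basic", "harmonic"), axes), 1,
               tolerance = 1e-3)

  # no harmonics -> 1 by convention
  expect_equal(harmonic_rate(list(basic), "basic", axes), 1)

  # harmonic at 2.1x with m = 2 -> 1.05
  h21 <- mk_trace(0:49, rep(round((2.1 * f0 - 5000) / 46.875), 50))
  expect_equal(harmonic_rate(list(basic, h21), c("basic", "harmonic"), axes),
               1.05, tolerance = 1e-2)

  # non-overlapping harmonic skipped with a warning
  h_far <- mk_trace(100:149, rep(200L, 50))
  expect_warning(
    out <- harmonic_rate(list(basic, h_far), c("basic", "harmonic"), axes),
    "no temporal overlap"
  )
  expect_equal(out, 1)
})

test_that("per-cluster features follow their definitions", {
  sp <- to_spec()
  hop_s <- sp$time_axis[2] - sp$time_axis[1]

  # lone whistle: 20 columns -> duration 20 * hop; all counts minimal
  tr <- mk_trace(0:19, rep(50L, 20))
  asg <- cluster_assignment(1L, "basic")
  rec <- compute_features(asg, list(tr), sp)
  expect_equal(rec$duration, 20 * hop_s)
  expect_equal(rec$whistle_number, 1L)
  expect_equal(rec$number_of_overlaps, 0L)
  expect_equal(rec$number_of_clusters, 1L)
  expect_equal(rec$harmonic_rate, 1)

  # 3 basic whistles within 60 s, harmonic on the middle one, overlap pair
  t1 <- mk_trace(0:49, rep(40L, 50))
  t2 <- mk_trace(1000:1049, rep(60L, 50))
  t2h <- mk_trace(1000:1049, rep(124L, 50))
  t3 <- mk_trace(1030:1079, rep(90L, 50)) # overlaps t2 in time
  asg2 <- cluster_assignment(c(1L, 2L, 2L, 3L),
                             c("basic", "basic", "harmonic", "basic"))
  recs <- compute_features(asg2, list(t1, t2, t2h, t3), sp)
  mid <- recs[recs$cluster == 2L, ]
  expect_equal(mid$whistle_number, 3L)
  expect_equal(mid$number_of_clusters, 2L)
  expect_equal(mid$number_of_overlaps, 1L)
  expect_equal(recs$number_of_overlaps[recs$cluster == 3L], 2L)

  expect_error(
    compute_features(cluster_assignment(c(1L, 1L), c("harmonic", "harmonic")),
                     list(t1, t2), sp),
    "unique basic"
  )
})

test_that("vessel labeling implements the 1 min / 5 min buffer rule", {
  vl <- vessel_log(start = c(130, 1000), end = c(200, 1200))
  recs <- tibble::tibble(timestamp = c(100, 150, 270, 420, 600, 1500, 1800),
                         id = 1:7)
  out <- label_whistles(recs, vl)
  expect_equal(
    as.character(out$label),
    c("with_vessel",  # 30 s before the first interval
      "with_vessel",  # inside
      "excluded",     # 70 s after
      "excluded",     # 220 s after
      "no_vessel",    # 400 s from both intervals
      "no_vessel",    # exactly 300 s after the second interval
      "no_vessel")    # 600 s after
  )
})

test_that("labeling boundary distances follow the rule exactly", {
  vl <- vessel_log(start = 1000, end = 1100)
  t <- c(940, 939.9, 800, 799.9, 700, 1160, 1400.1)
  out <- label_whistles(tibble::tibble(timestamp = t), vl)
  expect_equal(as.character(out$label),
               c("with_vessel",  # dist 60 (boundary -> with)
                 "excluded",     # dist 60.1
                 "excluded",     # dist 200
                 "excluded",     # dist 200.1
                 "no_vessel",    # dist 300
                 "with_vessel",  # dist 60
                 "no_vessel"))   # dist 300.1
  # the three labels partition the records
  expect_equal(sum(table(out$label)), nrow(out))
  expect_error(label_whistles(tibble::tibble(timestamp = 1), vl,
                              with_buffer = 400, no_buffer = 300),
               "with_buffer")
})

test_that("SNR filter keeps strictly above threshold", {
  recs <- tibble::tibble(snr = c(10, 15, 16, 30), id = 1:4)
  kept <- snr_filter(recs)
  expect_equal(kept$id, c(3L, 4L))
  expect_equal(nrow(snr_filter(recs, threshold = 9)), 4L)
})

test_that("rho statistic is a ratio of class means with equivariance", {
  recs <- tibble::tibble(
    x = c(2, 4, 1, 3),
    label = factor(c("with_vessel", "with_vessel", "no_vessel", "no_vessel"),
                   levels = c("with_vessel", "no_vessel", "excluded"))
  )
  expect_equal(as.numeric(rho_statistic(recs, "x")), 3 / 2)

  # doubling the with-class doubles rho; scaling the no-class divides it
  r2 <- recs; r2$x[r2$label == "with_vessel"] <- 2 * r2$x[r2$label == "with_vessel"]
  expect_equal(as.numeric(rho_statistic(r2, "x")), 3)
  r3 <- recs; r3$x[r3$label == "no_vessel"] <- 2 * r3$x[r3$label == "no_vessel"]
  expect_equal(as.numeric(rho_statistic(r3, "x")), 3 / 4)

  zero <- recs; zero$x[zero$label == "no_vessel"] <- 0
  expect_error(rho_statistic(zero, "x"), "zero")
  expect_error(rho_statistic(recs[recs$label == "no_vessel", ], "x"),
               "non-empty")
})

test_that("LODO separates a separable problem and stays at chance under permutation", {
  recs <- toy_records(60, days = 3, delta = 30, seed = 2)
  rep <- evaluate_lodo(recs, svm_grid(C = 10, gamma_mult = 1, cv_cap = 200,
                                      refit_cap = 400), seed = 1)
  expect_true(all(rep$by_day$tp_rate == 1))
  expect_true(all(rep$by_day$tn_rate == 1))

  # permuted labels: chance level over 20 seeds
  base <- toy_records(40, days = 3, delta = 2, seed = 3)
  rates <- vapply(1:20, function(s) {
    prm <- base
    set.seed(100 + s)
    prm$label <- sample(prm$label)
    rp <- evaluate_lodo(prm, svm_grid(C = 1, gamma_mult = 1, cv_cap = 150,
                                      refit_cap = 200, folds = 2),
                        seed = s)
    g <- glance(rp)
    (g$mean_tp + g$mean_tn) / 2
  }, numeric(1))
  expect_gt(mean(rates), 0.45)
  expect_lt(mean(rates), 0.55)
})

test_that("no test-day record leaks into training (hash check)", {
  recs <- toy_records(40, days = 3, delta = 2, seed = 7)
  rep1 <- evaluate_lodo(recs, svm_grid(C = 1, gamma_mult = 1, cv_cap = 100,
                                       refit_cap = 200, folds = 2), seed = 1)
  # perturb only day 3's records: training hashes for day 3 must not change
  recs2 <- recs
  d3 <- recs2$day_index == 3
  recs2$whistle_number[d3] <- recs2$whistle_number[d3] + 50
  rep2 <- evaluate_lodo(recs2, svm_grid(C = 1, gamma_mult = 1, cv_cap = 100,
                                        refit_cap = 200, folds = 2), seed = 1)
  h1 <- rep1$by_day$train_hash[rep1$by_day$day_index == 3]
  h2 <- rep2$by_day$train_hash[rep2$by_day$day_index == 3]
  expect_identical(h1, h2)
  # but other days' training sets do change
  expect_false(identical(rep1$by_day$train_hash[1], rep2$by_day$train_hash[1]))

  expect_error(evaluate_lodo(recs[recs$day_index == 1, ]), "2 days")
})

test_that("ablation isolates the informative feature", {
  # single informative feature: whistle_number
  recs <- toy_records(80, days = 3, delta = 8, seed = 5)
  tab <- ablation(recs, svm_grid(refit_cap = 400), seed = 1)
  all_acc <- (tab$tp_rate[tab$variant == "all"] +
              tab$tn_rate[tab$variant == "all"]) / 2
  drop_wn <- tab[tab$variant == "all_except" & tab$feature == "whistle_number", ]
  only_wn <- tab[tab$variant == "only" & tab$feature == "whistle_number", ]
  expect_lt((drop_wn$tp_rate + drop_wn$tn_rate) / 2, 0.6) # chance-ish
  expect_gt((only_wn$tp_rate + only_wn$tn_rate) / 2, all_acc - 0.05)
  # uninformative feature alone is chance-level
  only_hr <- tab[tab$variant == "only" & tab$feature == "harmonic_rate", ]
  expect_lt((only_hr$tp_rate + only_hr$tn_rate) / 2, 0.6)
  expect_true(all(is.finite(tab$f_measure[tab$variant == "all"])))
})

test_that("day/night report flags degenerate strata and balances identical ones", {
  pred <- tibble::tibble(
    day_index = rep(1:2, each = 40),
    timestamp = seq_len(80),
    is_daytime = rep(c(TRUE, FALSE), 40),
    truth = rep(c("with_vessel", "no_vessel"), each = 2, times = 20),
    pred = rep(c("with_vessel", "no_vessel"), each = 2, times = 20)
  )
  rep <- structure(list(predictions = pred,
                        by_day = tibble::tibble(day_index = 1:2)),
                   class = "eval_report")
  dn <- day_night_report(rep)
  expect_equal(dn$by_day$tp_ratio, c(1, 1))
  expect_equal(dn$by_day$tn_ratio, c(1, 1))
  expect_equal(unname(dn$averages["tp_ratio"]), 1)

  # night stratum lacking one class -> NA and degenerate flag
  pred2 <- pred
  pred2$truth[!pred2$is_daytime] <- "with_vessel"
  rep2 <- structure(list(predictions = pred2,
                         by_day = tibble::tibble(day_index = 1:2)),
                    class = "eval_report")
  dn2 <- day_night_report(rep2)
  expect_true(all(is.na(dn2$by_day$tn_ratio)))
  expect_true(all(dn2$by_day$degenerate))
})
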