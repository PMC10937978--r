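test_that("pairwise affinities follow their closed forms", {
  axes <- mk_axes()
  p <- affinity_params()
  base <- mk_trace(0:49, round(seq(20, 40, length.out = 50)))

  # exact 2x harmonic -> ~1
  f0 <- axes$freq_axis[base$bins + 1L]
  harm_bins <- round((2 * f0 - axes$freq_axis[1]) / 46.875)
  harm <- mk_trace(0:49, harm_bins, rho = 5L)
  expect_gte(harmonic_affinity(base, harm, axes, p), 0.99)

  # disjoint time supports -> 0
  far <- mk_trace(200:249, base$bins)
  expect_equal(harmonic_affinity(base, far, axes, p), 0)

  # constant ratio 1.4 rounds to 1 < 2 -> 0
  r14_bins <- round((1.4 * f0 - axes$freq_axis[1]) / 46.875)
  r14 <- mk_trace(0:49, r14_bins, rho = 5L)
  expect_equal(harmonic_affinity(base, r14, axes, p), 0)

  # multipath: identical contour shifted by 50 ms (within max_delay)
  lag_cols <- round(0.05 / (axes$time_axis[2] - axes$time_axis[1]))
  mp <- mk_trace(0:49 + lag_cols, base$bins)
  expect_gte(multipath_affinity(base, mp, axes, p), 0.99)

  # frequency-offset copy beyond the delta_f gate -> 0
  expect_equal(multipath_affinity(base, mk_trace(0:49 + lag_cols, base$bins + 40L),
                                  axes, p), 0)

  # jittered multipath matches direct formula re-evaluation
  set.seed(5)
  jit <- base$bins + sample(c(-1L, 0L, 1L), 50, replace = TRUE)
  mpj <- whistle_trace(0:49 + lag_cols, jit, rho = 5L)
  got <- multipath_affinity(base, mpj, axes, p)
  expect_equal(got, exp(-mean((jit - base$bins)^2) / p$sigma_m^2))

  # continuation: zero gap (adjacent columns), zero jump -> 1
  cont <- mk_trace(50:79, rep(base$bins[50], 30))
  expect_equal(continuum_affinity(base, cont, axes, p), 1.0)

  # gap beyond max_gap -> 0
  cont_far <- mk_trace(120:149, rep(base$bins[50], 30))
  expect_equal(continuum_affinity(base, cont_far, axes, p), 0)

  # gap = gamma with zero jump -> exp(-1) (hop chosen so gamma is integral)
  axes5 <- mk_axes(hop_s = 0.005)
  gap_cols <- p$gamma / 0.005
  cont_g <- mk_trace((50 + gap_cols):(79 + gap_cols), rep(base$bins[50], 30))
  expect_equal(continuum_affinity(base, cont_g, axes5, p), exp(-1))
})

test_that("affinity matrix takes the max relation and labels it", {
  axes <- mk_axes()
  base <- mk_trace(0:49, round(seq(20, 40, length.out = 50)))
  f0 <- axes$freq_axis[base$bins + 1L]
  harm <- mk_trace(0:49, round((2 * f0 - axes$freq_axis[1]) / 46.875), rho = 5L)
  lag_cols <- round(0.05 * 187.5)
  mp <- mk_trace(0:49 + lag_cols, base$bins)

  # single trace -> 1x1 zero matrix
  a1 <- build_affinity(list(base), axes)
  expect_equal(a1$W, matrix(0, 1, 1))

  A <- build_affinity(list(base, harm, mp), axes)
  expect_true(isSymmetric(A$W))
  expect_equal(diag(A$W), rep(0, 3))
  expect_gt(A$W[1, 2], 0.9)
  expect_equal(A$relation[1, 2], "harmonic")
  expect_gt(A$W[1, 3], 0.9)
  expect_equal(A$relation[1, 3], "multipath")

  # mutually unrelated traces -> zero matrix
  t1 <- mk_trace(0:29, rep(10L, 30))
  t2 <- mk_trace(300:329, rep(100L, 30))
  t3 <- mk_trace(700:729, rep(200L, 30))
  A0 <- build_affinity(list(t1, t2, t3), axes)
  expect_equal(A0$W, matrix(0, 3, 3))
})

test_that("degree matrix is the exact row sums and rejects asymmetry", {
  W <- matrix(c(0, .5, .5, 0), 2, 2)
  expect_equal(degree_matrix(W), diag(c(.5, .5)))
  expect_equal(degree_matrix(matrix(0, 3, 3)), diag(0, 3))
  set.seed(3)
  for (rep in 1:20) {
    W <- random_affinity(4)
    D <- degree_matrix(W)
    for (i in 1:4) expect_identical(D[i, i], sum(W[i, ]))
  }
  asym <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_error(degree_matrix(asym), "symmetric")
})

test_that("clustering objective equals its quadratic form exactly", {
  # two traces fully tied, one cluster: c'Wc - c'Dc = 2 - 2 = 0
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(cluster_objective(W, c(1L, 1L)), 0)
  # as singletons: -1 + -1
  expect_equal(cluster_objective(W, c(1L, 2L)), -2)

  # random W, random partition vs direct quadratic-form evaluation
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(3:7, 1)
    W <- random_affinity(n)
    D <- degree_matrix(W)
    member <- sample.int(3, n, replace = TRUE)
    direct <- 0
    for (k in unique(member)) {
      ck <- as.numeric(member == k)
      direct <- direct + drop(t(ck) %*% (W - D) %*% ck)
    }
    expect_equal(cluster_objective(W, member), direct, tolerance = 1e-12)
  }

  # objective invariant under cluster relabelling
  W <- random_affinity(6)
  m <- c(1L, 1L, 2L, 2L, 3L, 3L)
  perm <- c(3L, 1L, 2L)
  expect_equal(cluster_objective(W, m), cluster_objective(W, perm[m]))

  expect_error(cluster_objective(W, list(c(1, 2), c(2, 3))), "overlapping")
})

test_that("solver recovers planted structure and respects bounds", {
  # zero affinity -> all singletons
  asg0 <- solve_clustering(matrix(0, 4, 4))
  expect_equal(asg0$K, 4L)
  expect_equal(length(unique(asg0$membership)), 4L)

  # two well-separated groups recovered exactly
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 0.9; W[4:6, 4:6] <- 0.9
  diag(W) <- 0
  asg <- solve_clustering(W)
  expect_equal(asg$K, 2L)
  expect_equal(length(unique(asg$membership[1:3])), 1L)
  expect_equal(length(unique(asg$membership[4:6])), 1L)
  expect_false(asg$membership[1] == asg$membership[4])

  # never below the singleton or single-cluster partitions
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    W <- random_affinity(n)
    Wp <- W; Wp[Wp < 0.2] <- 0
    asg <- solve_clustering(W, theta_w = 0.2)
    singletons <- cluster_objective(Wp, seq_len(n))
    one <- cluster_objective(Wp, rep(1L, n))
    expect_gte(asg$objective, singletons - 1e-9)
    expect_gte(asg$objective, one - 1e-9)
  }
})

test_that("solver attains the exhaustive partition maximum at fixed K", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(3:7, 1)
    W <- random_affinity(n, density = 0.45)
    asg <- solve_clustering(W, theta_w = 0.2)
    Wp <- W; Wp[Wp < 0.2] <- 0
    best <- max(vapply(partitions_k(n, asg$K), function(m)
      cluster_objective(Wp, m), numeric(1)))
    expect_equal(asg$objective, best, tolerance = 1e-9)
  }
})

test_that("roles mark one basic per cluster and relation labels carry over", {
  axes <- mk_axes()
  base <- mk_trace(0:49, round(seq(20, 40, length.out = 50)))
  f0 <- axes$freq_axis[base$bins + 1L]
  harm <- mk_trace(0:49, round((2 * f0 - axes$freq_axis[1]) / 46.875), rho = 5L)
  lag_cols <- round(0.05 * 187.5)
  mp <- mk_trace(0:49 + lag_cols, base$bins)
  lone <- mk_trace(500:540, rep(60L, 41))
  A <- build_affinity(list(base, harm, mp, lone), axes)
  asg <- solve_clustering(A, traces = list(base, harm, mp, lone))
  td <- tidy(asg)
  expect_equal(sum(td$role == "basic"),
               length(unique(td$cluster)))
  expect_equal(td$role[2], "harmonic")
  expect_equal(td$role[3], "multipath")
  expect_equal(td$role[4], "basic")
})
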