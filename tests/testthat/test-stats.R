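# stats module: responder detection, masking, partition bootstrap,
# linear-prediction pseudo-trials, supra-linearity shuffle bootstrap.

test_that("responder detection handles ties, nulls and large effects", {
  x <- rep(1, 10)
  call <- detect_responders(x, x)
  expect_equal(call$p_value, 1)
  expect_equal(call$direction, "ns")
  # strong positive shift: flagged excited
  set.seed(1)
  for (s in 1:5) {
    stim <- rnorm(20, mean = 3)
    blank <- rnorm(20)
    expect_equal(detect_responders(stim, blank)$direction, "excited")
    expect_equal(detect_responders(-stim, blank)$direction, "inhibited")
  }
  expect_error(detect_responders(1:2, 1:5), class = "xmv1_bad_argument")
})

test_that("fast exact Mann-Whitney path agrees with stats::wilcox.test", {
  set.seed(2)
  for (i in 1:20) {
    n1 <- sample(5:25, 1); n2 <- sample(5:25, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = runif(1, -1, 1))
    p_pkg <- detect_responders(matrix(x, 1), matrix(y, 1))$p_value
    p_ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-12)
  }
})

test_that("masked fractions floor at zero", {
  expect_equal(masked_fraction(12.8), 11.8)
  expect_equal(masked_fraction(0.9), 0)
  expect_equal(masked_fraction(7.3, mask_pct = 0), 7.3)
  calls <- data.frame(direction = c(rep("excited", 3), rep("ns", 97)))
  mf <- masked_fraction(calls)
  expect_equal(mf$displayed_pct[mf$direction == "excited"], 2)
  expect_equal(mf$displayed_pct[mf$direction == "inhibited"], 0)
})

test_that("partition bootstrap: symmetry, extremes, contracts", {
  set.seed(3)
  a <- sample(rep(c("x", "y", "z"), times = c(30, 20, 10)))
  # identical multisets: observed difference 0, p large
  db <- distribution_bootstrap(a, a, n_partitions = 500, seed = 1)
  expect_true(all(db$observed == 0))
  expect_true(all(db$p_value >= 0.5))
  # perfectly segregated types: p at the add-one floor
  db2 <- distribution_bootstrap(rep("x", 200), rep("y", 200),
                                n_partitions = 2000, seed = 2)
  expect_true(all(db2$p_value <= 1e-3))
  expect_true(all(db2$p_value >= 1 / 2001))
  expect_error(distribution_bootstrap(a, a, n_partitions = 0),
               class = "xmv1_bad_argument")
  expect_error(distribution_bootstrap(character(0), a),
               class = "xmv1_bad_argument")
})

test_that("partition bootstrap is equivariant under cluster relabelling", {
  set.seed(4)
  a <- sample(c("c1", "c2", "c3"), 80, replace = TRUE)
  b <- sample(c("c1", "c2", "c3"), 60, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  db1 <- distribution_bootstrap(a, b, n_partitions = 500, seed = 9)
  # bijective relabelling that preserves alphabetical order mapping
  perm <- c(c1 = "d2", c2 = "d3", c3 = "d1")
  db2 <- distribution_bootstrap(perm[a], perm[b], n_partitions = 500, seed = 9)
  for (cl in db1$cluster) {
    expect_equal(db1$p_value[db1$cluster == cl],
                 db2$p_value[db2$cluster == perm[cl]])
    expect_equal(db1$observed[db1$cluster == cl],
                 db2$observed[db2$cluster == perm[cl]])
  }
})

test_that("linear predictions pair trials and preserve the mean exactly", {
  set.seed(5)
  vis <- matrix(rnorm(20 * 30), 20)
  aud <- matrix(rnorm(20 * 30), 20)
  pred <- linear_prediction_trials(vis, aud, seed = 1)
  expect_equal(nrow(pred), 20)
  expect_equal(colMeans(pred), colMeans(vis) + colMeans(aud), tolerance = 1e-12)
  # zero auditory trials: predictions are a permutation of the visual trials
  pred0 <- linear_prediction_trials(vis, matrix(0, 20, 30), seed = 2)
  expect_equal(pred0[order(pred0[, 1]), ], vis[order(vis[, 1]), ])
  # unequal counts: uses the smaller number
  expect_equal(nrow(linear_prediction_trials(vis[1:7, ], aud)), 7)
})

test_that("supra-linearity bootstrap: p-range, sign flip, null calibration", {
  set.seed(6)
  b <- matrix(rnorm(20 * 10), 20)
  p <- matrix(rnorm(20 * 10), 20)
  r1 <- supralinearity_bootstrap(b, p, n_shuffles = 500, seed = 3)
  expect_gte(r1$p_value, 1 / 501)
  expect_lte(r1$p_value, 1)
  r2 <- supralinearity_bootstrap(p, b, n_shuffles = 500, seed = 3)
  expect_equal(r2$observed_stat, -r1$observed_stat)
  expect_lt(abs(r2$p_value - r1$p_value), 0.1)
  expect_error(supralinearity_bootstrap(b[1:2, ], p),
               class = "xmv1_bad_argument")
  expect_warning(supralinearity_bootstrap(b, p, n_shuffles = 50, seed = 1),
                 "coarse")
})

test_that("windowed statistics use the requested response window", {
  fr <- 10
  n_t <- 30
  b <- matrix(0, 10, n_t); p <- matrix(0, 10, n_t)
  # effect confined to samples 11:20 (1-2 s)
  b[, 11:20] <- 5
  r_in <- supralinearity_bootstrap(b, p, n_shuffles = 200, window = c(1, 2),
                                   frame_rate = fr, seed = 1)
  expect_equal(r_in$observed_stat, 5)
  r_out <- supralinearity_bootstrap(b, p, n_shuffles = 200, window = c(2.2, 3),
                                    frame_rate = fr, seed = 1)
  expect_equal(r_out$observed_stat, 0)
})
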