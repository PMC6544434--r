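# preprocess module: neuropil subtraction, baseline, dF/F, deconvolution,
# smoothing, epoching.

test_that("neuropil subtraction is the stated elementwise identity", {
  tr <- roi_trace_set(matrix(10, 2, 5), matrix(10, 2, 5))
  expect_equal(unname(subtract_neuropil(tr, 0.7)), matrix(3, 2, 5))
  tr0 <- roi_trace_set(matrix(1:10, 2), matrix(0, 2, 5))
  expect_equal(subtract_neuropil(tr0), tr0$F)
  expect_error(roi_trace_set(matrix(0, 2, 5), matrix(0, 2, 4)),
               class = "xmv1_shape_mismatch")
})

test_that("exact 0.7 mixing makes neuropil subtraction an identity", {
  rates <- matrix(stats::runif(3 * 600, 0, 5), 3)
  tr <- rates_to_fluorescence(rates, noise_sd = 0.01, seed = 4)
  truth <- attr(tr, "truth")
  F_c <- subtract_neuropil(tr, 0.7)
  expect_equal(F_c, truth$F_cell, tolerance = 1e-10)
})

test_that("baseline estimation matches a brute-force block-window oracle", {
  fr <- 10
  n_block <- 50
  # constant trace: baseline equals the constant everywhere
  cst <- matrix(5, 1, n_block * 6)
  bl <- estimate_baseline(cst, fr)
  expect_true(all(abs(bl$F_c0 - 5) < 1e-12))

  # one deep notch in block 4 is shared by the 5-block neighbourhood
  x <- matrix(10, 1, n_block * 8)
  x[1, 3.5 * n_block] <- 1
  bl <- estimate_baseline(x, fr, gaussian_sigma = 0)  # no filtering: pure min
  g <- x[1, ]
  oracle <- sapply(1:8, function(k) {
    w <- max(1, k - 2):min(8, k + 2)
    min(g[((min(w) - 1) * n_block + 1):(max(w) * n_block)])
  })
  expect_equal(as.numeric(bl$F_c0), oracle)
  expect_true(all(bl$F_c0[1, 2:6] == 1))
  expect_true(all(bl$F_c0[1, c(1, 7, 8)] == 10))

  # rising staircase: baseline nondecreasing across blocks
  stair <- matrix(rep(1:7, each = n_block), 1)
  bl <- estimate_baseline(stair, fr)
  expect_true(all(diff(as.numeric(bl$F_c0)) >= 0))

  # non-positive baselines are flagged
  neg <- matrix(c(rep(1, 200), rep(-1, 100)), 1)
  expect_true(1 %in% estimate_baseline(neg, fr)$flagged)
})

test_that("dff normalises correctly and rejects bad baselines", {
  F_c <- matrix(c(2, 4), 1)
  bl <- list(F_c0 = matrix(2, 1, 1), block_index = c(1L, 1L))
  expect_equal(as.numeric(dff(F_c, bl)), c(0, 1))
  bad <- list(F_c0 = matrix(0, 1, 1), block_index = c(1L, 1L))
  expect_error(dff(F_c, bad), "ROI", class = "xmv1_bad_baseline")
})

test_that("deconvolution: kernel identities, linearity, round trip", {
  fr <- 31.5
  # constant f -> c / tau
  expect_equal(deconvolve(rep(3, 100), tau = 2, frame_rate = fr),
               rep(1.5, 100))
  # exp(-t/tau) is (approximately) in the nullspace
  t <- (0:199) / fr
  r <- deconvolve(exp(-t / 2), tau = 2, frame_rate = fr)
  expect_lt(max(abs(r)), 0.005)
  # exact linearity
  set.seed(1)
  f1 <- matrix(rnorm(300), 2)
  f2 <- matrix(rnorm(300), 2)
  expect_equal(deconvolve(2 * f1 + 3 * f2, 2, fr),
               2 * deconvolve(f1, 2, fr) + 3 * deconvolve(f2, 2, fr),
               tolerance = 1e-12)
  # impulse train round trip (up to the one-frame forward-difference lead)
  imp <- numeric(400)
  imp[c(50, 180, 300)] <- 1
  k <- calcium_kernel(fr, tau_decay = 2, tau_rise = 0)
  f <- xmv1:::conv_causal(imp, k)
  rec <- deconvolve(f, 2, fr) / fr  # derivative scaling: dt spikes
  expect_equal(which(rec > 0.5), c(50, 180, 300) - 1L)
  expect_lt(max(abs(rec[-(c(50, 180, 300) - 1L)])), 0.01)
})

test_that("sliding-window smoothing is a truncated centered boxcar", {
  fr <- 31.5
  expect_equal(smooth_traces(rep(2, 50), fr), rep(2, 50))
  # unit impulse -> plateau of height 1/w over w samples (interior)
  w <- round(0.19 * fr)
  x <- numeric(101); x[51] <- 1
  s <- smooth_traces(x, fr)
  expect_equal(sum(s > 1e-12), w)
  expect_equal(max(s), 1 / w)
  # white-noise variance reduced by ~1/w
  set.seed(2)
  z <- rnorm(30000)
  ratio <- stats::var(smooth_traces(z, fr)) / stats::var(z)
  expect_equal(ratio, 1 / w, tolerance = 0.1)
  expect_error(smooth_traces(z, fr, window = 0.001), class = "xmv1_bad_argument")
})

test_that("epoching subtracts baselines and blanks; missing profiles flagged", {
  ds <- small_dataset()
  pp <- small_preprocessed()
  rp <- epoch_and_average(pp$r, ds$trials, frame_rate = pp$frame_rate)
  # blank profile is exactly zero by self-subtraction
  expect_true(all(abs(rp$profiles$blank) < 1e-12))
  # loud_ON neurons peak within 0.5 s of the down-ramp onset
  loud <- which(ds$truth_labels[pp$kept] == "loud_ON")
  onset_i <- round(attr(ds$trials, "stim_onset") * pp$frame_rate)
  prof <- rp$profiles$down_ramp[loud, , drop = FALSE]
  peaks <- apply(prof, 1, which.max)
  # template peaks 150 ms after onset; the uninverted GCaMP6s rise time adds
  # a further ~70-150 ms lag to the deconvolved profiles
  lag_s <- (peaks - onset_i) / pp$frame_rate
  expect_true(all(lag_s > 0 & lag_s <= 0.65))
  expect_lte(stats::median(lag_s), 0.5)
  # a stimulus with zero valid trials is flagged missing, not zero-filled
  tr2 <- ds$trials
  tr2$valid[tr2$stimulus == "looming"] <- FALSE
  rp2 <- epoch_and_average(pp$r, tr2, frame_rate = pp$frame_rate)
  expect_true(rp2$missing[["looming"]])
  expect_null(rp2$profiles$looming)
})

test_that("dff is idempotent on a constant-baseline trace", {
  # compact noiseless pulses on a constant baseline: every baseline window
  # contains quiet samples, so F_c0 recovers the constant exactly and a
  # second application of baseline + dff is the identity
  fr <- 31.5
  n_block <- round(5 * fr)
  F_c <- matrix(100, 2, n_block * 8)
  for (b in c(2, 5)) {
    idx <- (b - 1) * n_block + 40:60
    F_c[, idx] <- F_c[, idx] + 30
  }
  bl1 <- estimate_baseline(F_c, fr, gaussian_sigma = 0.2)
  f1 <- dff(F_c, bl1)
  F2 <- 1 + f1
  bl2 <- estimate_baseline(F2, fr, gaussian_sigma = 0.2)
  f2 <- dff(F2, bl2)
  expect_lt(max(abs(f2 - f1)), 1e-10)
})
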