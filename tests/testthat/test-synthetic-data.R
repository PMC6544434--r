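# synthetic_data module: rate templates, forward model, pupil tracks,
# retinotopy movies, determinism.

test_that("rate templates respect the archetype timing rules", {
  tpl <- make_rate_templates()
  fr <- attr(tpl, "frame_rate")
  t <- attr(tpl, "time")
  onset <- attr(tpl, "stim_onset")
  dur <- attr(tpl, "stim_dur")

  # blank and visual stimuli give no auditory-archetype response; all >= 0
  for (ty in av_cell_types()) {
    expect_true(all(tpl[[ty]]$blank == 0))
    expect_true(all(unlist(tpl[[ty]]) >= 0))
  }
  expect_true(all(unlist(tpl$nonresponsive) == 0))

  peak_time <- function(v) t[which.max(v)] - onset
  # loud_ON: strong down-ramp onset response, weak up-ramp response near 2 s
  expect_lt(peak_time(tpl$loud_ON$down_ramp), 0.5)
  expect_gt(max(tpl$loud_ON$down_ramp), max(tpl$loud_ON$up_ramp))
  expect_gt(peak_time(tpl$loud_ON$up_ramp), 1.7)
  expect_lt(peak_time(tpl$loud_ON$up_ramp), 2.3)
  # loud_OFF: argmax after the 2 s stimulus ends, for both ramps
  expect_gt(peak_time(tpl$loud_OFF$down_ramp), dur)
  expect_gt(peak_time(tpl$loud_OFF$up_ramp), dur)

  # ON types peak within 500 ms of onset; OFF types within 500 ms of offset
  # (dominant stimulus = global argmax across stimuli)
  global_peak <- function(ty) {
    m <- sapply(tpl[[ty]], max)
    peak_time(tpl[[ty]][[names(which.max(m))]])
  }
  for (ty in c("quiet_ON", "ON_mixed")) {
    expect_lt(global_peak(ty), 0.5)
  }
  expect_true(global_peak("loud_OFF") > dur && global_peak("loud_OFF") < dur + 0.5)
})

test_that("unknown stimulus descriptors are rejected with a named error", {
  expect_error(make_rate_templates(c("up_ramp", "chirp")),
               class = "xmv1_unknown_stimulus")
  expect_error(make_rate_templates(frame_rate = 0), class = "xmv1_bad_argument")
})

test_that("forward model: zero rates give constant traces", {
  rates <- matrix(0, 2, 400)
  tr <- rates_to_fluorescence(rates, noise_sd = 0, np_sd = 0, drift_sd = 0,
                              baseline = 100, seed = 1)
  expect_true(all(abs(tr$F - tr$F[1, 1]) < 1e-9))
  expect_true(all(abs(tr$F_np - tr$F_np[1, 1]) < 1e-9))
  # with the contaminant removed, the cell signal is exactly the baseline
  expect_equal(unname(tr$F - 0.7 * tr$F_np), matrix(100, 2, 400),
               tolerance = 1e-12)
})

test_that("forward model: impulse response decays as exp(-t/tau)", {
  rates <- matrix(0, 1, 300)
  rates[1, 50] <- 1
  tr <- rates_to_fluorescence(rates, tau_rise = 0, noise_sd = 0, np_sd = 0,
                              drift_sd = 0, seed = 1)
  sig <- (tr$F - 0.7 * tr$F_np - 100)[1, ]
  expect_true(all(sig[1:49] == 0))
  post <- sig[51:120]
  ratios <- post[-1] / post[-length(post)]
  expect_equal(ratios, rep(exp(-1 / (31.5 * 2)), length(ratios)),
               tolerance = 1e-8)
})

test_that("nonzero rise time delays the deconvolved peak by tens of ms", {
  rates <- matrix(0, 1, 400)
  rates[1, 100] <- 1
  fr <- 31.5
  tr <- rates_to_fluorescence(rates, tau_rise = 0.18, noise_sd = 0, np_sd = 0,
                              drift_sd = 0, seed = 1)
  f <- (tr$F - 0.7 * tr$F_np) / 100 - 1
  r <- smooth_traces(deconvolve(f, 2, fr), fr)
  delay_s <- (which.max(r) - 100) / fr
  expect_gte(delay_s, 1 / fr)     # at least one frame
  expect_lte(delay_s, 0.2)        # and well under the indicator decay
})

test_that("non-finite rates are rejected", {
  expect_error(rates_to_fluorescence(matrix(c(1, NA), 1)),
               class = "xmv1_bad_argument")
})

test_that("pupil track: quiet tracks stay within jitter, saccades are logged", {
  trials <- make_trial_table(n_reps = 4, contexts = "light", seed = 2)
  quiet <- make_pupil_track(trials = trials, saccade_rate = 0, seed = 3)
  ftq <- filter_trials(trials, quiet)
  expect_true(all(ftq$max_displacement_um < 30))
  expect_equal(mean(ftq$keep), 1)

  sacc <- make_pupil_track(trials = trials, saccade_rate = 1,
                           saccade_amp_um = 100, seed = 3)
  truth <- attr(sacc, "saccades")
  expect_equal(nrow(truth), nrow(trials))
  fts <- filter_trials(trials, sacc)
  expect_true(all(!fts$keep[fts$trial_id %in% truth$trial_id]))
})

test_that("pupil track is byte-identical under a fixed seed", {
  a <- make_pupil_track(duration = 20, seed = 11)
  b <- make_pupil_track(duration = 20, seed = 11)
  expect_identical(a, b)
})

test_that("retinotopy movie matches its stated per-pixel model", {
  ph <- matrix(pi / 3, 1, 1)
  mv <- make_retinotopy_movie(width = 1, height = 1, n_cycles = 3,
                              frame_rate = 5, phase_map = ph, delay = 0,
                              amplitude_mask = matrix(1, 1, 1), noise_sd = 0)
  t <- (seq_len(dim(mv$fwd)[1]) - 1) / 5
  expect_equal(mv$fwd[, 1, 1], sin(2 * pi * 0.1 * t + pi / 3), tolerance = 1e-12)
  expect_equal(mv$rev[, 1, 1], sin(2 * pi * 0.1 * t - pi / 3), tolerance = 1e-12)
  expect_error(make_retinotopy_movie(n_cycles = 1), class = "xmv1_bad_argument")
})

test_that("synthetic dataset invariants hold and the seed is reproducible", {
  ds <- make_synthetic_dataset(n_neurons = 12, n_reps = 2, seed = 5)
  expect_equal(dim(ds$traces$F), dim(ds$truth_rates))
  expect_equal(length(ds$truth_labels), nrow(ds$traces$F))
  expect_true(all(ds$trials$onset_sample <= ncol(ds$traces$F)))
  expect_true(all(ds$trials$block_start + ds$trials$n_samples - 1 <=
                    ncol(ds$traces$F)))
  expect_true(all(ds$truth_rates[ds$truth_labels == "nonresponsive", ] == 0))
  ds2 <- make_synthetic_dataset(n_neurons = 12, n_reps = 2, seed = 5)
  expect_identical(ds$traces$F, ds2$traces$F)
  expect_identical(ds$trials, ds2$trials)
  expect_identical(ds$pupil, ds2$pupil)
})
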