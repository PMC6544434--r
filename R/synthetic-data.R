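# Synthetic-data generator: ground-truth datasets with the statistical
# structure the downstream analysis assumes (functional cell types, GCaMP6s
# kinetics, neuropil contamination, trial structure, pupil tracks, periodic
# retinotopy movies). Every stochastic draw is controlled by an explicit seed.

#' Canonical stimulus set
#'
#' White-noise intensity ramps (50-85 dB SPL range, 2 s), looming/receding
#' visual disks (2 s), and a blank (no stimulation) condition. The down-ramp
#' starts loud and decays; the up-ramp starts quiet and reaches its maximum at
#' the end of the 2 s stimulus.
#'
#' @return character vector of stimulus descriptors.
#' @export
av_stimuli <- function() c("up_ramp", "down_ramp", "looming", "receding", "blank")

#' Functional cell-type labels
#'
#' The archetypes emulated by the generator: onset (ON), offset (OFF) and
#' sustained (tonic) responders with loud or quiet intensity tuning, their
#' mixtures, and a non-responsive pool.
#'
#' @return character vector of type labels.
#' @export
av_cell_types <- function() {
  c("loud_ON", "quiet_ON", "ON_mixed", "loud_OFF",
    "quiet_tonic", "loud_tonic", "tonic_plus_loudOFF", "nonresponsive")
}

av_modality <- function(stimulus) {
  m <- c(up_ramp = "auditory", down_ramp = "auditory",
         looming = "visual", receding = "visual", blank = "blank")
  unname(m[stimulus])
}

# Alpha-function transient peaking at t0 + tau.
alpha_bump <- function(t, t0, tau, amp) {
  tt <- t - t0
  ifelse(tt > 0, amp * (tt / tau) * exp(1 - tt / tau), 0)
}

# Plateau over [t0, t1] with raised-cosine edges of width `edge`.
plateau <- function(t, t0, t1, amp, edge = 0.1) {
  y <- numeric(length(t))
  up <- t >= t0 & t < t0 + edge
  flat <- t >= t0 + edge & t <= t1 - edge
  down <- t > t1 - edge & t <= t1
  y[up] <- amp * 0.5 * (1 - cos(pi * (t[up] - t0) / edge))
  y[flat] <- amp
  y[down] <- amp * 0.5 * (1 - cos(pi * (t1 - t[down]) / edge))
  y
}

#' Ground-truth firing-rate templates per cell type and stimulus
#'
#' One non-negative rate time course (Hz) over a single imaging block for each
#' (functional type, stimulus) pair. Loud-ON cells respond strongly at the
#' down-ramp onset (the ramp starts loud) and weakly near 2 s into the up-ramp
#' (when it reaches its maximum); OFF cells respond after the 2 s stimulus
#' ends; tonic cells hold a plateau during the half of the ramp in their
#' preferred intensity range. Auditory archetypes do not respond to the visual
#' stimuli, and the blank template is identically zero.
#'
#' @param stimuli character vector of stimulus descriptors; must be a subset
#'   of [av_stimuli()].
#' @param frame_rate imaging frame rate in Hz (default 31.5).
#' @param block_len imaging block duration in seconds (default 5).
#' @param stim_onset stimulus onset within the block, seconds (default 0.5,
#'   leaving a pre-stimulus baseline window).
#' @param stim_dur stimulus duration in seconds (default 2).
#' @return named list: for each cell type, a named list of rate templates
#'   (numeric vectors of length `round(block_len * frame_rate)`). Attributes
#'   carry the timing parameters.
#' @export
make_rate_templates <- function(stimuli = av_stimuli(), frame_rate = 31.5,
                                block_len = 5, stim_onset = 0.5, stim_dur = 2) {
  if (frame_rate <= 0) xmv1_stop("frame_rate must be > 0", "xmv1_bad_argument")
  unknown <- setdiff(stimuli, av_stimuli())
  if (length(unknown) > 0) {
    xmv1_stop(paste0("unknown stimulus descriptor(s): ",
                     paste(unknown, collapse = ", ")), "xmv1_unknown_stimulus")
  }
  n <- round(block_len * frame_rate)
  t <- (seq_len(n) - 1) / frame_rate
  on <- stim_onset
  off <- stim_onset + stim_dur
  zero <- numeric(n)

  aud <- function(down, up) {
    tpl <- list(up_ramp = up, down_ramp = down, looming = zero,
                receding = zero, blank = zero)
    tpl[stimuli]
  }

  tau_on <- 0.15  # transient peaks 150 ms after its trigger
  templates <- list(
    loud_ON = aud(
      down = alpha_bump(t, on, tau_on, 20),
      up   = alpha_bump(t, on + stim_dur - tau_on, tau_on, 6)),
    quiet_ON = aud(
      down = alpha_bump(t, off - 0.3, tau_on, 5),
      up   = alpha_bump(t, on, tau_on, 18)),
    ON_mixed = aud(
      down = alpha_bump(t, on, tau_on, 12),
      up   = alpha_bump(t, on, tau_on, 12)),
    loud_OFF = aud(
      down = alpha_bump(t, off, tau_on, 4),
      up   = alpha_bump(t, off, tau_on, 18)),
    quiet_tonic = aud(
      down = plateau(t, on + 1, off, 8),
      up   = plateau(t, on, on + 1, 8)),
    loud_tonic = aud(
      down = plateau(t, on, on + 1, 8),
      up   = plateau(t, on + 1, off, 8)),
    tonic_plus_loudOFF = aud(
      down = plateau(t, on, on + 1, 6) + alpha_bump(t, off, tau_on, 3),
      up   = plateau(t, on + 1, off, 6) + alpha_bump(t, off, tau_on, 10)),
    nonresponsive = aud(down = zero, up = zero)
  )
  structure(templates, frame_rate = frame_rate, block_len = block_len,
            stim_onset = stim_onset, stim_dur = stim_dur,
            time = t, class = "xmv1_templates")
}

#' Trial/stimulus table for a block-structured recording
#'
#' Emulates the acquisition protocol: imaging in 5 s blocks (frames are
#' acquired only during blocks, so the recorded trace is the concatenation of
#' blocks), one stimulus per block, each stimulus repeated `n_reps` times per
#' context, order randomised within context.
#'
#' @param stimuli stimulus descriptors.
#' @param n_reps repetitions per stimulus per context (default 20).
#' @param contexts character vector of illumination contexts, e.g.
#'   `c("dark", "light")`.
#' @param frame_rate imaging frame rate (Hz).
#' @param block_len,stim_onset block duration and stimulus onset (s).
#' @param randomize randomise stimulus order within context.
#' @param seed RNG seed for the ordering.
#' @return data.frame with columns trial_id, stimulus, modality, context,
#'   block_start, onset_sample, n_samples, valid. Attributes: frame_rate,
#'   block_len, stim_onset.
#' @export
make_trial_table <- function(stimuli = av_stimuli(), n_reps = 20,
                             contexts = "dark", frame_rate = 31.5,
                             block_len = 5, stim_onset = 0.5,
                             randomize = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_block <- round(block_len * frame_rate)
  rows <- list()
  k <- 0L
  for (ctx in contexts) {
    stim <- rep(stimuli, each = n_reps)
    if (randomize) stim <- sample(stim)
    for (s in stim) {
      k <- k + 1L
      rows[[k]] <- data.frame(trial_id = k, stimulus = s,
                              modality = av_modality(s), context = ctx,
                              stringsAsFactors = FALSE)
    }
  }
  tt <- do.call(rbind, rows)
  tt$block_start <- (seq_len(nrow(tt)) - 1L) * n_block + 1L
  tt$onset_sample <- tt$block_start + round(stim_onset * frame_rate)
  tt$n_samples <- n_block
  tt$valid <- TRUE
  structure(tt, frame_rate = frame_rate, block_len = block_len,
            stim_onset = stim_onset)
}

#' ROI trace container
#'
#' @param F ROI fluorescence matrix (ROI x time, arbitrary units).
#' @param F_np matched neuropil matrix, same shape.
#' @param frame_rate acquisition rate in Hz.
#' @return object of class `RoiTraceSet`.
#' @export
roi_trace_set <- function(F, F_np, frame_rate = 31.5) {
  F <- as.matrix(F); F_np <- as.matrix(F_np)
  if (!all(dim(F) == dim(F_np))) {
    xmv1_stop("F and F_np must have the same shape", "xmv1_shape_mismatch")
  }
  if (frame_rate <= 0) xmv1_stop("frame_rate must be > 0", "xmv1_bad_argument")
  if (!all(is.finite(F)) || !all(is.finite(F_np))) {
    xmv1_stop("trace values must be finite", "xmv1_bad_argument")
  }
  structure(list(F = F, F_np = F_np, frame_rate = frame_rate),
            class = "RoiTraceSet")
}

#' @export
print.RoiTraceSet <- function(x, ...) {
  cat(sprintf("RoiTraceSet: %d ROIs x %d samples at %.3g Hz (%.1f s)\n",
              nrow(x$F), ncol(x$F), x$frame_rate, ncol(x$F) / x$frame_rate))
  invisible(x)
}

#' GCaMP6s-like calcium kernel
#'
#' Difference of exponentials `exp(-t/tau_decay) - exp(-t/tau_rise)`; with
#' `tau_rise = 0` it degenerates to a pure exponential decay, in which case
#' the deconvolution `r = f' + f/tau` inverts the forward model exactly (up to
#' discretisation).
#'
#' @param frame_rate sampling rate (Hz).
#' @param tau_decay decay time constant, seconds (default 2, GCaMP6s).
#' @param tau_rise rise time constant, seconds (default 0.18).
#' @return numeric kernel vector (lag 0 first).
#' @export
calcium_kernel <- function(frame_rate, tau_decay = 2, tau_rise = 0.18) {
  if (!(tau_decay > tau_rise) || tau_rise < 0) {
    xmv1_stop("need tau_decay > tau_rise >= 0", "xmv1_bad_argument")
  }
  t <- seq(0, 6 * tau_decay, by = 1 / frame_rate)
  k <- exp(-t / tau_decay)
  if (tau_rise > 0) k <- k - exp(-t / tau_rise)
  k
}

#' Forward model: firing rates to raw fluorescence
#'
#' Builds `F = baseline * (1 + amp * (rates (*) kernel) * dt) + noise` with a
#' GCaMP6s-like difference-of-exponentials kernel, plus a shared slow neuropil
#' contaminant mixed with the exact coefficient `neuropil_weight`, so that
#' downstream neuropil subtraction with the same coefficient removes it
#' exactly. An optional slow multiplicative drift emulates baseline
#' instability.
#'
#' @param rates firing-rate matrix (ROI x time, Hz), all finite and >= 0.
#' @param frame_rate sampling rate (Hz).
#' @param tau_decay,tau_rise calcium kernel time constants (s).
#' @param amp fluorescence response amplitude, dF/F per spike (default 0.05).
#' @param neuropil_weight mixing coefficient of the contaminant (default 0.7).
#' @param noise_sd white-noise standard deviation in dF/F units (default
#'   0.02, typical shot noise of good somatic GCaMP6s recordings; note the
#'   deconvolution derivative amplifies per-frame noise by ~frame_rate).
#' @param baseline baseline fluorescence (AU).
#' @param drift_sd standard deviation of a slow multiplicative baseline drift
#'   (dF/F units, default 0 = no drift).
#' @param np_sd amplitude of the shared neuropil fluctuation (dF/F units).
#' @param seed RNG seed.
#' @return `RoiTraceSet`; attribute `truth` holds the noiseless cell signal
#'   (`F_cell`), the clean dF/F (`f_sig`) and the kernel.
#' @export
rates_to_fluorescence <- function(rates, frame_rate = 31.5, tau_decay = 2,
                                  tau_rise = 0.18, amp = 0.05,
                                  neuropil_weight = 0.7, noise_sd = 0.02,
                                  baseline = 100, drift_sd = 0, np_sd = 0.05,
                                  seed = NULL) {
  rates <- as.matrix(rates)
  if (!all(is.finite(rates))) {
    xmv1_stop("rates must be finite", "xmv1_bad_argument")
  }
  if (noise_sd < 0) xmv1_stop("noise_sd must be >= 0", "xmv1_bad_argument")
  if (!is.null(seed)) set.seed(seed)
  n_roi <- nrow(rates); n_t <- ncol(rates)
  dt <- 1 / frame_rate
  k <- calcium_kernel(frame_rate, tau_decay, tau_rise)
  f_sig <- t(apply(rates, 1L, function(r) conv_causal(r, k))) * amp * dt
  if (n_roi == 1L) f_sig <- matrix(f_sig, nrow = 1L)

  drift <- 0
  if (drift_sd > 0) {
    d <- apply(matrix(stats::rnorm(n_roi * n_t), n_roi), 1L, cumsum)
    d <- t(d)
    d <- d / pmax(apply(d, 1L, stats::sd), .Machine$double.eps) * drift_sd
    drift <- gaussian_smooth_rows(d, 2 * frame_rate)
  }
  noise <- if (noise_sd > 0) {
    matrix(stats::rnorm(n_roi * n_t, sd = noise_sd), n_roi)
  } else 0

  F_cell <- baseline * (1 + f_sig + drift) + baseline * noise
  # Shared slow contaminant (one field of view): low-passed random walk.
  z <- cumsum(stats::rnorm(n_t))
  z <- z - mean(z)
  s <- stats::sd(z)
  if (s > 0) z <- z / s * np_sd
  z <- gaussian_smooth_rows(z, frame_rate)  # ~1 s smoothing
  F_np <- matrix(rep(baseline * 0.5 * (1 + z), each = n_roi), n_roi)
  F <- F_cell + neuropil_weight * F_np
  out <- roi_trace_set(F, F_np, frame_rate)
  attr(out, "truth") <- list(F_cell = F_cell, f_sig = f_sig, kernel = k,
                             amp = amp, baseline = baseline)
  out
}

#' Synthetic pupil-center trajectory with injected saccades
#'
#' Piecewise-constant gaze plus Gaussian jitter at 50 Hz; with a trial table,
#' each trial receives (with probability `saccade_rate`) one step displacement
#' of amplitude `saccade_amp_um` at a random time inside its 2 s stimulation
#' window. Ground-truth saccade times/amplitudes are recorded alongside. The
#' track shares the contiguous block timebase of the imaging.
#'
#' @param duration track duration (s); inferred from `trials` if omitted.
#' @param sample_rate sampling rate (Hz, default 50).
#' @param trials optional trial table from [make_trial_table()].
#' @param saccade_rate per-trial probability of one saccade.
#' @param saccade_amp_um saccade amplitude (micrometers on the eye).
#' @param jitter_um tracking jitter standard deviation (micrometers).
#' @param stim_window saccades are drawn inside `onset + stim_window` (s).
#' @param seed RNG seed; fixed seed gives a byte-identical track.
#' @return data.frame of class `PupilTrack` with columns t, x_um, y_um,
#'   diameter_um; attributes `sample_rate` and `saccades` (ground truth).
#' @export
make_pupil_track <- function(duration = NULL, sample_rate = 50, trials = NULL,
                             saccade_rate = 0.1, saccade_amp_um = 100,
                             jitter_um = 2, stim_window = c(0, 2),
                             seed = NULL) {
  if (sample_rate <= 0) xmv1_stop("sample_rate must be > 0", "xmv1_bad_argument")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(duration)) {
    if (is.null(trials)) xmv1_stop("need duration or trials", "xmv1_bad_argument")
    fr <- attr(trials, "frame_rate")
    duration <- (max(trials$block_start + trials$n_samples) - 1) / fr
  }
  n <- floor(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  x <- stats::rnorm(n, sd = jitter_um)
  y <- stats::rnorm(n, sd = jitter_um)
  sacc <- data.frame(trial_id = integer(0), t = numeric(0),
                     amplitude_um = numeric(0))
  if (!is.null(trials) && saccade_rate > 0) {
    fr <- attr(trials, "frame_rate")
    for (i in seq_len(nrow(trials))) {
      if (stats::runif(1) >= saccade_rate) next
      t_on <- (trials$onset_sample[i] - 1) / fr
      ts <- stats::runif(1, t_on + stim_window[1] + 0.05,
                         t_on + stim_window[2] - 0.05)
      ang <- stats::runif(1, 0, 2 * pi)
      step <- t >= ts
      x[step] <- x[step] + saccade_amp_um * cos(ang)
      y[step] <- y[step] + saccade_amp_um * sin(ang)
      sacc <- rbind(sacc, data.frame(trial_id = trials$trial_id[i], t = ts,
                                     amplitude_um = saccade_amp_um))
    }
  }
  diameter <- 1000 + 50 * sin(2 * pi * t / 60)
  out <- data.frame(t = t, x_um = x, y_um = y, diameter_um = diameter)
  structure(out, sample_rate = sample_rate, saccades = sacc,
            class = c("PupilTrack", "data.frame"))
}

#' Synthetic bidirectional retinotopy movies
#'
#' Periodic drifting-bar intrinsic-imaging movies: pixel (i, j) follows
#' `amplitude_mask * sin(2*pi*stim_freq*t + direction*phase_map + delay)` plus
#' Gaussian noise, for sweep directions +1 (forward) and -1 (reverse). The
#' hemodynamic delay enters with the same sign in both directions and the
#' retinotopic phase flips with the sweep direction, so the bidirectional
#' combination (half-difference / half-sum) recovers both exactly at zero
#' noise.
#'
#' @param width,height movie geometry in pixels.
#' @param n_cycles number of stimulus cycles (>= 2; default 10).
#' @param stim_freq stimulus frequency in Hz (default 0.1).
#' @param frame_rate acquisition rate (Hz, default 15).
#' @param phase_map height x width matrix of retinotopic phases (radians);
#'   default: horizontal linear gradient spanning +/- 0.4*pi.
#' @param delay hemodynamic phase delay (radians, default 0.4).
#' @param amplitude_mask height x width response amplitude per pixel;
#'   default: unit-amplitude centered disk of radius `min(width, height)/4`.
#' @param noise_sd Gaussian noise SD per frame.
#' @param seed RNG seed.
#' @return list with arrays `fwd` and `rev` (time x height x width),
#'   acquisition parameters, and the ground-truth `phase_map`, `delay`,
#'   `amplitude_mask`.
#' @export
make_retinotopy_movie <- function(width = 40, height = 40, n_cycles = 10,
                                  stim_freq = 0.1, frame_rate = 15,
                                  phase_map = NULL, delay = 0.4,
                                  amplitude_mask = NULL, noise_sd = 0,
                                  seed = NULL) {
  if (n_cycles < 2) xmv1_stop("n_cycles must be >= 2", "xmv1_bad_argument")
  if (stim_freq <= 0) xmv1_stop("stim_freq must be > 0", "xmv1_bad_argument")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(phase_map)) {
    phase_map <- matrix(rep(seq(-0.4 * pi, 0.4 * pi, length.out = width),
                            each = height), height)
  }
  if (is.null(amplitude_mask)) {
    cx <- (width + 1) / 2; cy <- (height + 1) / 2
    r <- min(width, height) / 4
    d2 <- outer(seq_len(height), seq_len(width),
                function(i, j) (i - cy)^2 + (j - cx)^2)
    amplitude_mask <- matrix(as.numeric(d2 <= r^2), height)
  }
  n_t <- round(n_cycles / stim_freq * frame_rate)
  t <- (seq_len(n_t) - 1) / frame_rate
  make_one <- function(direction) {
    arr <- array(0, c(n_t, height, width))
    for (ti in seq_len(n_t)) {
      arr[ti, , ] <- amplitude_mask *
        sin(2 * pi * stim_freq * t[ti] + direction * phase_map + delay)
    }
    if (noise_sd > 0) {
      arr <- arr + array(stats::rnorm(length(arr), sd = noise_sd), dim(arr))
    }
    arr
  }
  list(fwd = make_one(1), rev = make_one(-1), frame_rate = frame_rate,
       stim_freq = stim_freq, phase_map = phase_map, delay = delay,
       amplitude_mask = amplitude_mask)
}

#' Full synthetic dataset with known ground truth
#'
#' Draws a population of the canonical functional types, builds the trial
#' table, the noiseless rate matrix (templates scaled by per-trial lognormal
#' gains, plus an optional additive light-context modulation), the raw
#' fluorescence traces via the forward model, and a matched pupil track.
#'
#' @param n_neurons population size (default 300).
#' @param type_probs named numeric vector of type proportions over
#'   [av_cell_types()]; the default mirrors a loud-onset-dominated projection
#'   population with a large non-responsive pool.
#' @param stimuli,n_reps,contexts,frame_rate trial-structure parameters.
#' @param trial_gain_cv coefficient of variation of the per-trial
#'   multiplicative response gain (default 0.3).
#' @param context_mod_hz additive rate change (Hz) during stimulation in the
#'   "light" context for responsive cells (default 0; the projection neurons
#'   emulated by the default generator are context-independent).
#' @param noise_sd,drift_sd,tau_decay,tau_rise,amp,neuropil_weight forward
#'   model parameters, see [rates_to_fluorescence()].
#' @param saccade_rate,saccade_amp_um pupil-track parameters.
#' @param seed integer seed; fully determines all stochastic draws.
#' @return list of class `SyntheticDataset`: `traces` (RoiTraceSet), `trials`,
#'   `truth_labels`, `truth_rates`, `pupil`, `templates`, `seed`.
#' @export
make_synthetic_dataset <- function(n_neurons = 300,
                                   type_probs = c(loud_ON = 0.25,
                                                  quiet_ON = 0.08,
                                                  ON_mixed = 0.07,
                                                  loud_OFF = 0.08,
                                                  quiet_tonic = 0.05,
                                                  loud_tonic = 0.05,
                                                  tonic_plus_loudOFF = 0.07,
                                                  nonresponsive = 0.35),
                                   stimuli = av_stimuli(), n_reps = 20,
                                   contexts = "dark", frame_rate = 31.5,
                                   trial_gain_cv = 0.3, context_mod_hz = 0,
                                   noise_sd = 0.02, drift_sd = 0.01,
                                   tau_decay = 2, tau_rise = 0.18,
                                   amp = 0.05, neuropil_weight = 0.7,
                                   saccade_rate = 0.1, saccade_amp_um = 100,
                                   seed = 1) {
  stopifnot(abs(sum(type_probs) - 1) < 1e-8)
  set.seed(seed)
  templates <- make_rate_templates(stimuli, frame_rate)
  trials <- make_trial_table(stimuli, n_reps, contexts, frame_rate,
                             seed = NULL)  # uses the ambient RNG stream
  n_block <- trials$n_samples[1]
  n_t <- max(trials$block_start) + n_block - 1L

  counts <- round(type_probs * n_neurons)
  counts[1] <- counts[1] + n_neurons - sum(counts)
  labels <- sample(rep(names(counts), counts))

  sdlog <- sqrt(log(1 + trial_gain_cv^2))
  stim_onset <- attr(templates, "stim_onset")
  stim_dur <- attr(templates, "stim_dur")
  tt <- attr(templates, "time")
  stim_mask <- tt >= stim_onset & tt <= stim_onset + stim_dur

  rates <- matrix(0, n_neurons, n_t)
  for (i in seq_len(n_neurons)) {
    type <- labels[i]
    if (type == "nonresponsive") next
    for (j in seq_len(nrow(trials))) {
      tpl <- templates[[type]][[trials$stimulus[j]]]
      gain <- stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      blk <- trials$block_start[j]:(trials$block_start[j] + n_block - 1L)
      resp <- tpl * gain
      if (context_mod_hz != 0 && trials$context[j] == "light" &&
          trials$stimulus[j] != "blank") {
        resp[stim_mask] <- pmax(0, resp[stim_mask] + context_mod_hz)
      }
      rates[i, blk] <- rates[i, blk] + resp
    }
  }

  traces <- rates_to_fluorescence(rates, frame_rate, tau_decay, tau_rise,
                                  amp, neuropil_weight, noise_sd,
                                  drift_sd = drift_sd, seed = NULL)
  pupil <- make_pupil_track(trials = trials, saccade_rate = saccade_rate,
                            saccade_amp_um = saccade_amp_um, seed = NULL)
  structure(list(traces = traces, trials = trials, truth_labels = labels,
                 truth_rates = rates, pupil = pupil, templates = templates,
                 seed = seed),
            class = "SyntheticDataset")
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf("SyntheticDataset: %d neurons, %d trials, seed %d\n",
              nrow(x$traces$F), nrow(x$trials), x$seed))
  print(table(x$truth_labels))
  invisible(x)
}
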