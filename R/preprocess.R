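# Calcium-trace preprocessing: neuropil subtraction, block-wise baseline,
# dF/F, temporal deconvolution r(t) = f'(t) + f(t)/tau, sliding-window
# smoothing, and trial epoching/averaging into response profiles.

#' Neuropil subtraction
#'
#' `F_c(t) = F(t) - weight * F_np(t)`, the standard correction for
#' out-of-focus fluorescence; the default coefficient 0.7 follows the GCaMP6s
#' calibration for mouse cortex.
#'
#' @param traces a [roi_trace_set()].
#' @param weight fraction of the neuropil signal to remove, in `[0, 1]`.
#' @return corrected fluorescence matrix `F_c` (ROI x time).
#' @export
subtract_neuropil <- function(traces, weight = 0.7) {
  stopifnot(inherits(traces, "RoiTraceSet"))
  if (weight < 0 || weight > 1) {
    xmv1_stop("weight must be in [0, 1]", "xmv1_bad_argument")
  }
  traces$F - weight * traces$F_np
}

#' Block-wise baseline fluorescence
#'
#' For each 5 s imaging block, the baseline `F_c0` is the minimum of a
#' Gaussian-filtered trace over the `n_blocks` neighbouring blocks (the block
#' itself and its flanking blocks; truncated at the recording edges). ROIs
#' whose baseline is non-positive in any block are flagged for exclusion.
#'
#' @param F_c corrected fluorescence matrix (ROI x time).
#' @param frame_rate sampling rate (Hz).
#' @param block_len block duration (s, default 5).
#' @param n_blocks neighbourhood size in blocks (default 5, i.e. +/- 2).
#' @param gaussian_sigma Gaussian filter SD in seconds (default 1).
#' @return list: `F_c0` (ROI x block matrix), `block_index` (block id per
#'   sample), `flagged` (row indices of ROIs with non-positive baseline).
#' @export
estimate_baseline <- function(F_c, frame_rate, block_len = 5, n_blocks = 5,
                              gaussian_sigma = 1) {
  F_c <- as.matrix(F_c)
  n_t <- ncol(F_c)
  n_block <- round(block_len * frame_rate)
  n_blk <- max(1L, floor(n_t / n_block))
  block_index <- pmin(n_blk, (seq_len(n_t) - 1L) %/% n_block + 1L)
  g <- gaussian_smooth_rows(F_c, gaussian_sigma * frame_rate)
  if (is.null(dim(g))) g <- matrix(g, nrow = 1L)
  half <- (n_blocks - 1L) %/% 2L
  # block minima of the filtered trace, then window-min over neighbourhoods
  blk_min <- sapply(seq_len(n_blk), function(k) {
    cols <- which(block_index == k)
    apply(g[, cols, drop = FALSE], 1L, min)
  })
  if (is.null(dim(blk_min))) blk_min <- matrix(blk_min, nrow = nrow(F_c))
  F_c0 <- sapply(seq_len(n_blk), function(k) {
    w <- max(1L, k - half):min(n_blk, k + half)
    apply(blk_min[, w, drop = FALSE], 1L, min)
  })
  if (is.null(dim(F_c0))) F_c0 <- matrix(F_c0, nrow = nrow(F_c))
  flagged <- which(apply(F_c0, 1L, function(r) any(r <= 0)))
  list(F_c0 = F_c0, block_index = block_index, flagged = flagged)
}

#' Normalised fluorescence change
#'
#' `f(t) = (F_c(t) - F_c0) / F_c0`, using the per-block baseline.
#'
#' @param F_c corrected fluorescence (ROI x time).
#' @param baseline result of [estimate_baseline()], or a ROI x block matrix
#'   (in which case `block_index` must be given).
#' @param block_index block id per sample (taken from `baseline` if it is an
#'   [estimate_baseline()] result).
#' @return dF/F matrix `f`, same shape as `F_c`.
#' @export
dff <- function(F_c, baseline, block_index = NULL) {
  F_c <- as.matrix(F_c)
  if (is.list(baseline)) {
    block_index <- baseline$block_index
    F_c0 <- baseline$F_c0
  } else {
    F_c0 <- as.matrix(baseline)
  }
  bad <- which(apply(F_c0, 1L, function(r) any(r <= 0)))
  if (length(bad) > 0) {
    xmv1_stop(paste0("non-positive baseline for ROI(s): ",
                     paste(bad, collapse = ", ")), "xmv1_bad_baseline")
  }
  B <- F_c0[, block_index, drop = FALSE]
  (F_c - B) / B
}

#' Temporal deconvolution
#'
#' Inverts the slow calcium decay: `r(t) = f'(t) + f(t)/tau`, with the first
#' derivative computed as a forward difference at one-frame lag (~32 ms at
#' 31.5 Hz). The operator is exactly linear and annihilates `exp(-t/tau)` up
#' to finite-difference error; constants map to `c/tau`. Negative values are
#' retained by default (deconvolution noise and genuine suppression below
#' baseline); set `clip = TRUE` to floor at zero.
#'
#' @param f dF/F matrix (ROI x time) or vector.
#' @param tau indicator decay constant in seconds (default 2, GCaMP6s).
#' @param frame_rate sampling rate (Hz).
#' @param clip floor the result at zero (default FALSE).
#' @return firing-rate estimate `r`, same shape as `f`.
#' @export
deconvolve <- function(f, tau = 2, frame_rate = 31.5, clip = FALSE) {
  if (tau <= 0) xmv1_stop("tau must be > 0", "xmv1_bad_argument")
  vec <- is.null(dim(f))
  f <- if (vec) matrix(f, nrow = 1L) else as.matrix(f)
  n <- ncol(f)
  fp <- (f[, c(2:n, n), drop = FALSE] - f) * frame_rate
  fp[, n] <- fp[, n - 1L]  # repeat last defined derivative
  r <- fp + f / tau
  if (clip) r <- pmax(r, 0)
  if (vec) drop(r) else r
}

#' Sliding-window smoothing
#'
#' Centered moving average (boxcar) of width `window` seconds, truncated at
#' the trace edges; reduces fast deconvolution noise. The default 190 ms
#' corresponds to 6 frames at 31.5 Hz.
#'
#' @param x matrix (ROI x time) or vector.
#' @param frame_rate sampling rate (Hz).
#' @param window window length in seconds (default 0.190).
#' @return smoothed object, same shape.
#' @export
smooth_traces <- function(x, frame_rate = 31.5, window = 0.190) {
  w <- round(window * frame_rate)
  if (w < 1) xmv1_stop("window must cover at least one frame",
                       "xmv1_bad_argument")
  moving_average_rows(x, w)
}

#' Trial epoching and response averaging
#'
#' Cuts the deconvolved traces into stimulus blocks, subtracts the per-trial
#' pre-onset baseline (mean activity in the `baseline_window` seconds before
#' stimulus onset), averages across valid trials of each stimulus, and
#' finally subtracts the average blank-trial profile (so the blank profile
#' itself is identically zero). Stimuli with no valid trials are flagged as
#' missing rather than zero-filled.
#'
#' @param r deconvolved rate matrix (ROI x time).
#' @param trials trial table from [make_trial_table()] (or same layout);
#'   only rows with `valid == TRUE` are used.
#' @param frame_rate sampling rate (Hz); default from `trials` attribute.
#' @param baseline_window pre-onset baseline length in seconds (default 0.5).
#' @param subtract_blank subtract the blank-trial average profile.
#' @param blank_stimulus descriptor of the blank condition.
#' @return object of class `ResponseProfiles`: named list `profiles` of
#'   (neuron x block-sample) matrices, `n_trials_used`, logical `missing`,
#'   plus timing metadata.
#' @export
epoch_and_average <- function(r, trials, frame_rate = attr(trials, "frame_rate"),
                              baseline_window = 0.5, subtract_blank = TRUE,
                              blank_stimulus = "blank") {
  r <- as.matrix(r)
  n_pre <- round(baseline_window * frame_rate)
  stimuli <- unique(trials$stimulus)

  trial_mean <- function(rows) {
    # mean over trials of (block trace - per-trial pre-onset baseline)
    acc <- 0
    for (j in rows) {
      blk <- trials$block_start[j]:(trials$block_start[j] + trials$n_samples[j] - 1L)
      pre <- (trials$onset_sample[j] - n_pre):(trials$onset_sample[j] - 1L)
      pre <- pre[pre >= 1L]
      base <- rowMeans(r[, pre, drop = FALSE])
      acc <- acc + (r[, blk, drop = FALSE] - base)
    }
    acc / length(rows)
  }

  blank_prof <- NULL
  if (subtract_blank) {
    rows <- which(trials$stimulus == blank_stimulus & trials$valid)
    if (length(rows) == 0) {
      xmv1_stop("subtract_blank requires at least one valid blank trial",
                "xmv1_no_blank")
    }
    blank_prof <- trial_mean(rows)
  }

  profiles <- list(); n_used <- integer(0); missing <- logical(0)
  for (s in stimuli) {
    rows <- which(trials$stimulus == s & trials$valid)
    if (length(rows) == 0) {
      profiles[[s]] <- NULL
      n_used[s] <- 0L
      missing[s] <- TRUE
      next
    }
    p <- trial_mean(rows)
    if (subtract_blank) p <- p - blank_prof
    profiles[[s]] <- p
    n_used[s] <- length(rows)
    missing[s] <- FALSE
  }
  structure(list(profiles = profiles, n_trials_used = n_used,
                 missing = missing, frame_rate = frame_rate,
                 baseline_window = baseline_window,
                 stim_onset = attr(trials, "stim_onset"),
                 blank_stimulus = blank_stimulus),
            class = "ResponseProfiles")
}

#' Concatenate per-stimulus profiles into a clustering matrix
#'
#' @param rp a `ResponseProfiles` object.
#' @param stimuli which stimuli to concatenate (default: all non-blank,
#'   non-missing, in their stored order).
#' @return neurons x (stimuli * block length) matrix; attributes `stimuli`
#'   and `n_block` describe the segmentation.
#' @export
profiles_matrix <- function(rp, stimuli = NULL) {
  stopifnot(inherits(rp, "ResponseProfiles"))
  if (is.null(stimuli)) {
    stimuli <- setdiff(names(rp$profiles)[!rp$missing[names(rp$profiles)]],
                       rp$blank_stimulus)
  }
  mats <- rp$profiles[stimuli]
  out <- do.call(cbind, mats)
  structure(out, stimuli = stimuli, n_block = ncol(mats[[1]]),
            frame_rate = rp$frame_rate, stim_onset = rp$stim_onset)
}

#' One-call preprocessing pipeline
#'
#' Neuropil subtraction, baseline estimation, dF/F, deconvolution and
#' smoothing; ROIs flagged by the baseline step are excluded (rows dropped).
#'
#' @param traces a `RoiTraceSet`.
#' @param neuropil_weight,tau,smooth_window,gaussian_sigma stage parameters.
#' @return list with `r` (smoothed deconvolved rates), `f` (dF/F), `F_c0`,
#'   `excluded` (flagged ROI indices), `kept` (row indices kept),
#'   `frame_rate`.
#' @export
preprocess_traces <- function(traces, neuropil_weight = 0.7, tau = 2,
                              smooth_window = 0.190, gaussian_sigma = 1) {
  fr <- traces$frame_rate
  F_c <- subtract_neuropil(traces, neuropil_weight)
  bl <- estimate_baseline(F_c, fr, gaussian_sigma = gaussian_sigma)
  kept <- setdiff(seq_len(nrow(F_c)), bl$flagged)
  F_c <- F_c[kept, , drop = FALSE]
  bl_kept <- list(F_c0 = bl$F_c0[kept, , drop = FALSE],
                  block_index = bl$block_index)
  f <- dff(F_c, bl_kept)
  r <- smooth_traces(deconvolve(f, tau, fr), fr, smooth_window)
  list(r = r, f = f, F_c0 = bl_kept$F_c0, excluded = bl$flagged,
       kept = kept, frame_rate = fr)
}
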