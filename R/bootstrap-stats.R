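# Responder detection (Wilcoxon rank-sum vs blank trials at 1% with 1%
# masking of displayed fractions) and the two bespoke bootstraps: a
# 10,000-partition bootstrap for comparing cluster-distribution between two
# populations, and a label-shuffle bootstrap for supra-linearity of bimodal
# responses against trial-resolved linear predictions.

# Exact two-sided Mann-Whitney p-value for tie-free data, vectorised over
# neurons via pwilcox; mirrors stats::wilcox.test(exact = TRUE).
mann_whitney_exact_p <- function(W, n1, n2) {
  lo <- stats::pwilcox(W, n1, n2)
  hi <- stats::pwilcox(W - 1, n1, n2, lower.tail = FALSE)
  pmin(1, 2 * pmin(lo, hi))
}

#' Detect stimulus-responsive neurons against blank trials
#'
#' Two-sided Wilcoxon rank-sum test comparing the per-trial windowed response
#' scalars of stimulation trials against blank trials (both baseline
#' subtracted upstream). Direction is the sign of the median difference for
#' significant neurons. All-tied data yield p = 1 and "ns". An exact
#' tie-free fast path via `pwilcox` is used; ties fall back to
#' `stats::wilcox.test` (normal approximation with continuity correction).
#'
#' @param stim numeric vector (or neurons x trials matrix) of per-trial
#'   responses under stimulation.
#' @param blank matching vector/matrix for blank trials.
#' @param alpha significance threshold (default 0.01).
#' @return data.frame with columns neuron, p_value, direction
#'   ("excited"/"inhibited"/"ns").
#' @export
detect_responders <- function(stim, blank, alpha = 0.01) {
  if (is.null(dim(stim))) stim <- matrix(stim, nrow = 1L)
  if (is.null(dim(blank))) blank <- matrix(blank, nrow = 1L)
  stopifnot(nrow(stim) == nrow(blank))
  n1 <- ncol(stim); n2 <- ncol(blank)
  if (n1 < 3 || n2 < 3) xmv1_stop("need >= 3 trials per group",
                                  "xmv1_bad_argument")
  n <- nrow(stim)
  p <- numeric(n)
  for (i in seq_len(n)) {
    x <- stim[i, ]; y <- blank[i, ]
    if (length(unique(c(x, y))) == 1L) {
      p[i] <- 1
      next
    }
    if (anyDuplicated(c(x, y))) {
      p[i] <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    } else {
      r <- rank(c(x, y))
      W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
      p[i] <- mann_whitney_exact_p(W, n1, n2)
    }
  }
  med_diff <- apply(stim, 1L, stats::median) - apply(blank, 1L, stats::median)
  direction <- ifelse(p < alpha & med_diff > 0, "excited",
                      ifelse(p < alpha & med_diff < 0, "inhibited", "ns"))
  data.frame(neuron = seq_len(n), p_value = p, direction = direction,
             stringsAsFactors = FALSE)
}

#' Mask the chance-level fraction of responders
#'
#' By construction of the 1% detection threshold, on average 1% of truly
#' non-responding neurons are flagged; displayed fractions therefore mask the
#' first `mask_pct` percentage points: `displayed = max(raw - mask_pct, 0)`.
#'
#' @param calls a data.frame from [detect_responders()], or a numeric vector
#'   of raw percentages.
#' @param mask_pct percentage points to mask (default 1).
#' @return for numeric input, masked percentages; for calls, a data.frame
#'   with raw and displayed percentage per direction.
#' @export
masked_fraction <- function(calls, mask_pct = 1) {
  if (mask_pct < 0) xmv1_stop("mask_pct must be >= 0", "xmv1_bad_argument")
  if (is.numeric(calls)) return(pmax(calls - mask_pct, 0))
  n <- nrow(calls)
  raw <- 100 * c(excited = mean(calls$direction == "excited"),
                 inhibited = mean(calls$direction == "inhibited"))
  data.frame(direction = names(raw), raw_pct = as.numeric(raw),
             displayed_pct = pmax(as.numeric(raw) - mask_pct, 0),
             stringsAsFactors = FALSE)
}

#' Partition bootstrap for cluster-distribution differences
#'
#' Tests, per cluster, whether two populations have different fractions of
#' that cluster. The observed statistic is `fraction_A - fraction_B`; the
#' null distribution comes from random partitions of the pooled labels into
#' groups of sizes |A| and |B|. P-values are two-sided percentile with
#' add-one correction.
#'
#' @param labels_A,labels_B cluster labels (vectors, shared vocabulary).
#' @param n_partitions number of random partitions (default 10000).
#' @param seed RNG seed.
#' @param return_null keep the null matrix in the result.
#' @return data.frame of class `xmv1_bootstrap`: cluster, observed
#'   fractional difference, p_value; attributes `n_partitions`, `seed`
#'   (and `null` if requested).
#' @export
distribution_bootstrap <- function(labels_A, labels_B, n_partitions = 10000,
                                   seed = NULL, return_null = FALSE) {
  if (length(labels_A) == 0 || length(labels_B) == 0) {
    xmv1_stop("both groups must be non-empty", "xmv1_bad_argument")
  }
  if (n_partitions < 1) xmv1_stop("n_partitions must be >= 1",
                                  "xmv1_bad_argument")
  if (!is.null(seed)) set.seed(seed)
  lv <- sort(unique(c(labels_A, labels_B)))
  fA <- as.numeric(table(factor(labels_A, lv))) / length(labels_A)
  fB <- as.numeric(table(factor(labels_B, lv))) / length(labels_B)
  obs <- fA - fB
  pooled <- factor(c(labels_A, labels_B), lv)
  nA <- length(labels_A); n <- length(pooled)
  K <- length(lv)
  tot <- tabulate(pooled, K)
  null <- matrix(0, n_partitions, K)
  for (b in seq_len(n_partitions)) {
    cntA <- tabulate(pooled[sample.int(n, nA)], K)
    null[b, ] <- cntA / nA - (tot - cntA) / (n - nA)
  }
  p <- vapply(seq_len(K), function(k) {
    lo <- sum(null[, k] <= obs[k]) + 1
    hi <- sum(null[, k] >= obs[k]) + 1
    min(1, 2 * min(lo, hi) / (n_partitions + 1))
  }, numeric(1))
  out <- data.frame(cluster = lv, observed = obs, p_value = p,
                    stringsAsFactors = FALSE)
  attr(out, "n_partitions") <- n_partitions
  attr(out, "seed") <- seed
  if (return_null) attr(out, "null") <- null
  class(out) <- c("xmv1_bootstrap", "data.frame")
  out
}

#' Trial-resolved linear predictions for bimodal responses
#'
#' Builds pseudo-trials of the additive prediction by pairing one visual and
#' one auditory presentation at random (one-to-one, without replacement, up
#' to the smaller trial count) and summing their baseline-subtracted traces
#' samplewise.
#'
#' @param visual_trials trials x time matrix (or vector of per-trial
#'   scalars) of visual responses.
#' @param auditory_trials matching matrix/vector of auditory responses.
#' @param seed RNG seed for the pairing.
#' @return pseudo-trial matrix (min(n_v, n_a) rows).
#' @export
linear_prediction_trials <- function(visual_trials, auditory_trials,
                                     seed = NULL) {
  if (is.null(dim(visual_trials))) visual_trials <- cbind(visual_trials)
  if (is.null(dim(auditory_trials))) auditory_trials <- cbind(auditory_trials)
  nv <- nrow(visual_trials); na_ <- nrow(auditory_trials)
  if (nv < 1 || na_ < 1) xmv1_stop("need >= 1 trial per modality",
                                   "xmv1_bad_argument")
  if (!is.null(seed)) set.seed(seed)
  m <- min(nv, na_)
  iv <- sample.int(nv, m)
  ia <- sample.int(na_, m)
  visual_trials[iv, , drop = FALSE] + auditory_trials[ia, , drop = FALSE]
}

#' Label-shuffle bootstrap for supra-linear bimodal responses
#'
#' Observed statistic: difference between the mean windowed bimodal response
#' and the mean windowed linear prediction. The null distribution shuffles
#' the group labels of the pooled trials (the paper uses one million
#' shuffles; reduced counts are appropriate for testing). Two-sided
#' percentile p-value with add-one correction. Works equally on single-cell
#' trials and on cluster-mean pseudo-trials.
#'
#' @param bimodal_trials trials x time matrix (or per-trial scalars) of
#'   bimodal responses, baseline subtracted.
#' @param prediction_trials matching linear-prediction pseudo-trials (see
#'   [linear_prediction_trials()]).
#' @param n_shuffles number of label shuffles (default 10000; < 100 warns).
#' @param window response window `c(t0, t1)` in seconds from trace start
#'   (NULL = whole trace).
#' @param frame_rate sampling rate, required when `window` is given.
#' @param seed RNG seed.
#' @return list of class `BootstrapResult`: `observed_stat`, `p_value`,
#'   `null_samples`, `seed`.
#' @export
supralinearity_bootstrap <- function(bimodal_trials, prediction_trials,
                                     n_shuffles = 10000, window = NULL,
                                     frame_rate = NULL, seed = NULL) {
  if (is.null(dim(bimodal_trials))) bimodal_trials <- cbind(bimodal_trials)
  if (is.null(dim(prediction_trials))) prediction_trials <- cbind(prediction_trials)
  if (nrow(bimodal_trials) < 3 || nrow(prediction_trials) < 3) {
    xmv1_stop("need >= 3 trials per group", "xmv1_bad_argument")
  }
  if (n_shuffles < 100) warning("n_shuffles < 100: p-values will be coarse")
  if (!is.null(seed)) set.seed(seed)
  windowed <- function(m) {
    if (is.null(window)) return(rowMeans(m))
    if (is.null(frame_rate)) xmv1_stop("window requires frame_rate",
                                       "xmv1_bad_argument")
    cols <- max(1L, round(window[1] * frame_rate) + 1L):
      min(ncol(m), max(1L, round(window[2] * frame_rate)))
    rowMeans(m[, cols, drop = FALSE])
  }
  xb <- windowed(bimodal_trials)
  xp <- windowed(prediction_trials)
  obs <- mean(xb) - mean(xp)
  pooled <- c(xb, xp)
  n1 <- length(xb); n <- length(pooled); S <- sum(pooled)
  null <- vapply(seq_len(n_shuffles), function(b) {
    sb <- sum(pooled[sample.int(n, n1)])
    sb / n1 - (S - sb) / (n - n1)
  }, numeric(1))
  lo <- sum(null <= obs) + 1
  hi <- sum(null >= obs) + 1
  p <- min(1, 2 * min(lo, hi) / (n_shuffles + 1))
  structure(list(observed_stat = obs, p_value = p,
                 null_samples = n_shuffles, seed = seed),
            class = "BootstrapResult")
}

#' @export
print.BootstrapResult <- function(x, ...) {
  cat(sprintf("BootstrapResult: observed %.4g, p = %.4g (%d shuffles)\n",
              x$observed_stat, x$p_value, x$null_samples))
  invisible(x)
}
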