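# Fourier retinotopy: per-pixel phase and amplitude of the response at the
# stimulus frequency (0.1 Hz drifting bar), bidirectional combination that
# separates retinotopic phase from hemodynamic delay, and a V1 mask as the
# largest coherent retinotopic region.

#' Per-pixel Fourier phase map at the stimulus frequency
#'
#' Fits, per pixel, `x(t) ~ a + b*t + A*sin(wt) + B*cos(wt)` with
#' `w = 2*pi*stim_freq` (joint least squares, so the linear detrend cannot
#' leak into the stimulus bin) and reports amplitude `sqrt(A^2+B^2)` and
#' phase `atan2(B, A)`, i.e. the phase in the sin convention
#' `x = R*sin(wt + phi)`. This is single-bin band-pass extraction, the
#' limiting case of band-passing around the stimulus frequency.
#'
#' @param movie time x height x width array, or time x pixels matrix.
#' @param frame_rate acquisition rate (Hz).
#' @param stim_freq stimulus frequency (Hz, default 0.1); must be below the
#'   Nyquist frequency.
#' @param direction sweep direction tag (+1/-1), stored in the result.
#' @return object of class `PhaseMap`: `phase` (radians, wrapped to
#'   (-pi, pi]), `amplitude` (>= 0), `stim_freq`, `direction`; maps are
#'   height x width matrices when the input was an array.
#' @export
phase_map <- function(movie, frame_rate, stim_freq = 0.1, direction = NA) {
  dims <- dim(movie)
  if (length(dims) == 3L) {
    n_t <- dims[1]
    X <- matrix(movie, n_t)
    shape <- dims[2:3]
  } else {
    n_t <- nrow(movie)
    X <- movie
    shape <- NULL
  }
  if (stim_freq >= frame_rate / 2) {
    xmv1_stop("stim_freq must be below the Nyquist frequency",
              "xmv1_bad_argument")
  }
  if (n_t < 2 * frame_rate / stim_freq) {
    xmv1_stop("movie must cover at least 2 stimulus cycles",
              "xmv1_bad_argument")
  }
  t <- (seq_len(n_t) - 1) / frame_rate
  w <- 2 * pi * stim_freq
  Q <- cbind(1, t, sin(w * t), cos(w * t))
  coef <- solve(crossprod(Q), crossprod(Q, X))
  A <- coef[3, ]; B <- coef[4, ]
  amp <- sqrt(A^2 + B^2)
  ph <- atan2(B, A)
  if (!is.null(shape)) {
    amp <- matrix(amp, shape[1], shape[2])
    ph <- matrix(ph, shape[1], shape[2])
  }
  structure(list(phase = ph, amplitude = amp, stim_freq = stim_freq,
                 frame_rate = frame_rate, direction = direction),
            class = "PhaseMap")
}

#' Combine opposite-direction phase maps
#'
#' The retinotopic phase flips sign with the sweep direction while the
#' hemodynamic delay does not, so with `phi_fwd = phi + delta` and
#' `phi_rev = -phi + delta`: the circular half-difference recovers the
#' retinotopic phase `phi` and the circular half-sum the delay `delta`.
#' Exact modulo the inherent half-turn ambiguity (unique for
#' |phi|, |delta| < pi/2).
#'
#' @param map_fwd,map_rev `PhaseMap` objects with identical geometry and
#'   stimulus frequency.
#' @return list: `phase` (retinotopic, radians), `delay` (hemodynamic,
#'   radians), `amplitude` (mean of the two amplitude maps).
#' @export
combine_directions <- function(map_fwd, map_rev) {
  stopifnot(inherits(map_fwd, "PhaseMap"), inherits(map_rev, "PhaseMap"))
  if (!identical(dim(map_fwd$phase), dim(map_rev$phase))) {
    xmv1_stop("phase maps have mismatched shapes", "xmv1_shape_mismatch")
  }
  if (map_fwd$stim_freq != map_rev$stim_freq) {
    xmv1_stop("phase maps have different stimulus frequencies",
              "xmv1_bad_argument")
  }
  phase <- wrap_angle(map_fwd$phase - map_rev$phase) / 2
  delay <- wrap_angle(map_fwd$phase + map_rev$phase) / 2
  list(phase = phase, delay = delay,
       amplitude = (map_fwd$amplitude + map_rev$amplitude) / 2)
}

# 4-connected component labelling (iterative BFS), small images.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack) > 0) {
      px <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- (px - 1L) %% h + 1L
      j <- (px - 1L) %/% h + 1L
      nb <- c(if (i > 1) px - 1L, if (i < h) px + 1L,
              if (j > 1) px - h, if (j < w) px + h)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      stack <- c(stack, nb)
    }
  }
  lab
}

#' V1 mask from retinotopy
#'
#' Marks pixels as retinotopic when their response amplitude exceeds an
#' amplitude quantile AND their phase is locally smooth (maximal circular
#' phase difference with above-threshold 4-neighbours below `grad_cutoff`;
#' pixels with no above-threshold neighbour are excluded). The largest
#' 4-connected component of retinotopic pixels is returned as V1 — the V1
#' border is the limit between pixels displaying and not displaying
#' retinotopy.
#'
#' @param amplitude height x width amplitude map.
#' @param phase height x width phase map (radians).
#' @param amp_threshold_quantile amplitude quantile (default 0.75).
#' @param grad_cutoff circular phase-gradient cutoff in radians per pixel
#'   (default 0.5).
#' @return list: `mask` (logical V1 mask), `border` (logical edge-pixel
#'   mask), `retinotopic` (pre-component mask), `amp_threshold`.
#' @export
v1_mask <- function(amplitude, phase, amp_threshold_quantile = 0.75,
                    grad_cutoff = 0.5) {
  if (!identical(dim(amplitude), dim(phase))) {
    xmv1_stop("amplitude/phase shapes differ", "xmv1_shape_mismatch")
  }
  h <- nrow(amplitude); w <- ncol(amplitude)
  thr <- stats::quantile(amplitude, amp_threshold_quantile, names = FALSE)
  cand <- amplitude > thr
  smooth_ok <- matrix(FALSE, h, w)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!cand[i, j]) next
    diffs <- c()
    if (i > 1 && cand[i - 1, j]) diffs <- c(diffs, phase[i - 1, j])
    if (i < h && cand[i + 1, j]) diffs <- c(diffs, phase[i + 1, j])
    if (j > 1 && cand[i, j - 1]) diffs <- c(diffs, phase[i, j - 1])
    if (j < w && cand[i, j + 1]) diffs <- c(diffs, phase[i, j + 1])
    if (length(diffs) == 0) next
    smooth_ok[i, j] <- max(abs(wrap_angle(diffs - phase[i, j]))) < grad_cutoff
  }
  retino <- cand & smooth_ok
  if (!any(retino)) {
    warning("no retinotopic pixels found; returning empty mask")
    return(list(mask = retino, border = retino, retinotopic = retino,
                amp_threshold = thr))
  }
  lab <- label_components(retino)
  big <- which.max(tabulate(lab[lab > 0]))
  mask <- lab == big
  # border: mask pixels with a non-mask 4-neighbour (or at the image edge)
  pad <- rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
  core <- pad[2:(h + 1), 2:(w + 1)] & pad[1:h, 2:(w + 1)] &
    pad[3:(h + 2), 2:(w + 1)] & pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  list(mask = mask, border = mask & !core, retinotopic = retino,
       amp_threshold = thr)
}

#' Jaccard index of two masks
#' @param a,b logical matrices of identical shape.
#' @return intersection-over-union.
#' @export
mask_jaccard <- function(a, b) sum(a & b) / sum(a | b)
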