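# Pupil tracking and saccade-based trial filtering. The pupil is modelled as
# an axis-aligned ellipse (center x/y, radius, eccentricity); the per-trial
# saccade statistic is the maximal pairwise distance between pupil-center
# positions during the 2 s of stimulation, converted to degrees of visual
# angle via the arc length on a 1.65 mm-radius eye.

#' Render a synthetic eye image
#'
#' Dark elliptical pupil on a lighter iris, with a one-pixel anti-aliased rim
#' that gives the boundary-gradient term of the fitting objective something
#' to lock onto. Used as ground truth for testing the fitter.
#'
#' @param width,height image size in pixels.
#' @param cx,cy pupil center (pixels; x = column, y = row).
#' @param r pupil semi-major radius (pixels).
#' @param ecc eccentricity in `[0, 1)`; semi-minor axis (y) is
#'   `r * sqrt(1 - ecc^2)`.
#' @param inside,outside luminance of pupil and iris.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed.
#' @return height x width numeric matrix (row = y, column = x).
#' @export
make_pupil_image <- function(width = 100, height = 80, cx = 50, cy = 40,
                             r = 30, ecc = 0, inside = 0.2, outside = 0.8,
                             noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- r * sqrt(1 - ecc^2)
  X <- matrix(rep(seq_len(width), each = height), height)
  Y <- matrix(rep(seq_len(height), width), height)
  d <- sqrt(((X - cx) / r)^2 + ((Y - cy) / b)^2)
  # soft edge over ~1 px (in normalised radius units)
  edge <- 1 / r
  w <- pmin(1, pmax(0, (d - 1 + edge / 2) / edge))
  img <- matrix(inside + (outside - inside) * w, height, width)
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(length(img), sd = noise_sd),
                                        height)
  img
}

pupil_objective <- function(par, image, gx, gy, lambda, n_boundary) {
  cx <- par[1]; cy <- par[2]; r <- par[3]; ecc <- par[4]
  if (r <= 1 || ecc < 0 || ecc >= 1) return(-Inf)
  h <- nrow(image); w <- ncol(image)
  b <- r * sqrt(1 - ecc^2)
  X <- matrix(rep(seq_len(w), each = h), h)
  Y <- matrix(rep(seq_len(h), w), h)
  inside <- ((X - cx) / r)^2 + ((Y - cy) / b)^2 <= 1
  n_in <- sum(inside)
  if (n_in < 4 || n_in > length(image) - 4) return(-Inf)
  lum_term <- mean(image[!inside]) - mean(image[inside])

  th <- seq(0, 2 * pi, length.out = n_boundary + 1L)[-(n_boundary + 1L)]
  px <- cx + r * cos(th); py <- cy + b * sin(th)
  ok <- px >= 2 & px <= w - 1 & py >= 2 & py <= h - 1
  if (!any(ok)) return(lum_term)
  # outward normal of an axis-aligned ellipse at parameter theta
  nx <- cos(th) / r; ny <- sin(th) / b
  nn <- sqrt(nx^2 + ny^2); nx <- nx / nn; ny <- ny / nn
  interp <- function(G, x, y) {
    x0 <- floor(x); y0 <- floor(y); fx <- x - x0; fy <- y - y0
    G[cbind(y0, x0)] * (1 - fx) * (1 - fy) + G[cbind(y0, x0 + 1)] * fx * (1 - fy) +
      G[cbind(y0 + 1, x0)] * (1 - fx) * fy + G[cbind(y0 + 1, x0 + 1)] * fx * fy
  }
  grad_term <- mean(interp(gx, px[ok], py[ok]) * nx[ok] +
                    interp(gy, px[ok], py[ok]) * ny[ok])
  lum_term + lambda * grad_term
}

#' Fit the pupil ellipse on a grayscale image
#'
#' Maximises `J = (mean luminance outside - mean luminance inside) +
#' lambda * (mean outward normal luminance gradient along the boundary)` for
#' a dark pupil on a lighter iris, over the four parameters (center x,
#' center y, radius, eccentricity) of an axis-aligned ellipse, with a
#' derivative-free Nelder-Mead search started from `init`. A flat
#' (no-contrast) image returns `init` with a failure flag.
#'
#' @param image 2D grayscale matrix (row = y, column = x), finite values.
#' @param init starting parameters `c(cx, cy, r, ecc)`.
#' @param bounds optional list with `lower` and `upper` numeric vectors of
#'   length 4; the search is penalised outside them.
#' @param lambda weight of the boundary-gradient term (default 1).
#' @param n_boundary number of boundary sample points (default 72).
#' @param maxit maximum Nelder-Mead iterations.
#' @return list: `par` (fitted `c(cx, cy, r, ecc)`), `value` (objective),
#'   `converged` logical.
#' @export
fit_pupil_ellipse <- function(image, init, bounds = NULL, lambda = 1,
                              n_boundary = 72, maxit = 2000) {
  image <- as.matrix(image)
  if (!all(is.finite(image))) xmv1_stop("image must be finite",
                                        "xmv1_bad_argument")
  if (stats::sd(image) == 0) {
    return(list(par = init, value = NA_real_, converged = FALSE))
  }
  h <- nrow(image); w <- ncol(image)
  # central-difference luminance gradients
  gx <- (image[, c(2:w, w)] - image[, c(1, 1:(w - 1))]) / 2
  gy <- (image[c(2:h, h), ] - image[c(1, 1:(h - 1)), ]) / 2
  neg_obj <- function(par) {
    if (!is.null(bounds) &&
        (any(par < bounds$lower) || any(par > bounds$upper))) {
      return(1e6 + sum(pmax(0, bounds$lower - par) + pmax(0, par - bounds$upper)))
    }
    v <- pupil_objective(par, image, gx, gy, lambda, n_boundary)
    if (!is.finite(v)) 1e6 else -v
  }
  # the inside/outside term is piecewise constant in the parameters (pixel
  # memberships change discretely), so a tight relative tolerance would spin
  # until maxit; 1e-8 is far below one pixel of precision
  fit <- stats::optim(init, neg_obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8))
  list(par = fit$par, value = -fit$value, converged = fit$convergence == 0)
}

#' Per-trial saccade amplitude
#'
#' Maximal pairwise Euclidean distance between pupil-center positions at any
#' two instants inside the window (brute force over all sample pairs, the
#' statistic's literal definition).
#'
#' @param track a `PupilTrack` (or data.frame with t, x_um, y_um).
#' @param window numeric `c(t0, t1)` in seconds.
#' @return maximal displacement in micrometers.
#' @export
saccade_amplitude <- function(track, window) {
  sel <- track$t >= window[1] & track$t <= window[2]
  if (sum(sel) < 2) xmv1_stop("need at least 2 samples in the window",
                              "xmv1_bad_argument")
  max(stats::dist(cbind(track$x_um[sel], track$y_um[sel])))
}

#' Micrometers on the eye to degrees of visual angle
#'
#' Arc-length (small-angle) convention: `deg = d / (R * 1000) * 180 / pi`
#' for eye radius `R` in mm. With the default 1.65 mm radius, 57.6 um maps
#' to 2.0 degrees.
#'
#' @param d_um displacement in micrometers (>= 0).
#' @param eye_radius_mm eye radius in millimeters (default 1.65).
#' @return degrees of visual angle.
#' @export
um_to_deg <- function(d_um, eye_radius_mm = 1.65) {
  if (eye_radius_mm <= 0) xmv1_stop("eye_radius_mm must be > 0",
                                    "xmv1_bad_argument")
  if (any(d_um < 0, na.rm = TRUE)) {
    xmv1_stop("d_um must be >= 0", "xmv1_bad_argument")
  }
  d_um / (eye_radius_mm * 1000) * 180 / pi
}

#' Degrees of visual angle to micrometers on the eye
#' @rdname um_to_deg
#' @param deg angle in degrees (>= 0).
#' @export
deg_to_um <- function(deg, eye_radius_mm = 1.65) {
  if (eye_radius_mm <= 0) xmv1_stop("eye_radius_mm must be > 0",
                                    "xmv1_bad_argument")
  deg * pi / 180 * eye_radius_mm * 1000
}

#' Saccade-based trial filtering
#'
#' Computes the saccade amplitude during the stimulation window of each trial
#' and discards trials whose gaze change exceeds the mouse visual acuity
#' (2 degrees by default). Dark-context trials are never filtered (filtering
#' applies to the lit/bimodal contexts only, where saccades drive V1
#' activity). Trials without tracking coverage in a filtered context are
#' marked invalid with reason `"no_tracking"`.
#'
#' @param trials trial table (see [make_trial_table()]).
#' @param track a `PupilTrack` covering the recording.
#' @param threshold_deg acuity threshold in degrees (default 2).
#' @param eye_radius_mm eye radius for the conversion (default 1.65).
#' @param stim_window saccade window relative to stimulus onset, seconds
#'   (default `c(0, 2)`, the stimulation period).
#' @param frame_rate imaging frame rate; default from `trials` attribute.
#' @return `trials` with added columns `max_displacement_um`,
#'   `max_displacement_deg`, `keep`, `reason`; `valid` is ANDed with `keep`.
#'   Attribute `summary`: kept fraction per context.
#' @export
filter_trials <- function(trials, track, threshold_deg = 2,
                          eye_radius_mm = 1.65, stim_window = c(0, 2),
                          frame_rate = attr(trials, "frame_rate")) {
  thr_um <- deg_to_um(threshold_deg, eye_radius_mm)
  n <- nrow(trials)
  disp <- rep(NA_real_, n)
  keep <- rep(TRUE, n)
  reason <- rep("", n)
  for (i in seq_len(n)) {
    t_on <- (trials$onset_sample[i] - 1) / frame_rate
    win <- t_on + stim_window
    sel <- track$t >= win[1] & track$t <= win[2]
    if (sum(sel) >= 2) {
      disp[i] <- saccade_amplitude(track, win)
    }
    if (trials$context[i] == "dark") next  # dark trials are never filtered
    if (sum(sel) < 2) {
      keep[i] <- FALSE
      reason[i] <- "no_tracking"
    } else if (disp[i] > thr_um) {
      keep[i] <- FALSE
      reason[i] <- "saccade"
    }
  }
  trials$max_displacement_um <- disp
  trials$max_displacement_deg <- um_to_deg(disp, eye_radius_mm)
  trials$keep <- keep
  trials$reason <- reason
  trials$valid <- trials$valid & keep
  kept_frac <- tapply(keep, trials$context, mean)
  attr(trials, "summary") <- data.frame(context = names(kept_frac),
                                        kept_fraction = as.numeric(kept_frac))
  trials
}
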