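# Small numerical helpers shared across modules.

#' Causal discrete convolution
#'
#' Convolves a signal with a causal kernel and returns the first
#' `length(x)` samples (no acausal leakage).
#'
#' @param x numeric vector.
#' @param k causal kernel sampled at the same rate as `x` (`k[1]` is lag 0).
#' @return numeric vector, same length as `x`.
#' @keywords internal
conv_causal <- function(x, k) {
  fft_conv_full(x, k)[seq_along(x)]
}

# Full linear convolution via zero-padded FFT (padded to a 2-3-5-smooth
# length; stats::convolve pads to n+m-1 which can be prime and pathologically
# slow for long traces).
fft_conv_full <- function(x, k) {
  L <- length(x) + length(k) - 1L
  N <- stats::nextn(L, c(2L, 3L, 5L))
  X <- stats::fft(c(x, numeric(N - length(x))))
  K <- stats::fft(c(k, numeric(N - length(k))))
  Re(stats::fft(X * K, inverse = TRUE))[seq_len(L)] / N
}

#' Same-length centered convolution with an odd kernel
#' @keywords internal
conv_same <- function(x, k) {
  stopifnot(length(k) %% 2L == 1L)
  r <- (length(k) - 1L) / 2L
  n <- length(x)
  fft_conv_full(x, k)[(r + 1L):(r + n)]
}

#' Gaussian smoothing of each matrix row
#'
#' Truncated-Gaussian FIR filter (radius 3 sigma) with edge renormalisation so
#' that constants are preserved everywhere, including at the trace edges.
#'
#' @param x numeric matrix (signals in rows) or vector.
#' @param sigma_samples standard deviation of the kernel, in samples.
#' @return object of the same shape as `x`.
#' @keywords internal
gaussian_smooth_rows <- function(x, sigma_samples) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  if (sigma_samples <= 0) return(if (vec) drop(x) else x)
  r <- max(1L, ceiling(3 * sigma_samples))
  k <- stats::dnorm(seq(-r, r), sd = sigma_samples)
  k <- k / sum(k)
  denom <- conv_same(rep(1, ncol(x)), k)
  out <- t(apply(x, 1L, function(row) conv_same(row, k) / denom))
  if (vec) drop(out) else out
}

#' Centered moving average with truncated edges
#'
#' Window of `w` samples; for even `w` the window extends one sample further to
#' the right. Edges use whatever part of the window falls inside the trace.
#'
#' @keywords internal
moving_average_rows <- function(x, w) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  w <- as.integer(w)
  if (w <= 1L) return(if (vec) drop(x) else x)
  n <- ncol(x)
  left <- (w - 1L) %/% 2L
  right <- w %/% 2L
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  cs <- cbind(0, t(apply(x, 1L, cumsum)))
  out <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(x))
  if (vec) drop(out) else out
}

#' Wrap angles to (-pi, pi]
#' @keywords internal
wrap_angle <- function(x) atan2(sin(x), cos(x))

#' Stop with a classed condition
#' @keywords internal
xmv1_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "xmv1_error")))
}
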