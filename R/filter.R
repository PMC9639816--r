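# Butterworth band-pass denoising.
#
# sEMG energy lives in roughly 10-500 Hz; the pipeline denoises with a
# fourth-order Butterworth band-pass applied zero-phase (forward-backward).
# No signal-processing package is available in this environment, so the
# design is done from first principles: analog low-pass prototype poles,
# low-pass-to-band-pass transform, bilinear transform with pre-warping.
# Coefficients agree with scipy.signal.butter to ~1e-10 (see tests).

# polynomial coefficients (descending powers) from roots, complex-safe
.poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0i) - c(0i, p * ri)
  p
}

#' Design a digital Butterworth band-pass filter
#'
#' @param order analog prototype order (the digital band-pass has `2*order`
#'   poles); the pipeline default is 4.
#' @param low,high pass-band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param fs sampling rate in Hz.
#' @return list with numerator `b` and denominator `a` coefficients
#'   (length `2*order + 1`, `a[1] == 1`).
#' @export
butter_bandpass <- function(order = 4L, low = 10, high = 500, fs = 2000) {
  if (!is_count(order)) stopf("order must be a positive integer")
  if (!(low > 0 && high > low)) stopf("need 0 < low < high")
  if (high >= fs / 2) stopf("high edge %g Hz is at/above Nyquist (%g Hz)",
                            high, fs / 2)
  n <- as.integer(order)
  # analog low-pass prototype: poles on the unit circle, left half-plane
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # pre-warped band edges for the bilinear transform
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # low-pass -> band-pass: each prototype pole maps to a conjugate pair
  s <- proto * bw / 2
  poles <- c(s + sqrt(s^2 - w0^2), s - sqrt(s^2 - w0^2))
  gain <- bw^n                                 # n zeros at s = 0
  # bilinear transform z = (fs2 + s) / (fs2 - s)
  zp <- (fs2 + poles) / (fs2 - poles)
  zz <- c(rep(1 + 0i, n), rep(-1 + 0i, n))     # s=0 zeros -> z=1; excess -> z=-1
  kd <- gain * Re(fs2^n / prod(fs2 - poles))
  b <- Re(.poly_from_roots(zz)) * kd
  a <- Re(.poly_from_roots(zp))
  list(b = b / a[1L], a = a / a[1L])
}

# direct-form IIR filter, zero initial conditions, via stats::filter
# (C-level MA convolution + AR recursion)
.iir_filter <- function(x, b, a) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1L), x)
  ma <- stats::filter(xp, b, method = "convolution", sides = 1L)
  ma <- as.numeric(ma)[nb:length(xp)]
  if (length(a) > 1L)
    ma <- as.numeric(stats::filter(ma, -a[-1L], method = "recursive"))
  ma
}

# zero-phase filtering with odd (antisymmetric) edge extension; the long
# padding lets the zero-initial-condition transient die out before the data
.filtfilt <- function(x, b, a, padlen) {
  L <- length(x)
  padlen <- min(padlen, L - 1L)
  head_ext <- 2 * x[1L] - x[(padlen + 1L):2L]
  tail_ext <- 2 * x[L] - x[(L - 1L):(L - padlen)]
  ext <- c(head_ext, x, tail_ext)
  y <- .iir_filter(ext, b, a)
  y <- rev(.iir_filter(rev(y), b, a))
  y[(padlen + 1L):(padlen + L)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters each electrode channel independently with a Butterworth band-pass
#' of the given order, applied forward and backward (zero phase, squared
#' magnitude response).  Output length equals input length.
#'
#' @param x numeric vector or `T x E` matrix of samples.
#' @param fs sampling rate in Hz.
#' @param low,high pass-band edges in Hz (defaults 10 and 500, the sEMG
#'   energy band).
#' @param order Butterworth prototype order (default 4).
#' @return filtered data with the same shape as `x`.
#' @export
bandpass_filter <- function(x, fs, low = 10, high = 500, order = 4L) {
  coefs <- butter_bandpass(order, low, high, fs)
  nf <- length(coefs$a)
  warmup <- 3L * nf          # scipy-style minimum padding
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1L) else as.matrix(x)
  if (nrow(xm) <= warmup)
    stopf("signal too short to band-pass filter: %d samples <= warm-up %d",
          nrow(xm), warmup)
  # generous padding so the zero-IC start-up transient (time constant
  # ~ fs/low samples for the high-pass corner) has decayed inside the pad
  padlen <- min(nrow(xm) - 1L, max(warmup, as.integer(ceiling(fs / low)) * 2L))
  out <- xm
  for (j in seq_len(ncol(xm)))
    out[, j] <- .filtfilt(xm[, j], coefs$b, coefs$a, padlen)
  if (vec) drop(out) else out
}

#' Analytic Butterworth band-pass magnitude response
#'
#' Magnitude of the digital filter's frequency response at `f` Hz, evaluated
#' from the transfer function polynomials.  For the zero-phase pipeline the
#' effective gain is this value squared.
#'
#' @inheritParams bandpass_filter
#' @param f frequency (Hz) at which to evaluate, vectorised.
#' @return magnitude response |H(f)| of the single-pass filter.
#' @export
butter_gain <- function(f, fs, low = 10, high = 500, order = 4L) {
  coefs <- butter_bandpass(order, low, high, fs)
  vapply(f, function(fi) {
    z <- exp(-2i * pi * fi / fs)
    zp <- z^(seq_along(coefs$b) - 1L)
    Mod(sum(coefs$b * zp) / sum(coefs$a * zp))
  }, numeric(1))
}
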