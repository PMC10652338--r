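# Low-pass filters used by the nanopore generator and analysis path.
#
# Two families are provided on purpose:
#  * bessel4_lowpass(): a causal 4-pole Bessel, mimicking the acquisition
#    hardware (patch-clamp amplifier Bessel filter). Applied forward-only so
#    event onsets acquire the realistic asymmetric rise of recorded traces.
#  * fft_lowpass(): a zero-phase magnitude-only filter applied in the
#    frequency domain (Gaussian response by default, Butterworth optional),
#    used for the additional analysis low-pass (default 5 kHz). Zero phase
#    keeps detected event centers unbiased; DC gain is exactly 1 so event
#    areas are preserved; the Gaussian kernel is positive so deep events do
#    not ring.

# 4th-order Bessel analog prototype: denominator s^4+10s^3+45s^2+105s+105,
# -3 dB at ~2.1139 rad/s. Discretized pole-pair-wise via bilinear transform.
.bessel4_poles <- function() {
  p <- polyroot(c(105, 105, 45, 10, 1))
  p[order(Im(p))]
}

.bessel4_w3db <- 2.113917675

#' Causal 4-pole Bessel low-pass filter
#'
#' Forward-only IIR filter with unit DC gain, emulating the acquisition-side
#' Bessel filter of a patch-clamp amplifier. If `corner_hz >= 0.49 * fs / 2 * 2`
#' (corner at or beyond ~0.49 of the sampling rate, i.e. at Nyquist where the
#' bilinear transform is singular) the input is returned unchanged: the
#' passband then covers the whole sampled band.
#'
#' @param x numeric vector of samples.
#' @param fs sampling rate, Hz.
#' @param corner_hz -3 dB corner frequency, Hz.
#' @return filtered numeric vector, same length as `x`.
#' @export
bessel4_lowpass <- function(x, fs, corner_hz) {
  stopifnot_scalar_pos(fs, "fs")
  stopifnot_scalar_pos(corner_hz, "corner_hz")
  if (corner_hz >= 0.49 * fs) {
    return(as.numeric(x))
  }
  # prewarped corner in bilinear units s <-> (1 - z^-1)/(1 + z^-1)
  wc <- tan(pi * corner_hz / fs)
  poles <- .bessel4_poles() * (wc / .bessel4_w3db)
  # conjugate pairs -> two biquad sections, each with analog form
  # a0 / (s^2 + a1 s + a0), a1 = -2 Re(p), a0 = |p|^2  (unit DC gain)
  pos <- poles[Im(poles) > 0]
  y <- as.numeric(x)
  for (p in pos) {
    a1 <- -2 * Re(p)
    a0 <- Mod(p)^2
    d0 <- 1 + a1 + a0
    b <- a0 * c(1, 2, 1) / d0        # numerator a0 (1 + z^-1)^2
    a <- c(2 * a0 - 2, 1 - a1 + a0) / d0  # denominator trailing coeffs
    # pad with the initial value so the filter starts at steady state
    pad <- rep(y[1L], 2L)
    u <- stats::filter(c(pad, y), b, method = "convolution", sides = 1)
    v <- stats::filter(u[-seq_along(pad)] - 0, -a, method = "recursive",
                       init = rep(y[1L], 2L))
    y <- as.numeric(v)
  }
  y
}

#' Zero-phase low-pass filter (frequency domain)
#'
#' Applies a magnitude-only low-pass response in the frequency domain (no
#' phase shift). DC gain is 1 and the gain at `corner_hz` is exactly
#' 1/sqrt(2). Two response families:
#' * `"gaussian"` (default): `H(f) = exp(-(ln 2 / 2) (f/fc)^2)`. Its impulse
#'   response is a positive Gaussian kernel, so deep rectangular events are
#'   smoothed without ringing sidelobes — the property event detection needs.
#' * `"butterworth"`: `H(f) = 1/sqrt(1 + (f/fc)^(2 order))`; sharper roll-off
#'   but with small undershoot around steep edges.
#' The signal is reflected at both ends before the FFT to suppress
#' wrap-around transients.
#'
#' @param x numeric vector of samples.
#' @param fs sampling rate, Hz.
#' @param corner_hz -3 dB corner frequency, Hz.
#' @param family `"gaussian"` or `"butterworth"`.
#' @param order Butterworth order (default 4; ignored for Gaussian).
#' @return filtered numeric vector, same length as `x`.
#' @export
fft_lowpass <- function(x, fs, corner_hz, family = c("gaussian", "butterworth"),
                        order = 4L) {
  family <- match.arg(family)
  stopifnot_scalar_pos(fs, "fs")
  stopifnot_scalar_pos(corner_hz, "corner_hz")
  n <- length(x)
  if (n < 2L) return(as.numeric(x))
  if (corner_hz >= fs / 2) return(as.numeric(x))
  pad <- min(n, max(16L, ceiling(2 * fs / corner_hz)))
  xe <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1L):n]))
  m <- stats::nextn(length(xe), factors = c(2, 3, 5))
  xe <- c(xe, rep(xe[length(xe)], m - length(xe)))
  f <- (seq_len(m) - 1L) / m * fs
  f <- pmin(f, fs - f)  # two-sided frequency axis
  h <- .lowpass_response(f, corner_hz, family, order)
  y <- Re(stats::fft(stats::fft(xe) * h, inverse = TRUE)) / m
  y[pad + seq_len(n)]
}

.lowpass_response <- function(f, corner_hz, family, order) {
  if (family == "gaussian") {
    exp(-(log(2) / 2) * (f / corner_hz)^2)
  } else {
    1 / sqrt(1 + (f / corner_hz)^(2 * order))
  }
}

#' RMS noise gain of the zero-phase analysis filter
#'
#' For white input noise of standard deviation `sd`, the filtered standard
#' deviation is approximately `sd * lowpass_noise_gain(fs, corner_hz)`.
#' Computed numerically from the magnitude response; used as an independent
#' oracle for baseline-noise estimates.
#'
#' @inheritParams fft_lowpass
#' @return scalar gain in (0, 1].
#' @export
lowpass_noise_gain <- function(fs, corner_hz, family = c("gaussian", "butterworth"),
                               order = 4L) {
  family <- match.arg(family)
  if (corner_hz >= fs / 2) return(1)
  f <- seq(0, fs / 2, length.out = 20001L)
  sqrt(mean(.lowpass_response(f, corner_hz, family, order)^2))
}
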