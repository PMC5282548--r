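#' Filter a current trace through a frequency-dependent medium
#'
#' Computes the extracellular potential of a point current source at
#' distance `r` in an infinite homogeneous medium whose conductivity
#' follows a (possibly frequency-dependent) magnitude profile, enforcing
#' causality through the minimum-phase (Bode) relation:
#'
#' \deqn{\phi(t) = \mathrm{Re}\,\mathrm{iFFT}\!\left[
#'   \frac{e^{-j\theta(f)} I(f)}{4\pi |\tilde\sigma(f)| r}\right]}
#'
#' The profile magnitude is resampled onto the FFT grid of the (internally
#' zero-padded) trace by linear interpolation, held constant beyond the
#' profile's frequency range, and the minimum-phase `theta` is recomputed
#' on that grid so the filter is causal at the working resolution.  For a
#' constant profile the result equals `I(t) / (4*pi*sigma*r)` samplewise.
#'
#' @param i_t Current trace in amperes.
#' @param sample_rate Sampling rate in Hz.
#' @param distance Source-electrode distance in metres (> 0).
#' @param profile A [conductivity_profile()] (its magnitude is used; the
#'   phase is re-derived on the working grid).
#' @param pad_factor Zero-padding factor (default 2) suppressing circular
#'   wrap-around.
#' @return Potential trace in volts, same length as `i_t`.
#' @export
filter_potential <- function(i_t, sample_rate, distance, profile,
                             pad_factor = 2) {
  stopifnot(is.numeric(i_t), length(i_t) >= 2L, sample_rate > 0,
            inherits(profile, "conductivity_profile"), pad_factor >= 1)
  if (distance <= 0) stop("'distance' must be positive")
  n <- length(i_t)
  m <- stats::nextn(ceiling(pad_factor * n), 2)
  f_one <- (0:(m / 2)) * sample_rate / m
  mag <- stats::approx(profile$f, profile$magnitude, xout = f_one,
                       rule = 2)$y
  theta <- min_phase_theta(mag)
  h_one <- exp(-1i * theta) / (4 * pi * mag * distance)
  h_full <- c(h_one, Conj(rev(h_one[2:(m / 2)])))
  h_full[1] <- Re(h_full[1])
  h_full[m / 2 + 1] <- Re(h_full[m / 2 + 1])
  x <- c(i_t, rep(0, m - n))
  y <- Re(stats::fft(stats::fft(x) * h_full, inverse = TRUE)) / m
  y[seq_len(n)]
}

#' Steady-state gain of the medium filter at one frequency
#'
#' Filters a pure sinusoid of unit current amplitude through
#' [filter_potential()], discards the initial transient, and measures the
#' output amplitude by exact phasor projection.  For a causal
#' minimum-phase medium this equals `1 / (4*pi*|sigma(f)|*r)`.
#'
#' @param f Sinusoid frequency, Hz.
#' @param profile A [conductivity_profile()].
#' @param distance Source-electrode distance, m.
#' @param sample_rate Sampling rate, Hz.
#' @param duration Trace duration, s (should hold many cycles of `f`).
#' @param discard Fraction of the output discarded at each measurement end
#'   (default 0.1 at the start) before amplitude measurement.
#' @return Output amplitude in volts per ampere of input.
#' @export
sinusoid_gain <- function(f, profile, distance, sample_rate,
                          duration = 4, discard = 0.1) {
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  y <- filter_potential(cos(2 * pi * f * t), sample_rate, distance, profile)
  keep <- seq.int(floor(discard * n) + 1L, n)
  extract_phasor(y[keep], f, sample_rate)$amplitude
}
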