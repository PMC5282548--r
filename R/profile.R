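#' Complex conductivity profile on a uniform frequency grid
#'
#' Container for a (possibly complex) conductivity spectrum
#' `sigma(f) = |sigma(f)| * exp(1i*theta(f))` sampled on a uniform grid
#' from 0 to the Nyquist frequency.  The derived real and imaginary parts
#' are `sigma_R = |sigma| cos(theta)` and `sigma_I = |sigma| sin(theta)`;
#' the equivalent permittivity is `sigma_I / (2*pi*f)`.
#'
#' @param f Uniform frequency grid (Hz) starting at 0.
#' @param magnitude `|sigma(f)|` in S/m, strictly positive.
#' @param theta Phase in radians (`NULL` until filled by
#'   [minimum_phase()]); `theta[1]` (DC) must be 0.
#' @return Object of class `conductivity_profile`.
#' @export
conductivity_profile <- function(f, magnitude, theta = NULL) {
  stopifnot(is.numeric(f), length(f) >= 4L, f[1] == 0)
  df <- diff(f)
  if (max(abs(df - df[1])) > 1e-9 * df[1])
    stop("frequency grid must be uniform")
  if (length(magnitude) != length(f) || any(magnitude <= 0))
    stop("'magnitude' must be strictly positive on the whole grid")
  if (!is.null(theta)) {
    stopifnot(length(theta) == length(f))
    if (abs(theta[1]) > 1e-8) stop("theta at DC must be 0")
  }
  structure(list(f = f, magnitude = magnitude, theta = theta),
            class = "conductivity_profile")
}

#' @export
print.conductivity_profile <- function(x, ...) {
  cat("Conductivity profile: ", length(x$f), " points, 0-",
      max(x$f), " Hz, |sigma| in [", format(min(x$magnitude), digits = 4),
      ", ", format(max(x$magnitude), digits = 4), "] S/m, phase ",
      if (is.null(x$theta)) "not set" else "minimum-phase", "\n", sep = "")
  invisible(x)
}

#' @export
plot.conductivity_profile <- function(x, ...) {
  graphics::plot(x$f, x$magnitude, type = "l", log = "",
                 xlab = "frequency (Hz)", ylab = "|sigma| (S/m)", ...)
  invisible(x)
}

#' Real and imaginary conductivity of a profile
#'
#' @param profile A `conductivity_profile` with phase set.
#' @return Data frame with `f`, `sigma_r`, `sigma_i`, `permittivity`.
#' @export
profile_components <- function(profile) {
  stopifnot(inherits(profile, "conductivity_profile"),
            !is.null(profile$theta))
  sr <- profile$magnitude * cos(profile$theta)
  si <- profile$magnitude * sin(profile$theta)
  eps <- c(NA, si[-1] / (2 * pi * profile$f[-1]))
  data.frame(f = profile$f, sigma_r = sr, sigma_i = si, permittivity = eps)
}

#' Build a conductivity magnitude profile
#'
#' Constructs `|sigma(f)|` on a uniform grid: either a constant, or a
#' linear ramp rising by `percent` percent between `band[1]` and `band[2]`
#' (default 5-500 Hz).  Below the band the magnitude is held at `base`;
#' above the band it either saturates at the band-top value
#' (`above = "saturate"`) or continues with the same linear slope
#' (`above = "continue"`).
#'
#' @param kind `"constant"` or `"ramp"`.
#' @param base Base conductivity in S/m (the value at and below `band[1]`).
#' @param percent Ramp size in percent (e.g. 25 or 50); 0 gives a constant.
#' @param band Two frequencies (Hz) delimiting the ramp.
#' @param above `"saturate"` or `"continue"`.
#' @param f_max Nyquist frequency of the grid (Hz).
#' @param n Number of grid points from 0 to `f_max`.
#' @return A [conductivity_profile()] (magnitude only; apply
#'   [minimum_phase()] to obtain the causal phase).
#' @export
build_profile <- function(kind = c("constant", "ramp"), base = 0.48,
                          percent = 50, band = c(5, 500),
                          above = c("saturate", "continue"),
                          f_max = 1000, n = 2^12 + 1) {
  kind <- match.arg(kind)
  above <- match.arg(above)
  stopifnot(base > 0, percent >= 0, band[1] > 0, band[2] > band[1],
            band[2] <= f_max)
  f <- seq(0, f_max, length.out = n)
  if (kind == "constant" || percent == 0) {
    mag <- rep(base, n)
  } else {
    slope <- base * (percent / 100) / (band[2] - band[1])
    mag <- base + slope * pmax(0, pmin(f, band[2]) - band[1])
    if (above == "continue")
      mag <- ifelse(f > band[2],
                    base * (1 + percent / 100) + slope * (f - band[2]),
                    mag)
  }
  conductivity_profile(f, mag)
}

## minimum-phase phase of a one-sided magnitude spectrum via the real
## cepstrum: log|H| on the full (Hermitian) grid, causal folding of its
## cepstrum, imaginary part of the rebuilt log-spectrum.
min_phase_theta <- function(magnitude) {
  nf <- length(magnitude)            # one-sided points = N/2 + 1
  n <- 2L * (nf - 1L)                # full FFT length
  logmag <- log(magnitude)
  full <- c(logmag, rev(logmag[2:(nf - 1L)]))
  ceps <- Re(stats::fft(full, inverse = TRUE)) / n
  fold <- c(1, rep(2, nf - 2L), 1, rep(0, n - nf))
  theta <- Im(stats::fft(ceps * fold))[seq_len(nf)]
  theta[1] <- 0
  theta
}

#' Fill in the minimum-phase spectrum of a conductivity profile
#'
#' Computes the phase `theta(f)` implied by the magnitude `|sigma(f)|`
#' under the assumption that the medium is causal and minimum-phase — the
#' Bode magnitude-phase relation, evaluated with the real-cepstrum method:
#' the cepstrum of `log|sigma|` is folded onto non-negative quefrencies and
#' transformed back; the imaginary part of the rebuilt log-spectrum is the
#' minimum-phase `theta`.  A constant magnitude yields `theta == 0`; a
#' magnitude growing as `f^p` yields `theta ~ p*pi/2` in the band interior.
#'
#' @param profile A [conductivity_profile()] (magnitude only or with a
#'   phase to be recomputed).
#' @return The profile with `theta` filled in (`theta[1] = 0` at DC).
#' @export
minimum_phase <- function(profile) {
  stopifnot(inherits(profile, "conductivity_profile"))
  profile$theta <- min_phase_theta(profile$magnitude)
  profile
}
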