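#' Virtual recording electrode positions along the apical axis
#'
#' Default setup: three points 50 um lateral to the dendritic axis at
#' heights 0, 500 and 1000 um relative to the soma.
#'
#' @param heights Electrode heights relative to the soma, m.
#' @param lateral Lateral offset from the dendritic axis, m.
#' @return n x 3 matrix of electrode positions.
#' @export
electrode_setup <- function(heights = c(0, 500, 1000) * 1e-6,
                            lateral = 50e-6) {
  cbind(x = lateral, y = 0, z = heights)
}

#' Extracellular potentials of a current source set
#'
#' Superposes [filter_potential()] over all sources: each compartment
#' current is filtered through the (possibly frequency-dependent,
#' minimum-phase causal) medium at its own source-electrode distance and
#' the contributions are summed per electrode.  With a constant profile
#' this reduces samplewise to the homogeneous point-source superposition.
#'
#' @param sources A `current_source_set`.
#' @param electrodes n x 3 matrix of electrode positions, m (e.g.
#'   [electrode_setup()]).
#' @param profile A [conductivity_profile()].
#' @return Matrix (samples x electrodes) of potentials, volts.
#' @export
extracellular_response <- function(sources, electrodes, profile) {
  stopifnot(inherits(sources, "current_source_set"))
  electrodes <- as_points(electrodes)
  n_e <- nrow(electrodes)
  n_s <- nrow(sources$positions)
  out <- matrix(0, nrow(sources$currents), n_e)
  for (e in seq_len(n_e)) {
    for (s in seq_len(n_s)) {
      r <- sqrt(sum((electrodes[e, ] - sources$positions[s, ])^2))
      if (r == 0) stop("electrode coincides with a source")
      out[, e] <- out[, e] +
        filter_potential(sources$currents[, s], sources$sample_rate, r,
                         profile)
    }
  }
  out
}

#' Peak-to-peak amplitude
#'
#' @param trace Numeric vector.
#' @return `max(trace) - min(trace)`.
#' @export
peak_to_peak <- function(trace) {
  stopifnot(length(trace) >= 1L)
  max(trace) - min(trace)
}

#' One-sided periodogram power spectral density
#'
#' Mean-removed periodogram normalized so that the integral of the PSD
#' over frequency equals the signal variance (Parseval):
#' `sum(psd) * fs/n = mean((x - mean(x))^2)`.
#'
#' @param trace Numeric vector (length >= 2).
#' @param sample_rate Sampling rate, Hz.
#' @return Data frame with columns `f` (Hz, excluding DC) and `psd`
#'   (units^2 / Hz).
#' @export
psd_trace <- function(trace, sample_rate) {
  stopifnot(length(trace) >= 2L, sample_rate > 0)
  n <- length(trace)
  x <- trace - mean(trace)
  p <- Mod(stats::fft(x))^2 / (n * sample_rate)
  half <- floor(n / 2)
  k <- seq_len(half)
  psd <- 2 * p[k + 1]
  if (n %% 2 == 0) psd[half] <- p[half + 1]  # Nyquist bin is not doubled
  data.frame(f = k * sample_rate / n, psd = psd)
}
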