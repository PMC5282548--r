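#' Sinusoidal current injection protocol
#'
#' Describes the stimulation protocol: which frequencies and peak current
#' amplitudes are injected, at which source heights above the nearest
#' electrode, and how each condition is sampled.  The defaults reproduce
#' the standard slice protocol: five frequencies (5, 60, 100, 300, 500 Hz),
#' three amplitudes (175, 300, 500 pA), two source heights (100, 125 um),
#' 50 sweeps of 2.5 s at 20 kHz.
#'
#' A full-size protocol produces very large sessions (60 electrodes x 50
#' sweeps x 50000 samples per condition); analyses in the vignette and the
#' test-suite use reduced `sweeps`, `sweep_duration` and `sample_rate`,
#' which leave the estimation problem unchanged.
#'
#' @param frequencies Stimulation frequencies in Hz.
#' @param amplitudes Peak current amplitudes in amperes.
#' @param source_distances Source heights above the nearest electrode, m.
#' @param sweeps Sweeps per condition.
#' @param sweep_duration Sweep length in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param alpha Phase of the injected current in radians.  In a real rig
#'   this is unknown and must be recovered from saline fits; the generator
#'   stores it as ground truth.
#' @return Object of class `injection_protocol`.
#' @export
injection_protocol <- function(frequencies = c(5, 60, 100, 300, 500),
                               amplitudes = c(175, 300, 500) * 1e-12,
                               source_distances = c(100, 125) * 1e-6,
                               sweeps = 50L,
                               sweep_duration = 2.5,
                               sample_rate = 20000,
                               alpha = 0.2) {
  stopifnot(all(frequencies > 0), all(amplitudes > 0),
            all(source_distances > 0), sweeps >= 1L,
            sweep_duration > 0, sample_rate > 0,
            all(frequencies < sample_rate / 2),
            is.numeric(alpha), length(alpha) == 1L)
  structure(list(frequencies = frequencies, amplitudes = amplitudes,
                 source_distances = source_distances,
                 sweeps = as.integer(sweeps),
                 sweep_duration = sweep_duration,
                 sample_rate = sample_rate, alpha = alpha),
            class = "injection_protocol")
}

#' @export
print.injection_protocol <- function(x, ...) {
  cat("Injection protocol:\n",
      " frequencies:", paste(x$frequencies, collapse = ", "), "Hz\n",
      " amplitudes:", paste(x$amplitudes * 1e12, collapse = ", "), "pA\n",
      " source heights:", paste(x$source_distances * 1e6, collapse = ", "),
      "um\n",
      " sweeps:", x$sweeps, "x", x$sweep_duration, "s @",
      x$sample_rate, "Hz\n")
  invisible(x)
}

#' Electrode polarization model
#'
#' Electrode polarization (EP) arises at the electrolyte-metal interface of
#' the current-carrying ground electrode and appears in series with the
#' medium impedance.  Two parameterizations are supported:
#'
#' * `"cpe"`: a constant-phase element, `Z_EP(w) = K * (j*w)^(-n)` with
#'   `w = 2*pi*f`.  The default (`K = 5e4` Ohm s^-n, `n = 0.8`) gives
#'   an EP magnitude comparable to the medium impedance at 5 Hz that decays
#'   towards 500 Hz, producing the rising apparent-conductivity trend seen
#'   in uncorrected saline measurements.
#' * `"table"`: explicit per-frequency values `R_EP + j*X_EP` (Ohm).
#' * `"none"`: zero EP at all frequencies.
#'
#' @param kind One of `"cpe"`, `"table"`, `"none"`.
#' @param K CPE magnitude coefficient (Ohm (rad/s)^n).
#' @param n CPE exponent, dimensionless, typically 0.2-0.9.
#' @param table For `kind = "table"`: data frame with columns `frequency`,
#'   `R_ep`, `X_ep`.
#' @return Object of class `ep_model`.
#' @export
ep_model <- function(kind = c("cpe", "table", "none"), K = 5e4, n = 0.8,
                     table = NULL) {
  kind <- match.arg(kind)
  if (kind == "cpe") stopifnot(K >= 0, n > 0, n < 1)
  if (kind == "table") {
    stopifnot(is.data.frame(table),
              all(c("frequency", "R_ep", "X_ep") %in% names(table)))
  }
  structure(list(kind = kind, K = K, n = n, table = table),
            class = "ep_model")
}

#' @export
print.ep_model <- function(x, ...) {
  if (x$kind == "cpe")
    cat("EP model: constant-phase element, K =", x$K, "Ohm s^-n, n =",
        x$n, "\n")
  else if (x$kind == "table")
    cat("EP model: tabulated at", nrow(x$table), "frequencies\n")
  else cat("EP model: none\n")
  invisible(x)
}

#' Evaluate an electrode-polarization impedance at given frequencies
#'
#' @param ep An [ep_model()].
#' @param f Frequencies in Hz.
#' @return Complex impedance(s) in Ohm.
#' @export
ep_impedance <- function(ep, f) {
  stopifnot(inherits(ep, "ep_model"), all(f > 0))
  switch(ep$kind,
    none = rep(0 + 0i, length(f)),
    cpe = ep$K * (1i * 2 * pi * f)^(-ep$n),
    table = {
      i <- match(f, ep$table$frequency)
      if (anyNA(i))
        stop("no tabulated EP value at frequency ",
             paste(f[is.na(i)], collapse = ", "), " Hz")
      complex(real = ep$table$R_ep[i], imaginary = ep$table$X_ep[i])
    })
}
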