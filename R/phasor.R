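#' Average repeated sweeps
#'
#' Pointwise mean across sweeps.  Accepts a matrix (samples x sweeps) or a
#' list of equal-length numeric vectors.
#'
#' @param traces Matrix with one column per sweep, or list of vectors.
#' @return Numeric vector, the averaged trace.
#' @export
average_sweeps <- function(traces) {
  if (is.list(traces)) {
    n <- lengths(traces)
    if (length(unique(n)) != 1L) stop("ragged sweep lengths")
    traces <- do.call(cbind, traces)
  }
  if (is.null(dim(traces))) return(traces)
  rowMeans(traces)
}

#' Extract the complex phasor of a trace at one frequency
#'
#' Returns the amplitude `phi0` and phase `beta` of the component of
#' `trace` at exactly `f_stim`, under the convention
#' `trace(t) = phi0 * cos(2*pi*f_stim*t + beta) + rest`.
#'
#' Two estimators are available.  `"projection"` (default) solves the
#' two-parameter least-squares fit of `a*cos + b*sin` at `f_stim` via the
#' exact normal equations; it returns a pure sinusoid's amplitude exactly
#' even when the window does not hold an integer number of cycles (e.g.
#' 5 Hz in a 2.5 s sweep is 12.5 cycles).  `"bin"` reads the nearest FFT
#' bin, which is exact only for integer cycle counts and is provided for
#' comparison with bin-lookup analyses.
#'
#' @param trace Numeric vector (volts), sampled at `sample_rate`.
#' @param f_stim Stimulation frequency in Hz, below Nyquist.
#' @param sample_rate Sampling rate in Hz.
#' @param method `"projection"` or `"bin"`.
#' @return List with `amplitude` (>= 0), `phase` in (-pi, pi], `phasor`
#'   (complex `amplitude * exp(1i*phase)`), and `frequency`.
#' @export
extract_phasor <- function(trace, f_stim, sample_rate,
                           method = c("projection", "bin")) {
  method <- match.arg(method)
  stopifnot(is.numeric(trace), length(trace) >= 2L,
            f_stim > 0, sample_rate > 0)
  if (f_stim >= sample_rate / 2)
    stop("'f_stim' must be below the Nyquist frequency")
  n <- length(trace)
  if (method == "projection") {
    t <- (seq_len(n) - 1) / sample_rate
    cw <- cos(2 * pi * f_stim * t)
    sw <- sin(2 * pi * f_stim * t)
    ## exact 2x2 normal equations for trace ~ a*cos + b*sin
    gcc <- sum(cw * cw); gss <- sum(sw * sw); gcs <- sum(cw * sw)
    bc <- sum(trace * cw); bs <- sum(trace * sw)
    det <- gcc * gss - gcs * gcs
    a <- (bc * gss - bs * gcs) / det
    b <- (bs * gcc - bc * gcs) / det
    z <- complex(real = a, imaginary = -b)
  } else {
    k <- round(f_stim * n / sample_rate)
    z <- 2 * stats::fft(trace)[k + 1] / n
  }
  list(amplitude = Mod(z), phase = Arg(z), phasor = z, frequency = f_stim)
}

#' Flag electrodes with strongly reduced responses
#'
#' An electrode is excluded when its response amplitude falls below
#' `threshold_fraction` times the median amplitude of its immediate grid
#' neighbours — the quality-control rule used to drop poorly coupled sites
#' before fitting.
#'
#' @param amplitudes Named numeric vector of response amplitudes (volts),
#'   names are electrode labels covering the array.
#' @param array An [mea_array()].
#' @param threshold_fraction Exclusion threshold (default 0.5); 0 disables
#'   the criterion.
#' @return Character vector of excluded labels (possibly empty).
#' @export
qc_electrodes <- function(amplitudes, array, threshold_fraction = 0.5) {
  stopifnot(inherits(array, "mea_array"), threshold_fraction >= 0)
  miss <- setdiff(array$label, names(amplitudes))
  if (length(miss)) stop("amplitudes missing for electrode(s): ",
                         paste(utils::head(miss, 3), collapse = ", "))
  flagged <- character()
  for (lab in array$label) {
    nb <- mea_neighbors(array, lab)
    med <- stats::median(amplitudes[nb])
    if (amplitudes[lab] < threshold_fraction * med)
      flagged <- c(flagged, lab)
  }
  flagged
}

#' Reduce a session to per-electrode phasors
#'
#' Averages the sweeps of every condition, extracts the phasor at the
#' stimulation frequency on each electrode, and applies quality control.
#'
#' @param session An `mea_session`.
#' @param method Phasor estimator, see [extract_phasor()].
#' @param qc_threshold Threshold fraction for [qc_electrodes()]; `NA`
#'   disables QC.
#' @return Data frame of class `phasor_table`: one row per condition x
#'   electrode with columns `condition`, `frequency`, `amplitude_a`
#'   (injected current), `distance` (source height), `electrode`,
#'   `r` (electrode-source distance, m), `phi0`, `beta`, `qc_pass`.
#' @export
session_phasors <- function(session, method = "projection",
                            qc_threshold = 0.5) {
  stopifnot(inherits(session, "mea_session"))
  pos <- electrode_positions(session$array)
  out <- list()
  for (k in seq_along(session$conditions)) {
    cc <- session$conditions[[k]]
    labs <- dimnames(cc$traces)[[3]]
    ph <- vapply(labs, function(l) {
      avg <- average_sweeps(cc$traces[, , l])
      p <- extract_phasor(avg, cc$frequency, session$protocol$sample_rate,
                          method = method)
      c(p$amplitude, p$phase)
    }, numeric(2))
    amps <- stats::setNames(ph[1, ], labs)
    qc_fail <- if (is.na(qc_threshold)) character()
               else qc_electrodes(amps, session$array, qc_threshold)
    r <- sqrt((pos[labs, 1] - cc$source[1])^2 +
              (pos[labs, 2] - cc$source[2])^2 +
              (pos[labs, 3] - cc$source[3])^2)
    out[[k]] <- data.frame(condition = k, frequency = cc$frequency,
                           amplitude_a = cc$amplitude,
                           distance = cc$distance, electrode = labs,
                           r = unname(r), phi0 = unname(ph[1, ]),
                           beta = unname(ph[2, ]),
                           qc_pass = !(labs %in% qc_fail),
                           row.names = NULL)
  }
  res <- do.call(rbind, out)
  class(res) <- c("phasor_table", "data.frame")
  res
}
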