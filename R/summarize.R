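#' Per-frequency phase offset between tissue and saline recordings
#'
#' Circular mean of the phase difference `beta_tissue - beta_saline`
#' across matched electrodes and conditions, per frequency.  A nonzero
#' offset indicates capacitive behaviour of the tissue (the saline
#' reference cancels electrode-polarization phase shifts, which are common
#' to both).  With the phasor convention `phi0 * cos(w*t + beta)` an
#' impedance phase `-theta` appears as an offset of `-theta`, i.e. a
#' capacitive tissue with complex conductivity `sigma_R + 1i*sigma_I`
#' yields an offset of `-atan2(sigma_I, sigma_R)`.
#'
#' @param tissue,saline `phasor_table`s from [session_phasors()] for
#'   matched protocols.
#' @return Data frame with columns `frequency`, `phase_diff` (radians),
#'   `n` (electrode-condition pairs used).
#' @export
phase_difference <- function(tissue, saline) {
  key <- function(d) paste(d$frequency, d$amplitude_a, d$distance,
                           d$electrode)
  m <- merge(tissue[tissue$qc_pass, c("frequency", "amplitude_a",
                                      "distance", "electrode", "beta")],
             saline[saline$qc_pass, c("frequency", "amplitude_a",
                                      "distance", "electrode", "beta")],
             by = c("frequency", "amplitude_a", "distance", "electrode"),
             suffixes = c("_t", "_s"))
  if (nrow(m) == 0L) stop("no matched conditions between the two tables")
  out <- do.call(rbind, lapply(split(m, m$frequency), function(g) {
    z <- mean(exp(1i * (g$beta_t - g$beta_s)))
    data.frame(frequency = g$frequency[1], phase_diff = Arg(z),
               n = nrow(g))
  }))
  rownames(out) <- NULL
  out
}

#' Summarize conductivity estimates across conditions
#'
#' Builds the standard report from a table of per-condition conductivity
#' estimates: per-frequency mean and SEM (pooled over amplitudes and
#' distances), values normalized to the lowest-frequency (5 Hz) estimate,
#' an ordinary least-squares regression of conductivity on frequency
#' (slope and R^2), and the percent change from the lowest to the highest
#' frequency.
#'
#' @param estimates Data frame with columns `frequency` and `sigma` (or
#'   `sigma_s` / `sigma_t`, auto-detected), optionally `medium`; e.g. the
#'   `estimates` component of a [fit_saline()] or [fit_tissue()] object.
#' @return Object of class `conductivity_summary` with components
#'   `by_frequency` (mean, sem, n, normalized), `slope`, `r2`,
#'   `pct_change`; when a `medium` column is present all components are
#'   computed per medium.
#' @export
summarize_conductivity <- function(estimates) {
  stopifnot(is.data.frame(estimates), "frequency" %in% names(estimates))
  sig_col <- intersect(c("sigma", "sigma_s", "sigma_t"), names(estimates))
  if (length(sig_col) == 0L) stop("no conductivity column found")
  sig_col <- sig_col[1]
  if (length(unique(estimates$frequency)) < 2L)
    stop("need estimates at two or more frequencies")
  df <- data.frame(medium = if ("medium" %in% names(estimates))
                     estimates$medium else "all",
                   frequency = estimates$frequency,
                   sigma = estimates[[sig_col]])
  one_medium <- function(g) {
    byf <- split(g, g$frequency)
    tab <- do.call(rbind, lapply(byf, function(h) data.frame(
      medium = h$medium[1], frequency = h$frequency[1], n = nrow(h),
      sigma = mean(h$sigma),
      sem = if (nrow(h) > 1) stats::sd(h$sigma) / sqrt(nrow(h)) else NA_real_)))
    tab <- tab[order(tab$frequency), ]
    tab$normalized <- tab$sigma / tab$sigma[1]
    fit <- stats::lm(sigma ~ frequency, data = g)
    list(table = tab,
         slope = unname(stats::coef(fit)[2]),
         r2 = suppressWarnings(summary(fit))$r.squared,
         pct_change = 100 * (tab$sigma[nrow(tab)] - tab$sigma[1]) /
           tab$sigma[1])
  }
  parts <- lapply(split(df, df$medium), one_medium)
  tab <- do.call(rbind, lapply(parts, `[[`, "table"))
  rownames(tab) <- NULL
  structure(list(
    by_frequency = tab,
    slope = vapply(parts, `[[`, numeric(1), "slope"),
    r2 = vapply(parts, `[[`, numeric(1), "r2"),
    pct_change = vapply(parts, `[[`, numeric(1), "pct_change")),
    class = "conductivity_summary")
}

#' @export
print.conductivity_summary <- function(x, digits = 4, ...) {
  cat("Conductivity by frequency:\n")
  print(format(x$by_frequency, digits = digits), row.names = FALSE)
  cat("\nLinear trend (sigma ~ frequency):\n")
  for (m in names(x$slope))
    cat(sprintf("  %s: slope %.3g S/m/Hz, R^2 = %.3f, change %s -> %s Hz: %+.1f%%\n",
                m, x$slope[m], x$r2[m],
                min(x$by_frequency$frequency),
                max(x$by_frequency$frequency), x$pct_change[m]))
  invisible(x)
}
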