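#' Measured impedance from a phasor
#'
#' Converts a measured potential phasor into a complex transfer impedance
#' relative to the injected current: `Z = (phi0 / I0) * exp(1i*(beta -
#' alpha))`.  This is the total series impedance seen by the injection:
#' medium plus electrode polarization.
#'
#' @param phi0 Potential amplitude(s), volts.
#' @param beta Potential phase(s), radians.
#' @param I0 Injected current amplitude, amperes (> 0).
#' @param alpha Phase of the injected current, radians.
#' @return Complex impedance(s), Ohm.
#' @export
measured_impedance <- function(phi0, beta, I0, alpha = 0) {
  if (length(I0) != 1L || I0 <= 0) stop("'I0' must be a single positive current")
  (phi0 / I0) * exp(1i * (beta - alpha))
}

## residual of the saline model: centred measured impedance (rotated by
## -alpha) minus centred half-space model; the EP term is the complex mean
## and drops out of the centred residual.
saline_residual <- function(log_sigma, alpha, M, r) {
  sigma <- exp(log_sigma)
  z <- M * exp(-1i * alpha)
  s <- 1 / (2 * pi * sigma * r)
  res <- z - s
  res - mean(res)
}

#' Jointly estimate saline conductivity, injection phase, and EP impedance
#'
#' Core estimation step on saline (half-space) sessions.  For each
#' condition, the per-electrode measured impedances
#' `M_i = (phi0_i / I0) * exp(1i * beta_i)` are modelled as
#' `exp(1i*alpha) * (1 / (2*pi*sigma_s*r_i) + Z_EP)`: a real half-space
#' decay plus a position-independent series electrode-polarization
#' impedance, rotated by the unknown phase of the injected current.  The
#' fit minimizes the summed squared magnitude of the residuals over
#' `(log sigma_s, alpha)`, with `Z_EP` re-evaluated inside the objective as
#' the complex mean of (measured - model) across electrodes.  The
#' parameterization in `log sigma` keeps the conductivity positive.
#'
#' A consistency diagnostic is stored per condition: the slope (and
#' p-value) of the imaginary part of the rotated measured impedance versus
#' distance, which should be indistinguishable from zero in a purely ohmic
#' medium.
#'
#' @param session A saline `mea_session`, or a `phasor_table` from
#'   [session_phasors()].
#' @param sigma_init,alpha_init Starting values (1.5 S/m, 0 rad).
#' @param qc_threshold Passed to [session_phasors()] when `session` is a
#'   session object.
#' @param reltol Relative convergence tolerance of the optimizer.
#' @return Object of class `saline_fit` with components `estimates` (one
#'   row per condition: `sigma_s`, `alpha`, `R_ep`, `X_ep`, `rss`,
#'   `n_electrodes`, `im_slope`, `im_slope_p`), `ep` (per-frequency means
#'   of `alpha`, `R_ep`, `X_ep` — the transferable EP estimate), and
#'   `residuals` (per electrode).
#' @export
fit_saline <- function(session, sigma_init = 1.5, alpha_init = 0,
                       qc_threshold = 0.5, reltol = 1e-14) {
  ph <- if (inherits(session, "mea_session"))
    session_phasors(session, qc_threshold = qc_threshold)
  else session
  stopifnot(is.data.frame(ph),
            all(c("condition", "frequency", "amplitude_a", "distance",
                  "electrode", "r", "phi0", "beta", "qc_pass") %in% names(ph)))
  conds <- unique(ph$condition)
  est <- vector("list", length(conds))
  resid_rows <- vector("list", length(conds))
  for (i in seq_along(conds)) {
    d <- ph[ph$condition == conds[i] & ph$qc_pass, , drop = FALSE]
    if (nrow(d) < 5L)
      stop("need at least 5 usable electrodes (condition ", conds[i], ")")
    M <- measured_impedance(d$phi0, d$beta, d$amplitude_a[1])
    obj <- function(p) sum(Mod(saline_residual(p[1], p[2], M, d$r))^2)
    fit <- stats::optim(c(log(sigma_init), alpha_init), obj,
                        method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = 5000))
    ## restart to polish the Nelder-Mead solution
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = 5000))
    if (fit$convergence != 0)
      stop("saline fit failed to converge (condition ", conds[i], ")")
    sigma_s <- exp(fit$par[1]); alpha <- fit$par[2]
    z <- M * exp(-1i * alpha)
    s <- 1 / (2 * pi * sigma_s * d$r)
    z_ep <- mean(z - s)
    res <- z - s - z_ep
    ## imaginary-part flatness: X_EP must not depend on electrode position
    fl <- stats::lm(Im(z) ~ d$r)
    sl <- suppressWarnings(summary(fl))$coefficients
    est[[i]] <- data.frame(condition = conds[i], frequency = d$frequency[1],
                           amplitude_a = d$amplitude_a[1],
                           distance = d$distance[1],
                           sigma_s = sigma_s, alpha = alpha,
                           R_ep = Re(z_ep), X_ep = Im(z_ep),
                           rss = fit$value, n_electrodes = nrow(d),
                           im_slope = sl[2, 1], im_slope_p = sl[2, 4])
    resid_rows[[i]] <- data.frame(condition = conds[i],
                                  electrode = d$electrode, r = d$r,
                                  re = Re(res), im = Im(res))
  }
  estimates <- do.call(rbind, est)
  ep <- do.call(rbind, lapply(split(estimates, estimates$frequency),
    function(g) data.frame(frequency = g$frequency[1],
                           alpha = mean(g$alpha),
                           R_ep = mean(g$R_ep), X_ep = mean(g$X_ep))))
  rownames(ep) <- NULL
  structure(list(estimates = estimates, ep = ep,
                 residuals = do.call(rbind, resid_rows)),
            class = "saline_fit")
}

#' @export
print.saline_fit <- function(x, digits = 4, ...) {
  cat("Saline conductivity fit (", nrow(x$estimates), " conditions)\n",
      sep = "")
  print(format(x$estimates[, c("frequency", "amplitude_a", "distance",
                               "sigma_s", "alpha", "R_ep", "X_ep")],
               digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.saline_fit <- function(object, ...) {
  stats::setNames(object$estimates$sigma_s,
                  paste0(object$estimates$frequency, "Hz_c",
                         object$estimates$condition))
}

#' @export
residuals.saline_fit <- function(object, ...) object$residuals

#' @export
summary.saline_fit <- function(object, ...) {
  byf <- split(object$estimates, object$estimates$frequency)
  tab <- do.call(rbind, lapply(byf, function(g) data.frame(
    frequency = g$frequency[1], n = nrow(g),
    sigma_s = mean(g$sigma_s),
    sem = stats::sd(g$sigma_s) / sqrt(nrow(g)),
    alpha = mean(g$alpha), R_ep = mean(g$R_ep), X_ep = mean(g$X_ep))))
  rownames(tab) <- NULL
  structure(list(by_frequency = tab), class = "summary.saline_fit")
}

#' @export
print.summary.saline_fit <- function(x, ...) {
  cat("Per-frequency saline estimates (mean over conditions):\n")
  print(x$by_frequency, row.names = FALSE)
  invisible(x)
}
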