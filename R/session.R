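#' Generate a synthetic MEA recording session
#'
#' Produces raw per-electrode sweep traces for every condition of an
#' injection protocol, with known ground truth.  The point current source
#' is placed vertically above the `nearest` electrode at height equal to
#' the condition's source distance.  Each trace is
#'
#' \deqn{V_e(t) = \mathrm{Re}\left[(Z_{model,e} + Z_{EP}) I_0
#'   e^{j(\omega t + \alpha)}\right] + \epsilon(t)}
#'
#' where `Z_model` is the forward-model transfer impedance at the
#' stimulation frequency ([potential_mea()] per unit current for tissue,
#' [potential_saline_halfspace()] for saline), `Z_EP` the series
#' electrode-polarization impedance, and `eps` i.i.d. Gaussian noise of
#' standard deviation `noise_sd` per sample.
#'
#' @param protocol An [injection_protocol()].
#' @param array An [mea_array()].
#' @param medium `"tissue"` or `"saline"`.
#' @param geometry A [slice_geometry()]; required for tissue sessions.
#' @param sigma_s Saline conductivity in S/m; required for saline sessions.
#' @param ep An [ep_model()].
#' @param noise_sd Per-sample noise standard deviation in volts.  The
#'   default 0.5 uV gives a single-sweep signal-to-noise ratio of about one
#'   at the electrode nearest the source for protocol-scale currents.
#' @param seed Integer seed; equal seeds give bit-identical sessions.
#' @param nearest Label of the electrode the source sits above.
#' @param sigma_by_frequency Optional named numeric (or complex) vector
#'   giving a per-frequency ground-truth conductivity (names are
#'   frequencies in Hz); overrides the scalar `sigma_t`/`sigma_s` so
#'   frequency-dependent media can be emulated condition by condition.
#' @return Object of class `mea_session`.
#' @export
generate_session <- function(protocol, array = mea_array(),
                             medium = c("tissue", "saline"),
                             geometry = NULL, sigma_s = NULL,
                             ep = ep_model("none"), noise_sd = 5e-7,
                             seed = 1L, nearest = "E44",
                             sigma_by_frequency = NULL) {
  medium <- match.arg(medium)
  stopifnot(inherits(protocol, "injection_protocol"),
            inherits(array, "mea_array"), inherits(ep, "ep_model"))
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be non-negative")
  if (medium == "tissue" && !inherits(geometry, "slice_geometry"))
    stop("tissue sessions require a slice_geometry")
  if (medium == "saline" && is.null(sigma_s) && is.null(sigma_by_frequency))
    stop("saline sessions require 'sigma_s'")
  ni <- match(nearest, array$label)
  if (is.na(ni)) stop("unknown electrode label: ", nearest)

  pos <- electrode_positions(array)
  n_samples <- round(protocol$sweep_duration * protocol$sample_rate)
  t <- (seq_len(n_samples) - 1) / protocol$sample_rate
  conds <- expand.grid(frequency = protocol$frequencies,
                       amplitude = protocol$amplitudes,
                       distance = protocol$source_distances,
                       KEEP.OUT.ATTRS = FALSE)

  sigma_at <- function(f, default) {
    if (is.null(sigma_by_frequency)) return(default)
    v <- sigma_by_frequency[as.character(f)]
    if (is.na(v)) stop("no ground-truth sigma given for ", f, " Hz")
    unname(v)
  }

  set.seed(as.integer(seed))
  conditions <- vector("list", nrow(conds))
  for (k in seq_len(nrow(conds))) {
    f <- conds$frequency[k]
    I0 <- conds$amplitude[k]
    d <- conds$distance[k]
    src <- c(pos[ni, 1], pos[ni, 2], d)
    if (medium == "tissue") {
      sig <- sigma_at(f, geometry$sigma_t)
      g <- geometry; g$sigma_t <- sig
      if (d >= g$h) stop("source height must be below the slice surface")
      z_model <- potential_mea(src, 1, pos, g)
    } else {
      sig <- sigma_at(f, sigma_s)
      z_model <- potential_saline_halfspace(src, 1, pos, sig)
    }
    z_ep <- ep_impedance(ep, f)
    z_tot <- z_model + z_ep
    omega <- 2 * pi * f
    carrier <- exp(1i * (omega * t + protocol$alpha))
    clean <- I0 * Re(outer(carrier, z_tot))  # n_samples x n_electrodes
    traces <- array(0, dim = c(n_samples, protocol$sweeps, nrow(array)),
                    dimnames = list(NULL, NULL, array$label))
    for (s in seq_len(protocol$sweeps)) {
      noise <- if (noise_sd > 0)
        matrix(rnorm(n_samples * nrow(array), sd = noise_sd),
               n_samples, nrow(array))
      else 0
      traces[, s, ] <- clean + noise
    }
    conditions[[k]] <- list(frequency = f, amplitude = I0, distance = d,
                            source = src,
                            truth = list(sigma = sig, z_ep = z_ep,
                                         alpha = protocol$alpha,
                                         z_model = z_model),
                            traces = traces)
  }
  structure(list(array = array, protocol = protocol, medium = medium,
                 geometry = geometry, sigma_s = sigma_s, ep = ep,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 nearest = nearest, dead_electrodes = character(),
                 conditions = conditions),
            class = "mea_session")
}

#' @export
print.mea_session <- function(x, ...) {
  cat("MEA session (", x$medium, "): ", length(x$conditions),
      " conditions, ", nrow(x$array), " electrodes, ",
      x$protocol$sweeps, " sweeps @ ", x$protocol$sample_rate, " Hz, seed ",
      x$seed, "\n", sep = "")
  if (length(x$dead_electrodes))
    cat("  dead electrodes:", paste(x$dead_electrodes, collapse = ", "),
        "\n")
  invisible(x)
}

#' Attenuate selected electrodes of a session
#'
#' Emulates poorly coupled ("dead") recording sites by scaling their traces
#' by `attenuation` in every condition; the labels are recorded in the
#' session's truth metadata so downstream quality control can be verified.
#'
#' @param session An `mea_session`.
#' @param labels Electrode labels to attenuate.
#' @param attenuation Scale factor in `[0, 1)`; 0 leaves pure silence.
#' @return The modified session.
#' @export
inject_dead_electrodes <- function(session, labels, attenuation = 0.2) {
  stopifnot(inherits(session, "mea_session"),
            attenuation >= 0, attenuation < 1)
  if (length(labels) == 0L) return(session)
  bad <- setdiff(labels, session$array$label)
  if (length(bad)) stop("unknown electrode label: ",
                        paste(bad, collapse = ", "))
  for (k in seq_along(session$conditions)) {
    session$conditions[[k]]$traces[, , labels] <-
      session$conditions[[k]]$traces[, , labels, drop = FALSE] * attenuation
  }
  session$dead_electrodes <- union(session$dead_electrodes, labels)
  session
}

#' Write a session to a directory of plain-text files
#'
#' The container is a directory holding `metadata.json` (protocol,
#' geometry, ground truth, seed) plus one wide CSV per condition with
#' columns `sweep`, `sample`, then one column per electrode (volts).
#'
#' @param session An `mea_session`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    medium = session$medium,
    seed = session$seed,
    noise_sd = session$noise_sd,
    nearest = session$nearest,
    dead_electrodes = session$dead_electrodes,
    protocol = unclass(session$protocol),
    geometry = if (!is.null(session$geometry)) list(
      h = session$geometry$h,
      sigma_t_re = Re(session$geometry$sigma_t),
      sigma_t_im = Im(session$geometry$sigma_t),
      sigma_s = session$geometry$sigma_s,
      n_terms = session$geometry$n_terms),
    sigma_s = session$sigma_s,
    ep = list(kind = session$ep$kind, K = session$ep$K, n = session$ep$n),
    array = as.data.frame(session$array),
    conditions = lapply(session$conditions, function(cc) list(
      frequency = cc$frequency, amplitude = cc$amplitude,
      distance = cc$distance, source = cc$source,
      truth = list(sigma_re = Re(cc$truth$sigma),
                   sigma_im = Im(cc$truth$sigma),
                   z_ep_re = Re(cc$truth$z_ep),
                   z_ep_im = Im(cc$truth$z_ep),
                   alpha = cc$truth$alpha))))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  for (k in seq_along(session$conditions)) {
    cc <- session$conditions[[k]]
    dm <- dim(cc$traces)
    ## rows ordered sweep-major: all samples of sweep 1, then sweep 2, ...
    flat <- do.call(rbind, lapply(seq_len(dm[2]), function(s)
      cc$traces[, s, ]))
    df <- data.frame(sweep = rep(seq_len(dm[2]), each = dm[1]),
                     sample = rep(seq_len(dm[1]), times = dm[2]))
    df <- cbind(df, as.data.frame(flat))
    names(df) <- c("sweep", "sample", dimnames(cc$traces)[[3]])
    utils::write.csv(df, file.path(dir, sprintf("condition_%03d.csv", k)),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Session directory.
#' @return An `mea_session`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  arr <- meta$array
  class(arr) <- c("mea_array", "data.frame")
  proto <- do.call(injection_protocol, meta$protocol)
  geom <- if (!is.null(meta$geometry))
    slice_geometry(meta$geometry$h,
                   if (meta$geometry$sigma_t_im == 0) meta$geometry$sigma_t_re
                   else complex(real = meta$geometry$sigma_t_re,
                                imaginary = meta$geometry$sigma_t_im),
                   meta$geometry$sigma_s, meta$geometry$n_terms)
  ep <- if (meta$ep$kind == "none") ep_model("none")
        else ep_model(meta$ep$kind, K = meta$ep$K, n = meta$ep$n)
  n_samples <- round(proto$sweep_duration * proto$sample_rate)
  conds <- if (is.data.frame(meta$conditions))
    split(meta$conditions, seq_len(nrow(meta$conditions)))
  else meta$conditions
  conditions <- vector("list", length(conds))
  for (k in seq_along(conds)) {
    ck <- conds[[k]]
    df <- utils::read.csv(file.path(dir, sprintf("condition_%03d.csv", k)),
                          check.names = FALSE)
    labels <- setdiff(names(df), c("sweep", "sample"))
    traces <- array(0, dim = c(n_samples, proto$sweeps, length(labels)),
                    dimnames = list(NULL, NULL, labels))
    for (s in seq_len(proto$sweeps)) {
      traces[, s, ] <- as.matrix(df[df$sweep == s, labels])
    }
    conditions[[k]] <- list(
      frequency = ck$frequency, amplitude = ck$amplitude,
      distance = ck$distance, source = unlist(ck$source),
      truth = list(sigma = complex(real = ck$truth$sigma_re,
                                   imaginary = ck$truth$sigma_im),
                   z_ep = complex(real = ck$truth$z_ep_re,
                                  imaginary = ck$truth$z_ep_im),
                   alpha = ck$truth$alpha),
      traces = traces)
    if (Im(conditions[[k]]$truth$sigma) == 0)
      conditions[[k]]$truth$sigma <- Re(conditions[[k]]$truth$sigma)
  }
  structure(list(array = arr, protocol = proto, medium = meta$medium,
                 geometry = geom, sigma_s = meta$sigma_s, ep = ep,
                 noise_sd = meta$noise_sd, seed = meta$seed,
                 nearest = meta$nearest,
                 dead_electrodes = as.character(unlist(meta$dead_electrodes)),
                 conditions = conditions),
            class = "mea_session")
}
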