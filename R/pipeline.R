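#' Configuration for the end-to-end estimation pipeline
#'
#' Bundles everything [run_pipeline()] needs: the injection protocol, the
#' slice geometry, the ground-truth conductivities used for simulation
#' (scalars or per-frequency named vectors), the EP model, the noise level
#' and the seed.  The resolved configuration is stored in the pipeline
#' result so every run is auditable.
#'
#' @param protocol An [injection_protocol()].
#' @param h Slice thickness, m.
#' @param n_terms Image-series truncation.
#' @param sigma_bath Bath conductivity above the slice and the fixed
#'   `sigma_s` of the tissue fit, S/m.
#' @param truth_sigma_t Ground-truth tissue conductivity: scalar or named
#'   per-frequency vector (names in Hz).
#' @param truth_sigma_s Ground-truth saline conductivity for the saline
#'   sessions, scalar or named per-frequency vector.
#' @param ep An [ep_model()].
#' @param noise_sd Per-sample recording noise SD, V.
#' @param seed Integer seed.
#' @param qc_threshold Electrode QC threshold fraction.
#' @param out_dir Optional directory for the report bundle.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(protocol = injection_protocol(),
                            h = 200e-6, n_terms = 20L, sigma_bath = 1.5,
                            truth_sigma_t = 0.4, truth_sigma_s = 1.5,
                            ep = ep_model("cpe"), noise_sd = 5e-7,
                            seed = 1L, qc_threshold = 0.5,
                            out_dir = NULL) {
  structure(list(protocol = protocol, h = h, n_terms = as.integer(n_terms),
                 sigma_bath = sigma_bath, truth_sigma_t = truth_sigma_t,
                 truth_sigma_s = truth_sigma_s, ep = ep,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 qc_threshold = qc_threshold, out_dir = out_dir),
            class = "pipeline_config")
}

sigma_vec <- function(x, freqs) {
  if (length(x) == 1L && is.null(names(x))) return(NULL)
  stopifnot(all(as.character(freqs) %in% names(x)))
  x
}

#' Run the full simulate - extract - fit - report pipeline
#'
#' Generates a saline and a tissue session from the configured ground
#' truth, runs [fit_saline()] on the saline session, [fit_tissue()] on the
#' tissue session using the recovered per-frequency injection phase and EP
#' impedance, and assembles the report: a per-condition conductivity
#' table, per-frequency means normalized to the lowest frequency, the
#' tissue-saline phase-difference table, trend regressions, and a manifest
#' with all estimates, diagnostics and the resolved configuration.
#'
#' Any stage failure aborts with the stage name in the error message.
#' Reruns with the same configuration and seed are identical.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `slice_pipeline` with components
#'   `saline_fit`, `tissue_fit`, `results` (per-condition table),
#'   `summary_saline`, `summary_tissue`, `phase_diff`, `manifest`,
#'   `config`.  If `config$out_dir` is set, writes `conductivity.csv`,
#'   `normalized.csv`, `phase_difference.csv` and `manifest.json` there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  freqs <- config$protocol$frequencies
  saline <- stage("simulate-saline", {
    ss_vec <- sigma_vec(config$truth_sigma_s, freqs)
    generate_session(
      config$protocol, medium = "saline",
      sigma_s = if (is.null(ss_vec)) config$truth_sigma_s else NULL,
      sigma_by_frequency = ss_vec, ep = config$ep,
      noise_sd = config$noise_sd, seed = config$seed)
  })
  tissue <- stage("simulate-tissue", {
    st_vec <- sigma_vec(config$truth_sigma_t, freqs)
    geom <- slice_geometry(config$h,
                           if (is.null(st_vec)) config$truth_sigma_t
                           else st_vec[[1]],
                           config$sigma_bath, config$n_terms)
    generate_session(
      config$protocol, medium = "tissue", geometry = geom,
      sigma_by_frequency = st_vec, ep = config$ep,
      noise_sd = config$noise_sd, seed = config$seed + 1L)
  })

  sal_ph <- stage("extract-saline",
                  session_phasors(saline, qc_threshold = config$qc_threshold))
  tis_ph <- stage("extract-tissue",
                  session_phasors(tissue, qc_threshold = config$qc_threshold))
  sal_fit <- stage("fit-saline", fit_saline(sal_ph))
  tis_fit <- stage("fit-tissue", fit_tissue(
    tis_ph, sal_fit,
    geometry = slice_geometry(config$h, 0.4, config$sigma_bath,
                              config$n_terms),
    sigma_s_fixed = config$sigma_bath))
  pd <- stage("phase-difference", phase_difference(tis_ph, sal_ph))

  truth_at <- function(x, f) if (is.null(sigma_vec(x, freqs))) x
                             else unname(x[as.character(f)])
  results <- rbind(
    data.frame(medium = "saline",
               frequency = sal_fit$estimates$frequency,
               amplitude_pA = sal_fit$estimates$amplitude_a * 1e12,
               distance_um = sal_fit$estimates$distance * 1e6,
               sigma = sal_fit$estimates$sigma_s,
               truth = vapply(sal_fit$estimates$frequency, function(f)
                 Re(truth_at(config$truth_sigma_s, f)), numeric(1))),
    data.frame(medium = "tissue",
               frequency = tis_fit$estimates$frequency,
               amplitude_pA = tis_fit$estimates$amplitude_a * 1e12,
               distance_um = tis_fit$estimates$distance * 1e6,
               sigma = tis_fit$estimates$sigma_t,
               truth = vapply(tis_fit$estimates$frequency, function(f)
                 Re(truth_at(config$truth_sigma_t, f)), numeric(1))))

  sum_s <- summarize_conductivity(
    cbind(sal_fit$estimates, medium = "saline")[,
      c("medium", "frequency", "sigma_s")])
  sum_t <- if (length(unique(tis_fit$estimates$frequency)) >= 2L)
    summarize_conductivity(cbind(tis_fit$estimates, medium = "tissue")[,
      c("medium", "frequency", "sigma_t")]) else NULL

  manifest <- list(
    config = list(seed = config$seed, noise_sd = config$noise_sd,
                  h = config$h, sigma_bath = config$sigma_bath,
                  n_terms = config$n_terms,
                  frequencies = freqs,
                  amplitudes_pA = config$protocol$amplitudes * 1e12,
                  distances_um = config$protocol$source_distances * 1e6,
                  sweeps = config$protocol$sweeps,
                  sweep_duration = config$protocol$sweep_duration,
                  sample_rate = config$protocol$sample_rate,
                  ep_kind = config$ep$kind),
    estimates = results,
    ep = sal_fit$ep,
    phase_difference = pd,
    trend = list(
      saline = list(slope = unname(sum_s$slope), r2 = unname(sum_s$r2),
                    pct_change = unname(sum_s$pct_change)),
      tissue = if (!is.null(sum_t))
        list(slope = unname(sum_t$slope), r2 = unname(sum_t$r2),
             pct_change = unname(sum_t$pct_change))))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results,
                     file.path(config$out_dir, "conductivity.csv"),
                     row.names = FALSE)
    norm_tab <- rbind(sum_s$by_frequency,
                      if (!is.null(sum_t)) sum_t$by_frequency)
    utils::write.csv(norm_tab,
                     file.path(config$out_dir, "normalized.csv"),
                     row.names = FALSE)
    utils::write.csv(pd,
                     file.path(config$out_dir, "phase_difference.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  structure(list(saline_fit = sal_fit, tissue_fit = tis_fit,
                 results = results, summary_saline = sum_s,
                 summary_tissue = sum_t, phase_diff = pd,
                 manifest = manifest, config = config),
            class = "slice_pipeline")
}

#' @export
print.slice_pipeline <- function(x, digits = 4, ...) {
  cat("Slice conductivity pipeline (seed ", x$config$seed, ")\n\n",
      sep = "")
  agg <- stats::aggregate(cbind(sigma, truth) ~ medium + frequency,
                          data = x$results, FUN = mean)
  print(format(agg, digits = digits), row.names = FALSE)
  cat("\nTrend:\n")
  print(x$summary_saline)
  if (!is.null(x$summary_tissue)) print(x$summary_tissue)
  invisible(x)
}
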