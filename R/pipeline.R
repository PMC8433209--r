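## End-to-end orchestration of the analysis stages: synthetic data (or
## pre-extracted trajectories), mixer simulation, segmentation, volume
## extraction, 2-p fitting, concentration-dependence summary. The
## numbered scripts under analysis/ are thin drivers over run_pipeline()
## and the stage functions.

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are
#' rejected so typos fail before any compute.
#'
#' @param out_dir output directory.
#' @param seed master seed; all stage seeds derive from it.
#' @param cpa_name `"EG"` or `"PG"`.
#' @param concentrations mol/L, strictly increasing.
#' @param Lp,Ps ground-truth membrane parameters of the synthetic run.
#' @param times frame times, s.
#' @param backend segmentation backend, `"classical"` or `"network"`.
#' @param render logical: render micrographs and segment them (the full
#'   image chain) rather than fitting the noisy volume tables directly.
#' @param noise_sigma trajectory noise sd (render = FALSE) or pixel noise
#'   sd in 8-bit units (render = TRUE).
#' @param image_size canvas side, px, for rendered frames.
#' @param mixer_length_um unrolled mixing-channel length for the mixer
#'   stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("cryoperm_run_"), seed = 1,
                            cpa_name = "EG",
                            concentrations = c(0.5, 1.0, 1.5),
                            Lp = 0.8, Ps = 0.25,
                            times = seq(0, 600, by = 2),
                            backend = c("classical", "network"),
                            render = FALSE, noise_sigma = 0.01,
                            image_size = 256, mixer_length_um = 3e5) {
  backend <- match.arg(backend)
  stopifnot(is.numeric(seed), length(seed) == 1,
            length(concentrations) >= 2, all(diff(concentrations) > 0),
            Lp > 0, Ps >= 0, noise_sigma >= 0, mixer_length_um > 0)
  cpa_properties(cpa_name)   # validates the name
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 cpa_name = cpa_name, concentrations = concentrations,
                 Lp = Lp, Ps = Ps, times = times, backend = backend,
                 render = render, noise_sigma = noise_sigma,
                 image_size = image_size,
                 mixer_length_um = mixer_length_um),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in the order of the perfusion workflow: (1) mixer simulation
#' for the highest-vs-lowest concentration pair, reporting the delivered
#' capture concentration and mixing length; (2) ground-truth 2-p
#' trajectories per concentration; (3) either noisy volume tables or
#' rendered micrograph sequences segmented back to volumes; (4) 2-p fits
#' per concentration and the concentration-dependence trend. All tables
#' are written under `config$out_dir`; floating point is formatted at 9
#' significant digits so repeated runs are byte-identical.
#'
#' @param config [pipeline_config()].
#' @param net trained network (only for `backend = "network"`).
#' @return list of class `pipeline_result`: `config`, `mixing`
#'   (mixing_report), `truth`, `series` (concentration_series),
#'   `trajectories`, `files`.
#' @export
run_pipeline <- function(config, net = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cpa <- cpa_properties(config$cpa_name)
  geom_cell <- cell_geometry()
  files <- character()

  ## stage 1: serpentine mixer at the paper's operating point
  geom_ch <- channel_geometry(L = config$mixer_length_um)
  flow <- flow_condition(c1 = max(config$concentrations),
                         c2 = min(config$concentrations))
  D <- stokes_einstein_D(cpa, flow$temp_K)
  field <- solve_coflow(geom_ch, flow, D)
  mix_path <- file.path(config$out_dir, "mixing_report.json")
  jsonlite::write_json(list(
    c_out_mean = field$report$c_out_mean,
    L90_um = field$report$L90, L99_um = field$report$L99,
    wall_shear_rate_s = field$report$wall_shear_rate,
    D_m2_s = D), mix_path, auto_unbox = TRUE, digits = 9, null = "null")
  files <- c(files, mix_path)

  ## stage 2: ground-truth trajectories
  params <- membrane_params(config$Lp, config$Ps)
  truth <- lapply(config$concentrations, function(cc)
    scenario_truth(params, geom_cell, perfusion_env(m_cpa = cc), cpa,
                   config$times))
  names(truth) <- sprintf("%.1f", config$concentrations)

  ## stage 3: observations
  trajs <- if (config$render) {
    lapply(seq_along(truth), function(i) {
      spec <- render_spec(image_size = config$image_size,
                          r0 = config$image_size * 70 / 256,
                          noise_sigma = config$noise_sigma)
      seqs <- render_sequence(truth[[i]], spec, seed = config$seed + i)
      tr <- track_sequence(seqs$frames, seqs$times, backend = config$backend,
                           net = net, px_size = spec$px_size)
      tr$trajectory
    })
  } else {
    ds <- make_trajectory_dataset(truth, noise_sigma = config$noise_sigma,
                                  n_replicates = 1, seed = config$seed)
    lapply(ds, function(d) d$replicates[[1]])
  }
  names(trajs) <- names(truth)
  for (nm in names(trajs)) {
    p <- file.path(config$out_dir, sprintf("trajectory_%s.csv", nm))
    write_trajectory_csv(.round9(trajs[[nm]]), p)
    files <- c(files, p)
  }

  ## stage 4: fits and concentration trend
  series <- fit_concentration_series(trajs, geom_cell, cpa)
  fit_path <- file.path(config$out_dir, "fit_results.csv")
  tab <- series$table
  tab$cpa <- cpa$name
  tab <- tab[, c("cpa", "conc_M", "Lp", "Ps", "rmse", "converged")]
  names(tab) <- c("cpa", "conc_M", "Lp_um_min_atm", "Ps_um_s", "rmse",
                  "converged")
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(z) signif(z, 9))
  utils::write.csv(tab, fit_path, row.names = FALSE, quote = FALSE)
  files <- c(files, fit_path)
  json_path <- file.path(config$out_dir, "fit_results.json")
  jsonlite::write_json(list(
    table = tab, trend = as.list(series$trend),
    covariances = lapply(series$fits, function(f)
      if (is.null(f$cov)) NULL else signif(f$cov, 9)),
    seed = config$seed), json_path, auto_unbox = TRUE, digits = 9,
    null = "null")
  files <- c(files, json_path)

  structure(list(config = config, mixing = field$report, truth = truth,
                 series = series, trajectories = trajs, files = files),
            class = "pipeline_result")
}

.round9 <- function(traj)
  volume_trajectory(signif(traj$time_s, 9), signif(traj$v_norm, 9))

#' Human-readable pipeline summary
#'
#' Markdown summary of a [run_pipeline()] result: the delivered capture
#' concentration and mixing length, the per-concentration (Lp, Ps)
#' table, and the concentration-dependence trend of each parameter.
#'
#' @param result `pipeline_result`.
#' @param path optional file to write the Markdown to.
#' @return the summary lines, invisibly when `path` is given.
#' @export
report_pipeline <- function(result, path = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  tab <- result$series$table
  lines <- c(
    sprintf("# cryoperm run (%s, seed %d)", result$config$cpa_name,
            result$config$seed),
    "", "## Mixer",
    sprintf("- flux-weighted outlet concentration: %.4f mol/L",
            result$mixing$c_out_mean),
    sprintf("- 90%% / 99%% mixing length: %.0f / %.0f um",
            result$mixing$L90, result$mixing$L99),
    sprintf("- capture wall shear rate: %.1f 1/s",
            result$mixing$wall_shear_rate),
    "", "## Membrane permeability fits",
    "| conc (M) | Lp (um/min/atm) | Ps (um/s) | rmse | converged |",
    "|---|---|---|---|---|",
    sprintf("| %.1f | %.4f | %.4f | %.2e | %s |", tab$conc_M, tab$Lp,
            tab$Ps, tab$rmse, tab$converged),
    "",
    sprintf("Trend with concentration: Lp %s, Ps %s.",
            result$series$trend["Lp"], result$series$trend["Ps"]))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
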