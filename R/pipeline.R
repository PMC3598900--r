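## End-to-end experiment pipeline:
## simulate stimulus -> simulate neuron -> STA/STC -> significance ->
## localization -> sparse selection -> GNM fit -> tuning report.
## Every stochastic stage consumes an explicit named seed from the config,
## so re-running a config reproduces all numeric outputs bit-identically.

#' Build / validate an experiment configuration
#'
#' A configuration is a named list (typically read from YAML or JSON)
#' with components `stimulus`, `neuron`, `estimation`, `localization`,
#' `gnm` and `seeds`; missing fields fall back to the defaults of a
#' pooled-complex demonstration experiment.
#'
#' @param config named list, or path to a YAML/JSON file.
#' @return validated list of class `experiment_config`.
#' @export
experiment_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  }
  dflt <- list(
    stimulus = list(kind = "bars", n_bars = 16, n_frames = 50000,
                    mseq_order = 15, frame_rate_hz = 100),
    neuron = list(kind = "pooled_complex", spatial_freq = 4,
                  tilt_phase_per_lag = 0.55, n_lags = 12,
                  space_sd = 1.6, lag_sd = 2.5,
                  shifts = -4:4, pool_sd = 2.5,
                  gain = 6, offset = -1),
    estimation = list(n_lags = 12, selection = "shuffle", n_shuffles = 60,
                      alpha = 0.01, n_pos = 2, n_neg = 0, whiten_M = NA),
    localization = list(n_centers = 12, n_restarts = 20,
                        subspace = "excitatory"),
    gnm = list(knots = 15, lambda_smooth_f = 1, lambda_smooth_h = 1,
               folds = 5, h_len = 1),
    seeds = list(spikes = 1, selection = 2, localization = 3)
  )
  cfg <- utils::modifyList(dflt, config)
  stopifnot(cfg$stimulus$n_frames >= cfg$estimation$n_lags,
            !is.null(cfg$seeds$spikes))
  structure(cfg, class = c("experiment_config", "list"))
}

## Build the generating neuron_spec for a config (bar stimuli, 1-D).
config_neuron <- function(cfg) {
  ncfg <- cfg$neuron
  g1 <- make_gabor_strf(cfg$stimulus$n_bars, ncfg$n_lags,
                        spatial_freq = ncfg$spatial_freq,
                        tilt_phase_per_lag = ncfg$tilt_phase_per_lag,
                        phase = 0, space_sd = ncfg$space_sd,
                        lag_sd = ncfg$lag_sd)
  g2 <- make_gabor_strf(cfg$stimulus$n_bars, ncfg$n_lags,
                        spatial_freq = ncfg$spatial_freq,
                        tilt_phase_per_lag = ncfg$tilt_phase_per_lag,
                        phase = pi / 2, space_sd = ncfg$space_sd,
                        lag_sd = ncfg$lag_sd)
  switch(ncfg$kind,
    ln_simple = neuron_spec("ln_simple", list(g1), gain = ncfg$gain,
                            offset = ncfg$offset),
    separable_simple = {
      dec <- svd_separable(g1, rank = 2)
      neuron_spec("separable_simple",
                  list(separable_component(dec, 1),
                       separable_component(dec, 2)),
                  gain = ncfg$gain, offset = ncfg$offset)
    },
    energy_complex = neuron_spec("energy_complex", list(g1, g2),
                                 gain = ncfg$gain, offset = ncfg$offset),
    pooled_complex = neuron_spec("pooled_complex", list(g1, g2),
                                 subunit_nonlinearity = "square",
                                 shifts = ncfg$shifts,
                                 pool_sd = ncfg$pool_sd, pool_center = 0,
                                 gain = ncfg$gain, offset = ncfg$offset),
    stop("unknown neuron kind: ", ncfg$kind))
}

#' Run the full inference pipeline on a configuration
#'
#' Executes simulation, spike-triggered estimation, significance
#' selection, localization, sparse filter selection, GNM fitting and
#' grating tuning, writing per-stage outputs and a JSON manifest to
#' `out_dir`.
#'
#' @param config an [experiment_config()] (or list / file path coercible
#'   to one).
#' @param out_dir output directory, created if needed.
#' @return list of class `run_manifest`: per-stage results, output paths,
#'   the config hash and wall time.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("subunit_run_")) {
  t0 <- Sys.time()
  cfg <- experiment_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  ## stage 1: stimulus + neuron + spikes
  mov <- generate_bar_stimulus(cfg$stimulus$n_bars, cfg$stimulus$n_frames,
                               cfg$stimulus$mseq_order,
                               cfg$stimulus$frame_rate_hz)
  design <- embed_stimulus(mov, cfg$estimation$n_lags)
  truth <- config_neuron(cfg)
  rate <- neuron_rate(truth, design)
  spikes <- poisson_spikes(rate, cfg$seeds$spikes)
  data_path <- file.path(out_dir, "dataset.rds")
  write_dataset(data_path, mov, spikes,
                ground_truth = list(neuron = truth))

  ## stage 2: STA / STC + significance
  stc <- compute_stc(design, spikes)
  stc <- if (cfg$estimation$selection == "shuffle") {
    select_significant(stc, "shuffle", design = design, spikes = spikes,
                       n_shuffles = cfg$estimation$n_shuffles,
                       alpha = cfg$estimation$alpha,
                       seed = cfg$seeds$selection)
  } else {
    select_significant(stc, "fixed", n_pos = cfg$estimation$n_pos,
                       n_neg = cfg$estimation$n_neg)
  }

  ## stage 3: localization on the requested subspace
  basis <- stc_subspace(stc, cfg$localization$subspace)
  locset <- find_localized_set(basis,
                               n_centers = cfg$localization$n_centers,
                               n_restarts = cfg$localization$n_restarts,
                               seed = cfg$seeds$localization,
                               subspace_tag = cfg$localization$subspace)

  ## stage 4: sparse selection of relevant localized filters
  sel <- select_filters_sparse(locset, design, spikes,
                               folds = max(2, cfg$gnm$folds))
  fit_filters <- if (length(sel$selected)) sel$filters
                 else lapply(seq_along(basis), function(i) basis[[i]])

  ## stage 5: GNM fit + cross-validation
  fit <- fit_nonlinearities(fit_filters, design, spikes,
                            knots = cfg$gnm$knots,
                            lambda_smooth_f = cfg$gnm$lambda_smooth_f,
                            lambda_smooth_h = cfg$gnm$lambda_smooth_h,
                            folds = cfg$gnm$folds, h_len = cfg$gnm$h_len)

  ## stage 6: tuning report
  tuning <- grating_tuning(fit$model,
                           frame_rate_hz = cfg$stimulus$frame_rate_hz)
  report <- data.frame(dsi = tuning$dsi_pref, dsi_signed = tuning$dsi,
                       mi = tuning$mi,
                       pref_sf = tuning$preferred$spatial_freq,
                       pref_tf = tuning$preferred$temporal_freq,
                       pref_dir = tuning$preferred$direction,
                       xval_ll = fit$report$xval_ll,
                       n_spikes = attr(spikes, "total_spikes"),
                       n_excitatory = length(stc$excitatory),
                       n_suppressive = length(stc$suppressive),
                       n_selected = length(sel$selected))
  report_path <- file.path(out_dir, "tuning_report.csv")
  write.csv(report, report_path, row.names = FALSE)
  results_path <- file.path(out_dir, "results.rds")
  saveRDS(list(stc = stc, localized = locset, selected = sel,
               gnm = fit, tuning = tuning), results_path)

  manifest <- structure(list(
    config_hash = cfg_hash,
    package_version = as.character(utils::packageVersion("subunitscope")),
    paths = list(config = cfg_path, dataset = data_path,
                 results = results_path, report = report_path),
    report = report,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "run_manifest")
  jsonlite::write_json(
    list(config_hash = manifest$config_hash,
         package_version = manifest$package_version,
         paths = manifest$paths, report = report),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> hash=%s  (%.1f s)\n", x$config_hash,
              x$wall_time_s))
  print(x$report)
  invisible(x)
}
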