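#' Configuration-driven runners
#'
#' Thin reproducible entry points over the package's functions; these back
#' the command-line script (`system.file("cli", "pthpop", package =
#' "pthpop")`). Each runner takes a configuration (a named list, or a path
#' to a YAML/JSON file holding one), writes its outputs plus a config echo
#' into `out_dir`, and invisibly returns the output paths.
#'
#' Common fields: `protocol` (`"A"`/`"B"`/`"C"` or a profile CSV path),
#' `baseline` (mmol/L, default 1.25), `ramp_min` (default 10), `spec`
#' (`"table1"`, `"priors"`; generation also accepts `"table1-mean"` /
#' `"priors-mean"` for a fixed gland at the distribution means), `seed`,
#' `dt` (min), `n_runs`, `out_dir`,
#' `constants` (path to a YAML/JSON override file). Calibration adds
#' `observations` (CSV path), `n_models`, `max_iter`; generation adds
#' `noise_sd`, `n_subjects`.
#'
#' @param config Named list or file path.
#' @return Invisibly, a character vector of files written.
#' @name runners
NULL

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yaml", "yml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs require the 'yaml' package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a named list or a file path")
  defaults <- list(protocol = "A", baseline = 1.25, ramp_min = 10,
                   spec = "table1", seed = 1L, dt = 0.5, n_runs = 25,
                   out_dir = ".", n_models = 500, max_iter = 5,
                   threshold_sd = 1.5, noise_sd = 0.2, n_subjects = 4,
                   ca_lo = 0.6, ca_hi = 1.8, ca_step = 0.005)
  utils::modifyList(defaults, config)
}

config_protocol <- function(cfg) {
  if (cfg$protocol %in% c("A", "B", "C"))
    clamp_protocol(cfg$protocol, baseline = cfg$baseline,
                   ramp_min = cfg$ramp_min)
  else if (file.exists(cfg$protocol)) read_calcium_csv(cfg$protocol)
  else stop("unknown protocol: ", cfg$protocol,
            " (use A, B, C or a CSV path)")
}

config_spec <- function(cfg) {
  switch(as.character(cfg$spec),
         table1 = table1_spec(),
         priors = table1_priors(),
         stop("unknown spec: ", cfg$spec, " (use 'table1' or 'priors')"))
}

# ground truth for synthetic generation; the "-mean" variants give one fixed
# gland at the spec's distribution means (all subjects share it)
config_truth <- function(cfg) {
  switch(as.character(cfg$spec),
         `table1-mean` = mean_gland(table1_spec()),
         `priors-mean` = mean_gland(table1_priors()),
         config_spec(cfg))
}

config_constants <- function(cfg) {
  if (!is.null(cfg$constants)) read_constants(cfg$constants)
  else physio_constants()
}

echo_config <- function(cfg, out_dir, what) {
  p <- file.path(out_dir, paste0(what, "_config.json"))
  jsonlite::write_json(cfg, p, auto_unbox = TRUE, digits = NA, null = "null")
  p
}

#' @rdname runners
#' @export
run_simulate <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  profile <- config_protocol(cfg)
  spec <- config_spec(cfg)
  const <- config_constants(cfg)
  gland <- sample_gland(spec, seed = cfg$seed)
  sim <- simulate_gland(gland, profile, const, dt = cfg$dt)
  ts_path <- file.path(cfg$out_dir, "timeseries.csv")
  utils::write.csv(
    data.frame(t_min = sim$t, ca_mmol_L = sim$ca,
               serum_pth = sim$serum_pth, isf_pth = sim$isf_pth),
    ts_path, row.names = FALSE)
  meta_path <- file.path(cfg$out_dir, "timeseries_meta.json")
  jsonlite::write_json(
    list(gland = gland$params, constants = unclass(const),
         profile = profile$name, dt = cfg$dt, seed = cfg$seed),
    meta_path, auto_unbox = TRUE, digits = NA)
  paths <- c(ts_path, meta_path)
  if (cfg$n_runs >= 2) {
    band <- ensemble_band(spec, profile, n_runs = cfg$n_runs,
                          constants = const, dt = cfg$dt,
                          seed = cfg$seed + 1L)
    band_path <- file.path(cfg$out_dir, "band.csv")
    write_band_csv(band, band_path)
    paths <- c(paths, band_path)
  }
  paths <- c(paths, echo_config(cfg, cfg$out_dir, "simulate"))
  invisible(paths)
}

#' @rdname runners
#' @export
run_generate <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- config_truth(cfg)
  study <- synthetic_study(truth, protocol = cfg$protocol,
                           noise_sd = cfg$noise_sd,
                           n_subjects = cfg$n_subjects,
                           baseline = cfg$baseline, dt = cfg$dt,
                           seed = cfg$seed)
  obs <- generate_observations(study)
  obs_path <- file.path(cfg$out_dir, "observations.csv")
  write_observations_csv(obs, obs_path)
  invisible(c(obs_path, echo_config(cfg, cfg$out_dir, "generate")))
}

#' @rdname runners
#' @export
run_calibrate <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cfg$observations))
    stop("run_calibrate: config needs an 'observations' CSV path")
  obs <- read_observations_csv(cfg$observations)
  res <- calibrate(table1_priors(), obs,
                   protocol = config_protocol(cfg),
                   n_models = cfg$n_models, threshold_sd = cfg$threshold_sd,
                   max_iter = cfg$max_iter, dt = cfg$dt,
                   constants = config_constants(cfg), seed = cfg$seed,
                   verbose = isTRUE(cfg$verbose))
  rep_path <- file.path(cfg$out_dir, "calibration.json")
  write_calibration_json(res, rep_path)
  invisible(c(rep_path, echo_config(cfg, cfg$out_dir, "calibrate")))
}

#' @rdname runners
#' @export
run_analyze <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  profile <- config_protocol(cfg)
  spec <- config_spec(cfg)
  const <- config_constants(cfg)
  grid <- seq(cfg$ca_lo, cfg$ca_hi, by = cfg$ca_step)
  set.seed(cfg$seed)
  slopes <- numeric(cfg$n_runs)
  acute <- vector("list", cfg$n_runs)
  for (i in seq_len(cfg$n_runs)) {
    g <- sample_gland(spec)
    slopes[i] <- slope_10_90(steady_curve(g, const, grid))
    acute[[i]] <- acute_response_curve(g, const, grid,
                                       baseline = cfg$baseline)$pth
  }
  mean_acute <- structure(
    data.frame(ca = grid, pth = rowMeans(do.call(cbind, acute))),
    class = c("pth_curve", "data.frame"))
  fit <- fit_four_param(mean_acute)
  report <- list(
    slope_10_90_mean = mean(slopes), slope_10_90_sd = stats::sd(slopes),
    four_param = as.list(stats::coef(fit)), four_param_rss = fit$rss,
    n_runs = cfg$n_runs, seed = cfg$seed)
  if (!is.null(cfg$observations)) {
    obs <- read_observations_csv(cfg$observations)
    band <- ensemble_band(spec, profile, n_runs = cfg$n_runs,
                          constants = const, dt = cfg$dt,
                          seed = cfg$seed + 1L)
    gland <- sample_gland(spec, seed = cfg$seed + 2L)
    sim <- simulate_gland(gland, profile, const, dt = cfg$dt)
    dsc <- direction_score(
      data.frame(time = obs$time_min, value = serum_at(sim, obs$time_min)),
      data.frame(time = obs$time_min, value = obs$pth_mean))
    report$coverage_pct <- coverage(band, obs$time_min, obs$pth_mean)
    report$direction_agree <- dsc$n_agree
    report$direction_total <- dsc$n_total
    report$squared_residuals <- squared_residuals(sim, obs$time_min,
                                                  obs$pth_mean)
  }
  rep_path <- file.path(cfg$out_dir, "analysis.json")
  jsonlite::write_json(report, rep_path, auto_unbox = TRUE, digits = NA)
  invisible(c(rep_path, echo_config(cfg, cfg$out_dir, "analyze")))
}
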