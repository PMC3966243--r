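#' Phase-labelled PTH observations used as calibration targets
#'
#' Each row is a (time, mean, SD) summary of measured serum PTH at an
#' approximate steady state of a clamp phase, labelled `baseline`, `hypo`
#' (hypocalcemic plateau), `peak` (initial hysteretic response) or `hyper`
#' (hypercalcemic plateau). The standard layout for the training protocol
#' has 1 baseline, 5 hypo, 2 peak and 3 hyper points.
#'
#' @param time_min Observation times (min).
#' @param pth_mean Mean serum PTH at each time.
#' @param pth_sd Standard deviation at each time (> 0).
#' @param phase Phase label per time, one of `"baseline"`, `"hypo"`,
#'   `"peak"`, `"hyper"`.
#' @return An object of class `observation_set` (a data frame).
#' @export
observation_set <- function(time_min, pth_mean, pth_sd, phase) {
  n <- length(time_min)
  if (length(pth_mean) != n || length(pth_sd) != n || length(phase) != n)
    stop("observation_set: all columns must share a length")
  if (any(pth_sd <= 0)) stop("observation_set: all SDs must be > 0")
  phase <- as.character(phase)
  bad <- setdiff(unique(phase), c("baseline", "hypo", "peak", "hyper"))
  if (length(bad))
    stop("observation_set: unknown phase label(s): ",
         paste(bad, collapse = ", "))
  o <- order(time_min)
  structure(data.frame(time_min = time_min[o], pth_mean = pth_mean[o],
                       pth_sd = pth_sd[o], phase = phase[o]),
            class = c("observation_set", "data.frame"))
}

#' Standard observation times and phase labels for a clamp protocol
#'
#' Sampling layout on the plateau windows: for protocol A, baseline at
#' 0 min; the initial hysteretic peak at 5 and 10 min; the hypocalcemic
#' steady states at 30, 45, 60 and 150, 170 min; the hypercalcemic steady
#' state at 90, 105, 120 min.
#'
#' @param protocol `"A"`, `"B"` or `"C"`.
#' @return A data frame with `time_min` and `phase`.
#' @export
observation_layout <- function(protocol = c("A", "B", "C")) {
  protocol <- match.arg(protocol)
  switch(protocol,
    A = data.frame(
      time_min = c(0, 5, 10, 30, 45, 60, 90, 105, 120, 150, 170),
      phase = c("baseline", "peak", "peak", "hypo", "hypo", "hypo",
                "hyper", "hyper", "hyper", "hypo", "hypo")),
    B = data.frame(
      time_min = c(0, 5, 10, 30, 50, 70, 90, 115, 125, 150, 170, 190),
      phase = c("baseline", "peak", "peak", rep("hypo", 4),
                "baseline", "baseline", rep("hypo", 3))),
    C = data.frame(
      time_min = c(0, 5, 10, 25, 40, 55, 75, 80, 100, 120, 150, 175),
      phase = c("baseline", "peak", "peak", rep("hypo", 9)))
  )
}

#' Read / write observation sets as CSV
#'
#' Columns: `time_min`, `pth_mean`, `pth_sd`, `phase`.
#' @param path File path.
#' @export
read_observations_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_min", "pth_mean", "pth_sd", "phase")
  if (!all(need %in% names(d)))
    stop("observation CSV must have columns: ", paste(need, collapse = ", "))
  observation_set(d$time_min, d$pth_mean, d$pth_sd, d$phase)
}

#' @param obs An [observation_set()].
#' @rdname read_observations_csv
#' @export
write_observations_csv <- function(obs, path) {
  stopifnot(inherits(obs, "observation_set"))
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE)
  invisible(path)
}

#' Z-scores of a simulated trajectory against observations
#'
#' `z_j = (sim(t_j) - mean_j) / sd_j`, with the simulation read at the
#' observation times by linear interpolation of the output grid.
#'
#' @param sim A `pth_sim` covering all observation times.
#' @param obs An [observation_set()].
#' @return Numeric z-scores, one per observation row.
#' @export
phase_zscores <- function(sim, obs) {
  stopifnot(inherits(obs, "observation_set"))
  (serum_at(sim, obs$time_min) - obs$pth_mean) / obs$pth_sd
}

#' Rejection gate on per-point z-scores
#'
#' A candidate model is retained iff every output lies within
#' `threshold_sd` standard deviations of the observed mean (inclusive):
#' `max_j |z_j| <= threshold_sd`. Outputs are treated independently.
#'
#' @param zscore_sets A list of z-score vectors, one per candidate model
#'   (or a single numeric vector for one model).
#' @param threshold_sd Gate width in SDs. Default 1.5.
#' @return Logical vector, `TRUE` for retained models.
#' @export
retain_models <- function(zscore_sets, threshold_sd = 1.5) {
  if (is.numeric(zscore_sets)) zscore_sets <- list(zscore_sets)
  vapply(zscore_sets, function(z) max(abs(z)) <= threshold_sd, TRUE)
}

#' Calibration stopping rule
#'
#' The population is accepted when the mean z-score product is below 0.1
#' and the largest |z| is below 0.75, where z-scores compare the
#' population-mean simulated outputs with the observations. "Z-score
#' product" is read as `z*z` (`rule = "mean-square"`); the alternative
#' reading, the mean of all pairwise products `z_j*z_k` (j < k), is
#' available as `rule = "pairwise-product"`.
#'
#' @param z Z-scores of the population-mean outputs.
#' @param rule `"mean-square"` or `"pairwise-product"`.
#' @param product_limit,max_limit Stopping thresholds (0.1 and 0.75).
#' @return Logical flag.
#' @export
calibration_converged <- function(z, rule = c("mean-square",
                                              "pairwise-product"),
                                  product_limit = 0.1, max_limit = 0.75) {
  rule <- match.arg(rule)
  prod_stat <- if (rule == "mean-square") mean(z^2) else {
    if (length(z) < 2) 0 else mean(utils::combn(z, 2, prod))
  }
  prod_stat < product_limit && max(abs(z)) < max_limit
}

#' Iterative rejection-sampling calibration with kernel re-estimation
#'
#' One iteration samples `n_models` candidate glands from the current
#' parameter distributions, simulates each under the clamp protocol,
#' computes per-point z-scores against the observations, and retains the
#' candidates whose outputs all fall within `threshold_sd` SDs
#' ([retain_models()]). The retained candidates' parameter draws are pooled
#' per parameter and smoothed into new kernel distributions
#' ([fit_kernel()]), which seed the next iteration. Iteration stops when
#' the retained population's mean outputs satisfy the
#' [calibration_converged()] rule, or after `max_iter` iterations.
#'
#' @param initial A [gland_spec()] of starting distributions
#'   (conventionally uniform priors, [table1_priors()]).
#' @param obs An [observation_set()].
#' @param protocol A `calcium_profile` (default the training protocol A).
#' @param n_models Candidate models per iteration. Default 2500.
#' @param threshold_sd Rejection gate width. Default 1.5.
#' @param max_iter Iteration cap. Default 20.
#' @param dt Integration step for candidate simulations (min). Default 0.5.
#' @param constants A [physio_constants()].
#' @param rule Stopping-rule reading, see [calibration_converged()].
#' @param seed Optional integer seed; the whole run is deterministic
#'   given it.
#' @param verbose Print per-iteration progress.
#' @return An object of class `calibration_result`: final `spec`
#'   (kernel distributions), per-iteration `history` (retained counts and
#'   z summaries), `converged`, `seed`, and the pooled retained draws of
#'   the final iteration (`retained_draws`).
#' @export
calibrate <- function(initial, obs, protocol = clamp_protocol("A"),
                      n_models = 2500, threshold_sd = 1.5, max_iter = 20,
                      dt = 0.5, constants = physio_constants(),
                      rule = "mean-square", seed = NULL, verbose = FALSE) {
  stopifnot(inherits(initial, "gland_spec"), inherits(obs, "observation_set"))
  if (n_models < 1) stop("calibrate: n_models must be >= 1")
  if (max(obs$time_min) > protocol$t_end)
    stop("calibrate: observations extend beyond the protocol")
  if (!is.null(seed)) set.seed(seed)
  t_end <- min(protocol$t_end, max(obs$time_min) + 2 * dt)
  par_names <- c("k_v1", "k_v2", "beta", "gamma_c", "m1", "m2", "k_d1", "k_d2")
  spec <- initial
  history <- NULL
  converged <- FALSE
  retained_draws <- NULL

  for (iter in seq_len(max_iter)) {
    draws <- vector("list", n_models)
    sims <- matrix(NA_real_, n_models, nrow(obs))
    for (i in seq_len(n_models)) {
      g <- sample_gland(spec)
      p <- g$params
      draws[[i]] <- list(
        k_v1 = p$k_v[p$sensitive], k_v2 = p$k_v[!p$sensitive],
        beta = p$beta, gamma_c = p$gamma_c,
        m1 = p$m[p$sensitive], m2 = p$m[!p$sensitive],
        k_d1 = p$k_d[p$sensitive], k_d2 = p$k_d[!p$sensitive])
      sim <- simulate_gland(g, protocol, constants, dt = dt, t_end = t_end)
      sims[i, ] <- serum_at(sim, obs$time_min)
    }
    z <- sweep(sweep(sims, 2, obs$pth_mean), 2, obs$pth_sd, "/")
    keep <- apply(abs(z), 1, max) <= threshold_sd
    if (!any(keep)) {
      worst <- obs$phase[which.max(colMeans(abs(z)))]
      stop("calibrate: no models retained in iteration ", iter,
           " (worst-matched phase: ", worst, ")")
    }
    pooled <- lapply(par_names, function(nm)
      unlist(lapply(draws[keep], `[[`, nm), use.names = FALSE))
    names(pooled) <- par_names
    newdists <- lapply(par_names, function(nm)
      fit_kernel(pooled[[nm]],
                 support = if (nm == "beta") c(0, 1) else c(0, Inf)))
    names(newdists) <- par_names
    spec <- do.call(gland_spec,
                    c(newdists, list(n_pairs = initial$n_pairs,
                                     k_deg = initial$k_deg)))
    mean_out <- colMeans(sims[keep, , drop = FALSE])
    zbar <- (mean_out - obs$pth_mean) / obs$pth_sd
    converged <- calibration_converged(zbar, rule = rule)
    history <- rbind(history, data.frame(
      iteration = iter, n_sampled = n_models, n_retained = sum(keep),
      mean_sq_z = mean(zbar^2), max_abs_z = max(abs(zbar)),
      converged = converged))
    if (verbose)
      message(sprintf(
        "iter %d: retained %d/%d, mean z^2 = %.3f, max |z| = %.3f%s",
        iter, sum(keep), n_models, mean(zbar^2), max(abs(zbar)),
        if (converged) " [converged]" else ""))
    retained_draws <- pooled
    if (converged) break
  }
  structure(list(spec = spec, history = history, converged = converged,
                 seed = seed, obs = obs, retained_draws = retained_draws,
                 settings = list(n_models = n_models,
                                 threshold_sd = threshold_sd,
                                 max_iter = max_iter, dt = dt, rule = rule)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  h <- x$history
  cat(sprintf("<calibration_result> %d iteration(s), %s\n", nrow(h),
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  last: retained %d/%d, mean z^2 = %.3f, max |z| = %.3f\n",
              h$n_retained[nrow(h)], h$n_sampled[nrow(h)],
              h$mean_sq_z[nrow(h)], h$max_abs_z[nrow(h)]))
  invisible(x)
}

#' @export
summary.calibration_result <- function(object, ...) {
  means <- vapply(c("k_v1", "k_v2", "beta", "gamma_c", "m1", "m2",
                    "k_d1", "k_d2"),
                  function(nm) dist_mean(object$spec[[nm]]), 0)
  list(history = object$history, converged = object$converged,
       posterior_means = means)
}

#' Write a calibration report as JSON
#'
#' @param result A `calibration_result`.
#' @param path Output path.
#' @export
write_calibration_json <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  s <- summary(result)
  jsonlite::write_json(
    list(converged = result$converged, seed = result$seed,
         settings = result$settings,
         posterior_means = as.list(s$posterior_means),
         history = result$history),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
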