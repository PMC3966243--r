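#' Steady-state calcium–PTH curve of a gland
#'
#' Evaluates the closed-form steady state ([steady_state()]) over a calcium
#' grid. Intracellular stores re-equilibrate at every calcium level, so
#' this is the long-exposure (chronic) dose–response relationship; it is
#' non-increasing in calcium.
#'
#' @param gland A [gland_model()].
#' @param constants A [physio_constants()].
#' @param ca_grid Increasing positive calcium grid (mmol/L). Default
#'   0.6–1.8 by 0.005.
#' @return A data frame (class `pth_curve`) with columns `ca` and `pth`.
#' @export
steady_curve <- function(gland, constants = physio_constants(),
                         ca_grid = seq(0.6, 1.8, by = 0.005)) {
  check_grid(ca_grid)
  k_cl <- clearance_constant(constants)
  p <- gland$params
  pth <- vapply(ca_grid, function(ca) {
    f <- gland_fractions(ca, gland)
    sum(f * p$k_v / (p$k_deg + f)) / k_cl
  }, 0)
  structure(data.frame(ca = ca_grid, pth = pth),
            class = c("pth_curve", "data.frame"))
}

#' Acute secretion dose–response curve at baseline-equilibrated stores
#'
#' The instantaneous secretion response: intracellular stores are fixed at
#' their steady state for `baseline` calcium, and calcium is swept without
#' letting the stores re-equilibrate — the situation of acute secretion
#' experiments on dispersed cells, where sampling is fast relative to
#' store turnover. Secretion is expressed as the equivalent serum PTH
#' (divided by clearance) so the curve shares the units and scale of
#' [steady_curve()]. Because suppressed (sensitive) populations hold large
#' stores at baseline, this curve is considerably steeper than the
#' re-equilibrated steady-state curve; it is the appropriate comparator
#' for empirical four-parameter secretion sigmoids (see
#' [fit_four_param()]).
#'
#' @inheritParams steady_curve
#' @param baseline Calcium (mmol/L) at which stores are equilibrated.
#'   Default 1.25.
#' @return A data frame (class `pth_curve`) with columns `ca` and `pth`.
#' @export
acute_response_curve <- function(gland, constants = physio_constants(),
                                 ca_grid = seq(0.6, 1.8, by = 0.005),
                                 baseline = 1.25) {
  check_grid(ca_grid)
  v0 <- steady_state(baseline, gland, constants)$vpth
  k_cl <- clearance_constant(constants)
  pth <- vapply(ca_grid, function(ca)
    sum(gland_fractions(ca, gland) * v0) / k_cl, 0)
  structure(data.frame(ca = ca_grid, pth = pth),
            class = c("pth_curve", "data.frame"))
}

check_grid <- function(ca_grid) {
  if (any(ca_grid <= 0) || any(diff(ca_grid) <= 0))
    stop("ca_grid must be positive and strictly increasing")
}

#' @export
plot.pth_curve <- function(x, ...) {
  graphics::plot(x$ca, x$pth, type = "l",
                 xlab = "ionized calcium (mmol/L)", ylab = "PTH", ...)
  invisible(x)
}

# first calcium at which the descending normalized curve crosses `level`
cross_descending <- function(ca, yn, level) {
  below <- yn[-1] <= level & yn[-length(yn)] > level
  i <- which(below)[1]
  if (is.na(i)) return(NA_real_)
  ca[i] + (yn[i] - level) / (yn[i] - yn[i + 1]) * (ca[i + 1] - ca[i])
}

#' 10–90% slope of a calcium–PTH curve
#'
#' Normalizes the (descending) curve to percent, locates the calcium
#' values where it crosses the 90% and 10% levels by linear interpolation,
#' and returns the magnitude of the slope between them,
#' `(90 - 10) / (ca_10 - ca_90)`, in %/(mmol/L).
#'
#' With `normalize = "range"` (default) percent is of the min–max span —
#' required for curves whose minimum stays well above zero, as secretion
#' is never fully suppressed. `normalize = "max"` uses percent of the raw
#' maximum; both coincide when the minimum is zero. The statistic is
#' invariant under rescaling of the PTH axis.
#'
#' @param curve A `pth_curve` (or data frame with `ca`, `pth`).
#' @param normalize `"range"` or `"max"`.
#' @return Slope magnitude in %/(mmol/L).
#' @export
slope_10_90 <- function(curve, normalize = c("range", "max")) {
  normalize <- match.arg(normalize)
  ca <- curve$ca; y <- curve$pth
  if (max(y) - min(y) <= .Machine$double.eps * max(abs(y), 1) * 100)
    stop("slope_10_90: flat curve")
  yn <- if (normalize == "range") {
    (y - min(y)) / (max(y) - min(y)) * 100
  } else y / max(y) * 100
  ca90 <- cross_descending(ca, yn, 90)
  ca10 <- cross_descending(ca, yn, 10)
  if (is.na(ca90) || is.na(ca10))
    stop("slope_10_90: curve does not cross both the 10% and 90% levels")
  80 / (ca10 - ca90)
}

#' Four-parameter sigmoid fit (empirical secretion model)
#'
#' Least-squares fit of the classical four-parameter description of the
#' calcium–PTH relationship,
#' `PTH(ca) = D + (A - D) / (1 + (ca/C)^B)`,
#' with maximum `A`, minimum `D`, midpoint (set point) `C` and sensitivity
#' `B`. Initialization: `A`/`D` from the curve extremes, `C` from the
#' half-height crossing, `B` from a coarse grid, each refined by
#' Levenberg–Marquardt; the best-RSS solution is returned. The fitted `B`
#' is invariant under rescaling of the PTH axis.
#'
#' @param curve A `pth_curve` (>= 6 points spanning the transition).
#' @param b_grid Coarse initialization grid for `B`.
#' @return An object of class `four_param_fit` with `coefficients`
#'   (A, D, C, B), `rss`, `fitted`, and the data.
#' @examples
#' ca <- seq(0.8, 1.6, by = 0.01)
#' y <- 1 + (10 - 1) / (1 + (ca / 1.2)^8)
#' coef(fit_four_param(data.frame(ca = ca, pth = y)))
#' @export
fit_four_param <- function(curve, b_grid = c(2, 4, 8, 16, 32, 64)) {
  ca <- curve$ca; y <- curve$pth
  if (length(ca) < 6) stop("fit_four_param: need at least 6 points")
  A0 <- max(y); D0 <- min(y)
  if (A0 - D0 <= .Machine$double.eps * max(abs(A0), 1) * 100)
    stop("fit_four_param: flat curve; sensitivity is indeterminate")
  yn <- (y - D0) / (A0 - D0)
  C0 <- cross_descending(ca, yn, 0.5)
  if (is.na(C0)) C0 <- stats::median(ca)
  dat <- data.frame(ca = ca, y = y)
  best <- NULL
  for (b0 in b_grid) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        y ~ D + (A - D) / (1 + (ca / C)^B), data = dat,
        start = list(A = A0, D = D0, C = C0, B = b0),
        lower = c(-Inf, -Inf, min(ca) / 10, 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || stats::deviance(f) < stats::deviance(best)))
      best <- f
  }
  if (is.null(best))
    stop("fit_four_param: no starting point converged")
  cf <- stats::coef(best)
  if (cf["A"] <= cf["D"])
    stop("fit_four_param: fit degenerate (A <= D)")
  structure(list(coefficients = cf, rss = stats::deviance(best),
                 fitted = stats::fitted(best), data = dat),
            class = "four_param_fit")
}

#' @export
coef.four_param_fit <- function(object, ...) object$coefficients

#' @export
print.four_param_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf(
    "<four_param_fit> A=%.4g D=%.4g C=%.4g mmol/L B=%.4g (RSS %.4g)\n",
    cf["A"], cf["D"], cf["C"], cf["B"], x$rss))
  invisible(x)
}

#' @param newdata Optional data frame with a `ca` column.
#' @rdname fit_four_param
#' @param object A `four_param_fit`.
#' @param ... Unused.
#' @export
predict.four_param_fit <- function(object, newdata = NULL, ...) {
  ca <- if (is.null(newdata)) object$data$ca else newdata$ca
  cf <- object$coefficients
  unname(cf["D"] + (cf["A"] - cf["D"]) / (1 + (ca / cf["C"])^cf["B"]))
}

#' @export
residuals.four_param_fit <- function(object, ...) {
  object$data$y - object$fitted
}

#' Pointwise ensemble confidence band
#'
#' Simulates `n_runs` freshly sampled glands under the protocol and takes
#' pointwise quantiles of the member serum-PTH trajectories (default the
#' 2.5% and 97.5% quantiles, a pointwise 95% band).
#'
#' @param spec A [gland_spec()] to sample members from.
#' @param protocol A `calcium_profile`.
#' @param n_runs Ensemble size (>= 2). Default 25.
#' @param constants A [physio_constants()].
#' @param dt Integration step (min).
#' @param level Band coverage level. Default 0.95.
#' @param seed Optional integer seed.
#' @return An object of class `ensemble_band`: data frame `t`, `lower`,
#'   `upper`, `mean`, with member trajectories in attribute `"members"`.
#' @export
ensemble_band <- function(spec, protocol, n_runs = 25,
                          constants = physio_constants(), dt = 0.5,
                          level = 0.95, seed = NULL) {
  if (n_runs < 2) stop("ensemble_band: need n_runs >= 2")
  if (!is.null(seed)) set.seed(seed)
  sims <- lapply(seq_len(n_runs), function(i)
    simulate_gland(sample_gland(spec), protocol, constants, dt = dt))
  tt <- sims[[1]]$t
  mem <- vapply(sims, function(s) s$serum_pth, numeric(length(tt)))
  a <- (1 - level) / 2
  qs <- apply(mem, 1, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  out <- data.frame(t = tt, lower = qs[1, ], upper = qs[2, ],
                    mean = rowMeans(mem))
  attr(out, "members") <- mem
  attr(out, "level") <- level
  class(out) <- c("ensemble_band", "data.frame")
  out
}

#' @export
print.ensemble_band <- function(x, ...) {
  cat(sprintf("<ensemble_band> %d members, %d time points, level %.2f\n",
              ncol(attr(x, "members")), nrow(x), attr(x, "level")))
  invisible(x)
}

#' @export
plot.ensemble_band <- function(x, ...) {
  graphics::plot(x$t, x$mean, type = "n", ylim = range(x$lower, x$upper),
                 xlab = "time (min)", ylab = "serum PTH", ...)
  graphics::polygon(c(x$t, rev(x$t)), c(x$lower, rev(x$upper)),
                    col = "grey85", border = NA)
  graphics::lines(x$t, x$mean)
  invisible(x)
}

#' Write an ensemble band as CSV (`t`, `lower`, `upper`, `mean`)
#' @param band An `ensemble_band`.
#' @param path Output path.
#' @export
write_band_csv <- function(band, path) {
  utils::write.csv(as.data.frame(band), path, row.names = FALSE)
  invisible(path)
}

#' Fraction of observed points inside a pointwise band
#'
#' @param band An `ensemble_band` (or data frame with `t`, `lower`,
#'   `upper`).
#' @param times,values Observation times and values; times must lie in the
#'   band's range.
#' @return Percentage of points with `lower(t) <= value <= upper(t)`.
#' @export
coverage <- function(band, times, values) {
  if (length(times) != length(values))
    stop("coverage: times and values must share a length")
  if (any(times < min(band$t) - 1e-9) || any(times > max(band$t) + 1e-9))
    stop("coverage: observation times outside the band's range")
  lo <- stats::approx(band$t, band$lower, times, rule = 2)$y
  hi <- stats::approx(band$t, band$upper, times, rule = 2)$y
  100 * mean(values >= lo & values <= hi)
}

#' Dynamic-direction agreement between model and observations
#'
#' For each consecutive pair of shared time points the sign of the change
#' is compared between model and observation; changes smaller in magnitude
#' than `dead_band` count as "no change" (sign zero). Agreement requires
#' equal signs.
#'
#' @param model_series,obs_series Data frames with columns `time` and
#'   `value`, on identical time grids (>= 2 points).
#' @param dead_band Magnitude below which a change counts as zero.
#'   Default 0.5 (model PTH units).
#' @return A list with `n_agree`, `n_total` and the per-interval signs.
#' @export
direction_score <- function(model_series, obs_series, dead_band = 0.5) {
  if (nrow(model_series) != nrow(obs_series) ||
      any(abs(model_series$time - obs_series$time) > 1e-9))
    stop("direction_score: series must share an identical time grid")
  if (nrow(model_series) < 2) stop("direction_score: need >= 2 points")
  sgn <- function(d) ifelse(abs(d) < dead_band, 0, sign(d))
  sm <- sgn(diff(model_series$value))
  so <- sgn(diff(obs_series$value))
  list(n_agree = sum(sm == so), n_total = length(sm),
       model_sign = sm, obs_sign = so)
}

#' Memoryless prediction from a four-parameter fit
#'
#' Applies the fitted steady-state sigmoid pointwise to the calcium
#' profile: `PTH(t) = fourparam(ca(t))`. Identical calcium values map to
#' identical PTH regardless of history, so this comparator exhibits
#' exactly zero hysteresis.
#'
#' @param fit A `four_param_fit`.
#' @param profile A `calcium_profile`.
#' @param times Evaluation times within the profile domain.
#' @return A data frame with `t`, `ca` and `pth`.
#' @export
brown_prediction <- function(fit, profile, times) {
  stopifnot(inherits(fit, "four_param_fit"))
  ca <- ca_at(profile, times)
  data.frame(t = times, ca = ca,
             pth = predict(fit, newdata = data.frame(ca = ca)))
}

#' Sum of squared residuals of a simulation against observed points
#'
#' @param sim A `pth_sim`.
#' @param times,values Observation times (within the simulated range) and
#'   values.
#' @return `sum((sim(t_j) - value_j)^2)`.
#' @export
squared_residuals <- function(sim, times, values) {
  if (length(times) != length(values))
    stop("squared_residuals: times and values must share a length")
  sum((serum_at(sim, times) - values)^2)
}

#' Area of the hysteresis loop in the calcium–PTH plane
#'
#' Shoelace (polygon) area of the closed trajectory traced by
#' `(ca(t), pth(t))`. A memoryless calcium–PTH mapping retraces its path
#' and encloses zero area; storage-driven hysteresis encloses a positive
#' area.
#'
#' @param ca,pth Trajectory coordinates (equal length, the path is closed
#'   implicitly).
#' @return Non-negative loop area (mmol/L × PTH units).
#' @export
hysteresis_loop_area <- function(ca, pth) {
  if (length(ca) != length(pth))
    stop("hysteresis_loop_area: ca and pth must share a length")
  n <- length(ca)
  i2 <- c(2:n, 1)
  abs(sum(ca * pth[i2] - ca[i2] * pth)) / 2
}

#' Prominence of a late-window secretion peak
#'
#' Height of the maximal serum PTH inside a time window above the larger
#' of the window's endpoint values. A trajectory that is monotone across
#' the window has zero prominence; an interior peak has positive
#' prominence. Used to test for the secondary secretion peak that appears
#' when progressively deeper hypocalcemia recruits previously silent
#' subpopulations.
#'
#' @param sim A `pth_sim`.
#' @param window `c(t_start, t_end)` within the simulated range.
#' @return Non-negative prominence (serum PTH units).
#' @export
peak_prominence <- function(sim, window) {
  stopifnot(inherits(sim, "pth_sim"), length(window) == 2)
  w <- sim$serum_pth[sim$t >= window[1] & sim$t <= window[2]]
  if (!length(w)) stop("peak_prominence: empty window")
  max(0, max(w) - max(w[1], w[length(w)]))
}
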