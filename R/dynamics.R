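#' System state: compartment concentrations and intracellular stores
#'
#' @param t Time (min).
#' @param serum_pth Serum PTH concentration (pmol/L model units, >= 0).
#' @param isf_pth Interstitial PTH concentration (>= 0).
#' @param vpth Per-population intracellular PTH amounts (>= 0).
#' @return An object of class `system_state`.
#' @export
system_state <- function(t, serum_pth, isf_pth, vpth) {
  if (serum_pth < 0 || isf_pth < 0 || any(vpth < 0))
    stop("system_state: concentrations and stores must be >= 0")
  structure(list(t = t, serum_pth = serum_pth, isf_pth = isf_pth,
                 vpth = as.numeric(vpth)), class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system_state t=%g> serum %.4g, isf %.4g, total store %.4g\n",
              x$t, x$serum_pth, x$isf_pth, sum(x$vpth)))
  invisible(x)
}

#' Time derivatives of the PTH system
#'
#' For each subpopulation i with secretion fraction `f_i(ca)`:
#' `dVPTH_i/dt = k_v,i - (k_deg,i + f_i) * VPTH_i`. Total secretion
#' `S = sum(f_i * VPTH_i)` (amount/min) is delivered to serum. The
#' serum–interstitial exchange mass flux is
#' `J = exchange_fraction * (serum - isf) * serum_volume` (amount/min,
#' positive toward the interstitium), and
#' `d(serum)/dt = (S - k_cl*serum - J)/serum_volume`,
#' `d(isf)/dt = J/isf_volume`.
#'
#' @param state A [system_state()] whose `vpth` length matches the gland.
#' @param ca Serum ionized calcium (mmol/L, >= 0).
#' @param gland A [gland_model()].
#' @param constants A [physio_constants()].
#' @return A list with `dvpth`, `dserum_pth`, `disf_pth`, and the
#'   diagnostic fluxes `secretion` and `exchange` (amount/min).
#' @export
pth_derivatives <- function(state, ca, gland, constants = physio_constants()) {
  stopifnot(inherits(state, "system_state"), inherits(gland, "gland_model"))
  n <- n_populations(gland)
  if (length(state$vpth) != n)
    stop("pth_derivatives: state has ", length(state$vpth),
         " stores but gland has ", n, " populations")
  f <- gland_fractions(ca, gland)
  p <- gland$params
  S <- sum(f * state$vpth)
  J <- constants$exchange_fraction * (state$serum_pth - state$isf_pth) *
    constants$serum_volume
  k_cl <- clearance_constant(constants)
  list(
    dvpth = p$k_v - (p$k_deg + f) * state$vpth,
    dserum_pth = (S - k_cl * state$serum_pth - J) / constants$serum_volume,
    disf_pth = J / constants$isf_volume,
    secretion = S, exchange = J
  )
}

#' Closed-form steady state at fixed calcium
#'
#' At constant calcium the stores settle at
#' `VPTH_i* = k_v,i / (k_deg,i + f_i(ca))`, there is no net compartment
#' exchange (`isf* = serum*`), and serum PTH balances secretion against
#' clearance: `serum* = sum(f_i * VPTH_i*) / k_cl`.
#'
#' @inheritParams pth_derivatives
#' @return A [system_state()] (with `t = 0`).
#' @export
steady_state <- function(ca, gland, constants = physio_constants()) {
  stopifnot(inherits(gland, "gland_model"))
  k_cl <- clearance_constant(constants)
  if (k_cl <= 0)
    stop("steady_state: zero clearance has no finite steady state")
  f <- gland_fractions(ca, gland)
  vpth <- gland$params$k_v / (gland$params$k_deg + f)
  serum <- sum(f * vpth) / k_cl
  system_state(0, serum, serum, vpth)
}

#' Simulate the gland under a calcium clamp profile
#'
#' Deterministic fixed-step integration (classical Runge–Kutta 4 via
#' \pkg{deSolve}) of the store/serum/interstitium system forced by a
#' calcium profile.
#'
#' @param gland A [gland_model()].
#' @param profile A `calcium_profile` defined on `[0, t_end]`.
#' @param constants A [physio_constants()].
#' @param dt Integration step (min). Default 0.1.
#' @param t_end End time (min); defaults to the profile's domain end.
#' @param init `"steady"` (start at the steady state for `profile(0)`) or a
#'   [system_state()].
#' @param keep_vpth Keep the per-population store trajectories (matrix
#'   attribute `"vpth"`). Default `FALSE`.
#' @return An object of class `pth_sim`: a data frame with columns `t`,
#'   `ca`, `serum_pth`, `isf_pth`, `secretion` (amount/min) and attributes
#'   `gland`, `constants`, `dt`, `profile_name`.
#' @examples
#' g <- gland_model(list(
#'   cell_params(3.6, 0.5, 0.0032, 270, 1.13, sensitive = TRUE),
#'   cell_params(2.1, 0.5, 0.0032, 244, 1.27, sensitive = FALSE)))
#' sim <- simulate_gland(g, clamp_protocol("A"), dt = 0.5)
#' head(sim)
#' @export
simulate_gland <- function(gland, profile, constants = physio_constants(),
                           dt = 0.1, t_end = NULL, init = "steady",
                           keep_vpth = FALSE) {
  stopifnot(inherits(gland, "gland_model"),
            inherits(profile, "calcium_profile"))
  if (!is.numeric(dt) || dt <= 0) stop("simulate_gland: dt must be > 0")
  if (is.null(t_end)) t_end <- profile$t_end
  if (t_end > profile$t_end + 1e-9)
    stop("simulate_gland: profile undefined beyond t = ", profile$t_end)
  state0 <- if (identical(init, "steady")) {
    steady_state(ca_at(profile, 0), gland, constants)
  } else if (inherits(init, "system_state")) init else
    stop("simulate_gland: init must be \"steady\" or a system_state")
  n <- n_populations(gland)
  if (length(state0$vpth) != n)
    stop("simulate_gland: init state does not match the gland")

  p <- gland$params
  k_cl <- clearance_constant(constants)
  Vs <- constants$serum_volume; Vi <- constants$isf_volume
  ex <- constants$exchange_fraction
  logkd <- log(p$k_d)
  deriv <- function(t, y, parms) {
    ca <- profile$fun(min(t, profile$t_end))
    r <- exp(pmin(p$m * (log(max(ca, .Machine$double.xmin)) - logkd), 700))
    f <- pmin(p$gamma_c + (p$beta - p$gamma_c) / (1 + r), p$beta)
    v <- y[seq_len(n)]
    S <- sum(f * v)
    J <- ex * (y[n + 1L] - y[n + 2L]) * Vs
    list(c(p$k_v - (p$k_deg + f) * v,
           (S - k_cl * y[n + 1L] - J) / Vs,
           J / Vi))
  }
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  y0 <- c(state0$vpth, state0$serum_pth, state0$isf_pth)
  out <- deSolve::ode(y0, times, deriv, parms = NULL, method = "rk4")

  ca_t <- ca_at(profile, out[, 1])
  vmat <- out[, 1 + seq_len(n), drop = FALSE]
  fmat <- vapply(ca_t, gland_fractions, numeric(n), gland = gland)
  secretion <- colSums(t(vmat) * fmat)
  res <- data.frame(t = out[, 1], ca = ca_t,
                    serum_pth = out[, n + 2L], isf_pth = out[, n + 3L],
                    secretion = secretion)
  attr(res, "gland") <- gland
  attr(res, "constants") <- constants
  attr(res, "dt") <- dt
  attr(res, "profile_name") <- profile$name
  if (keep_vpth) attr(res, "vpth") <- vmat
  class(res) <- c("pth_sim", "data.frame")
  res
}

#' @export
print.pth_sim <- function(x, ...) {
  cat(sprintf("<pth_sim '%s'> %d steps, 0-%g min (dt=%g)\n",
              attr(x, "profile_name"), nrow(x), max(x$t), attr(x, "dt")))
  cat(sprintf("  serum PTH: start %.4g, peak %.4g, end %.4g\n",
              x$serum_pth[1], max(x$serum_pth), x$serum_pth[nrow(x)]))
  invisible(x)
}

#' @export
plot.pth_sim <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t, x$ca, type = "l", xlab = "", ylab = "Ca (mmol/L)", ...)
  graphics::plot(x$t, x$serum_pth, type = "l", xlab = "time (min)",
                 ylab = "serum PTH", ...)
  invisible(x)
}

#' Interpolate simulated serum PTH at arbitrary times
#'
#' @param sim A `pth_sim`.
#' @param times Times within the simulated range.
#' @return Serum PTH values at `times` (linear interpolation of the output
#'   grid).
#' @export
serum_at <- function(sim, times) {
  stopifnot(inherits(sim, "pth_sim"))
  if (any(times < min(sim$t) - 1e-9) || any(times > max(sim$t) + 1e-9))
    stop("serum_at: requested times outside the simulated range")
  stats::approx(sim$t, sim$serum_pth, times, rule = 2)$y
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Mass bookkeeping over a simulation
#'
#' Integrates the secretion and clearance fluxes over the simulated
#' interval (trapezoid rule on the output grid) and compares them with the
#' change in total extracellular PTH mass: conservation requires
#' `secreted - cleared = delta(serum mass) + delta(interstitial mass)`.
#'
#' @param sim A `pth_sim`.
#' @return A list with `secreted`, `cleared`, `delta_mass`, and `residual`
#'   (= secreted − cleared − delta_mass; zero up to integration error).
#' @export
mass_balance <- function(sim) {
  stopifnot(inherits(sim, "pth_sim"))
  const <- attr(sim, "constants")
  k_cl <- clearance_constant(const)
  secreted <- trapz(sim$t, sim$secretion)
  cleared <- trapz(sim$t, k_cl * sim$serum_pth)
  n <- nrow(sim)
  dmass <- const$serum_volume * (sim$serum_pth[n] - sim$serum_pth[1]) +
    const$isf_volume * (sim$isf_pth[n] - sim$isf_pth[1])
  list(secreted = secreted, cleared = cleared, delta_mass = dmass,
       residual = secreted - cleared - dmass)
}
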