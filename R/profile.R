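#' Idealized calcium clamp protocols
#'
#' Builds the piecewise-linear serum ionized-calcium profiles of the three
#' clamp experiments the model is trained and validated on. All offsets are
#' relative to the subject's baseline calcium; plateaus are joined by linear
#' ramps of `ramp_min` minutes.
#'
#' * **A** (training): hypocalcemia (−0.20 mmol/L) through 75 min, a brief
#'   hypercalcemic phase (+0.20 mmol/L) whose plateau spans 90–120 min,
#'   then re-induced hypocalcemia whose plateau spans 150–170 min
#'   (total 200 min).
#' * **B** (validation): hypocalcemia (−0.20) through 100 min, a brief
#'   return to normocalcemia (110–130 min), then hypocalcemia again
#'   (total 200 min).
#' * **C** (validation): hypocalcemia (−0.20) through 60 min, then extreme
#'   hypocalcemia (−0.40) to 180 min.
#'
#' @param protocol `"A"`, `"B"` or `"C"`.
#' @param baseline Baseline ionized calcium (mmol/L). Default 1.25.
#' @param ramp_min Linear ramp duration between plateaus (min, <= 15 so the
#'   plateaus cover the standard sampling windows). Default 10.
#' @return A `calcium_profile` object: callable time -> mmol/L on
#'   `[0, t_end]`.
#' @examples
#' pr <- clamp_protocol("A")
#' ca_at(pr, c(0, 45, 105, 160))
#' @export
clamp_protocol <- function(protocol = c("A", "B", "C"), baseline = 1.25,
                           ramp_min = 10) {
  protocol <- match.arg(protocol)
  if (!is.numeric(baseline) || baseline <= 0.4)
    stop("clamp_protocol: baseline must exceed 0.4 mmol/L")
  if (ramp_min <= 0 || ramp_min > 15)
    stop("clamp_protocol: ramp_min must lie in (0, 15] minutes")
  r <- ramp_min
  kn <- switch(protocol,
    A = list(t = c(0, r, 75, 75 + r, 130, 130 + r, 200),
             off = c(0, -0.2, -0.2, 0.2, 0.2, -0.2, -0.2)),
    B = list(t = c(0, r, 100, 100 + r, 130, 130 + r, 200),
             off = c(0, -0.2, -0.2, 0, 0, -0.2, -0.2)),
    C = list(t = c(0, r, 60, 60 + r, 180),
             off = c(0, -0.2, -0.2, -0.4, -0.4))
  )
  ca <- baseline + kn$off
  if (any(ca <= 0))
    stop("clamp_protocol: offsets drive calcium non-positive at this baseline")
  new_profile(kn$t, ca, baseline = baseline,
              name = paste0("protocol_", protocol))
}

new_profile <- function(times, values, baseline, name, fun = NULL) {
  if (is.null(fun)) fun <- stats::approxfun(times, values, rule = 1)
  structure(
    list(fun = fun, knots = data.frame(time = times, ca = values),
         baseline = baseline, t_end = max(times), name = name),
    class = "calcium_profile"
  )
}

#' Evaluate a calcium profile
#'
#' @param profile A `calcium_profile`.
#' @param t Time(s) in minutes; must lie within `[0, t_end]`.
#' @return Calcium concentration(s) in mmol/L.
#' @export
ca_at <- function(profile, t) {
  stopifnot(inherits(profile, "calcium_profile"))
  if (any(!is.finite(t)) || any(t < 0) || any(t > profile$t_end + 1e-9))
    stop("ca_at: time outside the profile domain [0, ", profile$t_end, "]")
  profile$fun(pmin(t, profile$t_end))
}

#' Calcium profile through user-supplied (minute, mmol/L) points
#'
#' Interpolates a table of clamp measurements into a continuous profile,
#' exact at the knots. `"linear"` uses piecewise-linear interpolation;
#' `"pchip"` a monotonicity-preserving cubic Hermite interpolant
#' (no overshoot between knots).
#'
#' @param time Strictly increasing times (min), length >= 2.
#' @param ca Calcium values (mmol/L, > 0), same length.
#' @param interpolation `"linear"` or `"pchip"`.
#' @param baseline Baseline calcium; defaults to `ca[1]`.
#' @return A `calcium_profile`.
#' @export
profile_from_table <- function(time, ca,
                               interpolation = c("linear", "pchip"),
                               baseline = ca[1]) {
  interpolation <- match.arg(interpolation)
  if (length(time) < 2L || length(ca) != length(time))
    stop("profile_from_table: need >= 2 (time, ca) pairs of equal length")
  if (any(diff(time) <= 0))
    stop("profile_from_table: times must be strictly increasing")
  if (any(!is.finite(ca)) || any(ca <= 0))
    stop("profile_from_table: calcium values must be positive")
  if (time[1] != 0) {
    # anchor the domain at 0 by holding the first value
    time <- c(0, time); ca <- c(ca[1], ca)
  }
  fun <- if (interpolation == "linear") {
    stats::approxfun(time, ca, rule = 1)
  } else {
    stats::splinefun(time, ca, method = "monoH.FC")
  }
  new_profile(time, ca, baseline = baseline, name = "table", fun = fun)
}

#' Read / write calcium profiles as CSV
#'
#' The CSV format is two columns, `time_min` and `ca_mmol_L`.
#'
#' @param path File path.
#' @param interpolation Passed to [profile_from_table()].
#' @return `read_calcium_csv()` returns a `calcium_profile`;
#'   `write_calcium_csv()` invisibly returns `path`.
#' @export
read_calcium_csv <- function(path, interpolation = "linear") {
  d <- utils::read.csv(path)
  need <- c("time_min", "ca_mmol_L")
  if (!all(need %in% names(d)))
    stop("profile CSV must have columns: ", paste(need, collapse = ", "))
  profile_from_table(d$time_min, d$ca_mmol_L, interpolation)
}

#' @param profile A `calcium_profile`.
#' @rdname read_calcium_csv
#' @export
write_calcium_csv <- function(profile, path) {
  stopifnot(inherits(profile, "calcium_profile"))
  utils::write.csv(
    data.frame(time_min = profile$knots$time, ca_mmol_L = profile$knots$ca),
    path, row.names = FALSE)
  invisible(path)
}

#' @export
print.calcium_profile <- function(x, ...) {
  cat(sprintf("<calcium_profile '%s'> baseline %.3g mmol/L, 0-%g min, %d knots\n",
              x$name, x$baseline, x$t_end, nrow(x$knots)))
  invisible(x)
}

#' @export
plot.calcium_profile <- function(x, n = 501, ...) {
  t <- seq(0, x$t_end, length.out = n)
  graphics::plot(t, ca_at(x, t), type = "l", xlab = "time (min)",
                 ylab = "ionized calcium (mmol/L)", main = x$name, ...)
  invisible(x)
}
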