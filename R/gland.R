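#' A virtual parathyroid gland: a collection of cell subpopulations
#'
#' A gland is an ordered set of subpopulations (default 40 = 20 sensitive +
#' 20 insensitive pairs), each a [cell_params()], together with the current
#' intracellular PTH store (`vpth`) of each subpopulation.
#'
#' @param populations A list of [cell_params()] objects. The count must be
#'   even with exactly half flagged sensitive (the 50–50 partition).
#' @param vpth Optional numeric vector of intracellular stores (amount
#'   units, >= 0), one per population. Defaults to 0; most workflows
#'   initialize stores at steady state via [steady_state()] or
#'   [simulate_gland()].
#'
#' @return An object of class `gland_model`: a list with a parameter table
#'   (`params`, one row per population) and `vpth`.
#' @examples
#' g <- gland_model(list(
#'   cell_params(3.6, 0.5, 0.0032, 270, 1.13, sensitive = TRUE),
#'   cell_params(2.1, 0.5, 0.0032, 244, 1.27, sensitive = FALSE)))
#' steady_state(1.25, g)
#' @export
gland_model <- function(populations, vpth = NULL) {
  if (!is.list(populations) || !length(populations) ||
      !all(vapply(populations, inherits, TRUE, "cell_params")))
    stop("gland_model: 'populations' must be a list of cell_params")
  n <- length(populations)
  sens <- vapply(populations, function(p) p$sensitive, TRUE)
  if (n %% 2L != 0L || sum(sens) != n / 2L)
    stop("gland_model: population count must be even with exactly half ",
         "flagged sensitive")
  params <- data.frame(
    k_v     = vapply(populations, `[[`, 0, "k_v"),
    beta    = vapply(populations, `[[`, 0, "beta"),
    gamma_c = vapply(populations, `[[`, 0, "gamma_c"),
    m       = vapply(populations, `[[`, 0, "m"),
    k_d     = vapply(populations, `[[`, 0, "k_d"),
    k_deg   = vapply(populations, `[[`, 0, "k_deg"),
    sensitive = sens
  )
  if (is.null(vpth)) vpth <- rep(0, n)
  if (length(vpth) != n || any(!is.finite(vpth)) || any(vpth < 0))
    stop("gland_model: vpth must be a non-negative vector of length ", n)
  structure(list(params = params, vpth = as.numeric(vpth)),
            class = "gland_model")
}

n_populations <- function(gland) nrow(gland$params)

#' @export
print.gland_model <- function(x, ...) {
  p <- x$params
  cat(sprintf("<gland_model> %d populations (%d sensitive / %d insensitive)\n",
              nrow(p), sum(p$sensitive), sum(!p$sensitive)))
  cat(sprintf("  k_d  sensitive: %.3f±%.3f   insensitive: %.3f±%.3f mmol/L\n",
              mean(p$k_d[p$sensitive]), stats::sd(p$k_d[p$sensitive]),
              mean(p$k_d[!p$sensitive]), stats::sd(p$k_d[!p$sensitive])))
  cat(sprintf("  total stored PTH: %.4g amount units\n", sum(x$vpth)))
  invisible(x)
}

#' @export
summary.gland_model <- function(object, ...) {
  p <- object$params
  out <- do.call(rbind, lapply(split(p, p$sensitive), function(d) {
    data.frame(class = if (d$sensitive[1]) "sensitive" else "insensitive",
               n = nrow(d),
               k_v = mean(d$k_v), beta = mean(d$beta),
               gamma_c = mean(d$gamma_c), m = mean(d$m), k_d = mean(d$k_d))
  }))
  rownames(out) <- NULL
  out
}

# per-population secretion fractions at calcium ca (scalar), vectorized over
# populations; same sigmoid as secretion_fraction()
gland_fractions <- function(ca, gland) {
  p <- gland$params
  if (ca < 0) stop("gland_fractions: ca must be >= 0")
  r <- exp(pmin(p$m * (log(max(ca, .Machine$double.xmin)) - log(p$k_d)), 700))
  pmin(p$gamma_c + (p$beta - p$gamma_c) / (1 + r), p$beta)
}
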