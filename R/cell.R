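#' Secretion and synthesis constants for one parathyroid cell subpopulation
#'
#' One subpopulation is described by a constant synthesis rate feeding its
#' intracellular store, a first-order degradation loss, and a
#' calcium-inhibited secretion fraction: a decreasing sigmoid falling from
#' `beta` (maximal per-minute secretable fraction of the store) to `gamma_c`
#' (the never-fully-suppressed minimum), with half-inhibition at the set
#' point `k_d` and steepness `m`. `m` is an empirical augmentation factor
#' summarizing the intracellular cascade downstream of the calcium-sensing
#' receptor, not a Hill coefficient.
#'
#' @param k_v Synthesis rate of intracellular PTH (amount units/min, > 0).
#' @param beta Maximal per-minute secretable fraction, in (0, 1].
#' @param gamma_c Minimal per-minute secretable fraction, in (0, beta).
#' @param m Sigmoid steepness (> 0).
#' @param k_d Half-inhibition calcium set point (mmol/L, > 0).
#' @param k_deg Per-minute intracellular degradation fraction. Fixed at 0.02
#'   by default (70% of an isolated store decays in 60 min).
#' @param sensitive Logical; `TRUE` marks the calcium-sensitive class (lower
#'   set point, silenced at normocalcemia), `FALSE` the insensitive class.
#'
#' @return An object of class `cell_params`.
#' @examples
#' p <- cell_params(k_v = 3.6, beta = 0.5, gamma_c = 0.0032,
#'                  m = 270, k_d = 1.13, sensitive = TRUE)
#' secretion_fraction(c(0, 1.13, 2), p)
#' @export
cell_params <- function(k_v, beta, gamma_c, m, k_d, k_deg = 0.02,
                        sensitive = TRUE) {
  num1 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("cell_params: '", nm, "' must be a single finite number")
    v
  }
  k_v <- num1(k_v, "k_v"); beta <- num1(beta, "beta")
  gamma_c <- num1(gamma_c, "gamma_c"); m <- num1(m, "m")
  k_d <- num1(k_d, "k_d"); k_deg <- num1(k_deg, "k_deg")
  if (k_v < 0) stop("cell_params: k_v must be >= 0")
  if (beta <= 0 || beta > 1) stop("cell_params: beta must lie in (0, 1]")
  if (gamma_c <= 0 || gamma_c >= beta)
    stop("cell_params: need 0 < gamma_c < beta")
  if (m <= 0) stop("cell_params: m must be > 0")
  if (k_d <= 0) stop("cell_params: k_d must be > 0")
  if (k_deg < 0) stop("cell_params: k_deg must be >= 0")
  structure(
    list(k_v = k_v, beta = beta, gamma_c = gamma_c, m = m, k_d = k_d,
         k_deg = k_deg, sensitive = isTRUE(sensitive)),
    class = "cell_params"
  )
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf(
    "<cell_params %s> k_v=%.3g beta=%.3g gamma_c=%.3g m=%.3g k_d=%.3g k_deg=%.3g\n",
    if (x$sensitive) "sensitive" else "insensitive",
    x$k_v, x$beta, x$gamma_c, x$m, x$k_d, x$k_deg))
  invisible(x)
}

#' Calcium-inhibited per-minute secretion fraction
#'
#' The dose–response sigmoid
#' `f(ca) = beta - (beta - gamma_c) * ca^m / (ca^m + k_d^m)`:
#' strictly decreasing in calcium, equal to `beta` at `ca = 0`, to the
#' midpoint `beta - (beta - gamma_c)/2` at `ca = k_d`, and approaching
#' `gamma_c` at high calcium.
#'
#' @param ca Serum ionized calcium (mmol/L), vectorized, all values >= 0.
#' @param params A [cell_params()] object.
#' @return Per-minute secretable fraction(s), in `(gamma_c, beta]`.
#' @export
secretion_fraction <- function(ca, params) {
  stopifnot(inherits(params, "cell_params"))
  if (!is.numeric(ca) || any(!is.finite(ca)))
    stop("secretion_fraction: ca must be finite numeric")
  if (any(ca < 0)) stop("secretion_fraction: ca must be >= 0")
  # log scale so ca^m cannot overflow for large m; the gamma_c-anchored
  # form stays exactly on the floor without cancellation
  r <- exp(pmin(params$m * (log(pmax(ca, .Machine$double.xmin)) -
                              log(params$k_d)), 700))
  pmin(params$gamma_c + (params$beta - params$gamma_c) / (1 + r),
       params$beta)
}
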