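#' One-dimensional parameter distributions
#'
#' Parameter uncertainty is carried by one-dimensional distributions with
#' explicit CDF and inverse-CDF evaluators; sampling is by inversion of a
#' uniform draw, so seeded runs are reproducible. Three kinds are
#' supported: uniform priors, positivity-truncated normals (the
#' representation of the post-calibration moments), and smoothed kernel
#' densities re-estimated from retained calibration samples.
#'
#' @param lo,hi Support bounds.
#' @return An object of class `param_dist`.
#' @seealso [fit_kernel()], [dist_cdf()], [dist_quantile()], [dist_sample()]
#' @export
dist_uniform <- function(lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("dist_uniform: need finite lo < hi")
  structure(list(kind = "uniform", lo = lo, hi = hi),
            class = "param_dist")
}

#' @param mean,sd Moments of the untruncated normal.
#' @rdname dist_uniform
#' @export
dist_truncnorm <- function(mean, sd, lo = 0, hi = Inf) {
  if (!is.finite(mean) || !is.finite(sd) || sd <= 0)
    stop("dist_truncnorm: need finite mean and sd > 0")
  if (lo >= hi) stop("dist_truncnorm: need lo < hi")
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo < 1e-12)
    stop("dist_truncnorm: support carries no probability mass")
  structure(list(kind = "truncnorm", lo = lo, hi = hi, mean = mean, sd = sd,
                 plo = plo, phi = phi),
            class = "param_dist")
}

#' Smoothed kernel density estimate as a sampling distribution
#'
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth, truncated to
#' `support` and renormalized. The CDF is accumulated on the density grid
#' (trapezoid rule) and inverted by monotone linear interpolation, so
#' `dist_quantile(d, dist_cdf(d, x)) == x` on the support interior.
#' If all samples are identical a point mass is returned with a warning.
#'
#' @param samples Numeric sample (length >= 5).
#' @param support `(lo, hi)` truncation interval. Default `c(0, Inf)`
#'   (positivity).
#' @param n Density grid size.
#' @return A `param_dist` of kind `"kernel"` (or `"point"` if degenerate).
#' @export
fit_kernel <- function(samples, support = c(0, Inf), n = 1024) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 5L) stop("fit_kernel: need at least 5 samples")
  lo <- support[1]; hi <- support[2]
  if (stats::sd(samples) == 0) {
    warning("fit_kernel: degenerate sample; returning a point mass")
    return(structure(list(kind = "point", lo = samples[1], hi = samples[1],
                          at = samples[1]), class = "param_dist"))
  }
  den <- stats::density(samples, bw = "nrd0", n = n,
                        from = max(lo, min(samples) - 3 * stats::bw.nrd0(samples)),
                        to = min(hi, max(samples) + 3 * stats::bw.nrd0(samples)))
  x <- den$x; y <- pmax(den$y, 0)
  cdf <- c(0, cumsum(diff(x) * (y[-1] + y[-length(y)]) / 2))
  tot <- cdf[length(cdf)]
  if (tot <= 0) stop("fit_kernel: density carries no mass on the support")
  cdf <- cdf / tot
  keep <- !duplicated(cdf)
  structure(list(kind = "kernel", lo = x[1], hi = x[length(x)],
                 bw = den$bw, x = x, pdf = y / tot, cdf = cdf,
                 cdf_fun = stats::approxfun(x, cdf, rule = 2),
                 q_fun = stats::approxfun(cdf[keep], x[keep], rule = 2),
                 n_samples = length(samples)),
            class = "param_dist")
}

#' Distribution evaluators
#'
#' `dist_cdf()` evaluates the cumulative distribution, `dist_quantile()`
#' its inverse, `dist_sample()` draws by inverse-CDF sampling of uniform
#' variates (reproducible under `set.seed`), and `dist_mean()` returns the
#' distribution mean (analytic for uniform/truncated-normal, numeric for
#' kernels).
#'
#' @param d A `param_dist`.
#' @param x,p,n Evaluation points / probabilities / draw count.
#' @export
dist_cdf <- function(d, x) {
  stopifnot(inherits(d, "param_dist"))
  switch(d$kind,
    uniform = pmin(1, pmax(0, (x - d$lo) / (d$hi - d$lo))),
    truncnorm = pmin(1, pmax(0,
      (stats::pnorm(x, d$mean, d$sd) - d$plo) / (d$phi - d$plo))),
    kernel = d$cdf_fun(x),
    point = as.numeric(x >= d$at)
  )
}

#' @rdname dist_cdf
#' @export
dist_quantile <- function(d, p) {
  stopifnot(inherits(d, "param_dist"))
  if (any(p < 0 | p > 1)) stop("dist_quantile: p must lie in [0, 1]")
  switch(d$kind,
    uniform = d$lo + p * (d$hi - d$lo),
    truncnorm = stats::qnorm(d$plo + p * (d$phi - d$plo), d$mean, d$sd),
    kernel = d$q_fun(p),
    point = rep(d$at, length(p))
  )
}

#' @rdname dist_cdf
#' @export
dist_sample <- function(d, n) dist_quantile(d, stats::runif(n))

#' @rdname dist_cdf
#' @export
dist_mean <- function(d) {
  switch(d$kind,
    uniform = (d$lo + d$hi) / 2,
    truncnorm = {
      a <- (d$lo - d$mean) / d$sd; b <- (d$hi - d$mean) / d$sd
      d$mean + d$sd * (stats::dnorm(a) - stats::dnorm(b)) / (d$phi - d$plo)
    },
    kernel = trapz(d$x, d$x * d$pdf),
    point = d$at
  )
}

#' @export
print.param_dist <- function(x, ...) {
  desc <- switch(x$kind,
    uniform = sprintf("U[%g, %g]", x$lo, x$hi),
    truncnorm = sprintf("N(%g, %g) truncated to [%g, %g]",
                        x$mean, x$sd, x$lo, x$hi),
    kernel = sprintf("kernel density (bw %.3g, %d samples) on [%.3g, %.3g]",
                     x$bw, x$n_samples, x$lo, x$hi),
    point = sprintf("point mass at %g", x$at))
  cat("<param_dist>", desc, "\n")
  invisible(x)
}

#' Parameter distributions defining a virtual-gland population
#'
#' A gland specification holds one distribution per model parameter, with
#' suffix 1 for the sensitive class (lower calcium set point: suppressed
#' earlier as calcium rises) and 2 for the insensitive class. `beta` and
#' `gamma_c` are shared between classes: each population draws its own
#' value from the one distribution.
#'
#' @param k_v1,k_v2 Synthesis-rate distributions (sensitive, insensitive).
#' @param beta Maximal secretable-fraction distribution (shared).
#' @param gamma_c Minimal secretable-fraction distribution (shared).
#' @param m1,m2 Steepness distributions.
#' @param k_d1,k_d2 Set-point distributions (mmol/L).
#' @param n_pairs Number of sensitive/insensitive pairs. Default 20.
#' @param k_deg Fixed degradation fraction (1/min). Default 0.02.
#' @return An object of class `gland_spec`.
#' @export
gland_spec <- function(k_v1, k_v2, beta, gamma_c, m1, m2, k_d1, k_d2,
                       n_pairs = 20, k_deg = 0.02) {
  dists <- list(k_v1 = k_v1, k_v2 = k_v2, beta = beta, gamma_c = gamma_c,
                m1 = m1, m2 = m2, k_d1 = k_d1, k_d2 = k_d2)
  ok <- vapply(dists, inherits, TRUE, "param_dist")
  if (!all(ok))
    stop("gland_spec: not param_dist objects: ",
         paste(names(dists)[!ok], collapse = ", "))
  if (n_pairs < 1) stop("gland_spec: n_pairs must be >= 1")
  if (dist_mean(k_d1) >= dist_mean(k_d2))
    warning("gland_spec: sensitive set points (k_d1) are expected below ",
            "insensitive ones (k_d2)")
  structure(c(dists, list(n_pairs = as.integer(n_pairs), k_deg = k_deg)),
            class = "gland_spec")
}

#' @export
print.gland_spec <- function(x, ...) {
  cat(sprintf("<gland_spec> %d sensitive + %d insensitive populations, k_deg=%g\n",
              x$n_pairs, x$n_pairs, x$k_deg))
  for (nm in c("k_v1", "k_v2", "beta", "gamma_c", "m1", "m2", "k_d1", "k_d2")) {
    cat(sprintf("  %-8s", nm)); print(x[[nm]])
  }
  invisible(x)
}

#' Post-calibration parameter distributions (reference population)
#'
#' The calibrated population: positivity-truncated normal distributions
#' with the published post-calibration means and standard deviations —
#' k_v1 (3.6, 1.13), k_v2 (2.1, 1.41), beta (0.50, 0.26),
#' gamma_c (0.0032, 0.00117), m1 (270, 102), m2 (244, 92),
#' k_d1 (1.13, 0.056), k_d2 (1.27, 0.051). `beta` is additionally
#' truncated to (0, 1] so drawn fractions remain valid. Note the
#' calibrated kernel densities themselves were not published; the
#' truncated-normal representation matches their first two moments only
#' (see `vignette("pth-population-model")`).
#'
#' @param n_pairs Number of sensitive/insensitive pairs. Default 20.
#' @return A [gland_spec()].
#' @export
table1_spec <- function(n_pairs = 20) {
  gland_spec(
    k_v1 = dist_truncnorm(3.6, 1.13),
    k_v2 = dist_truncnorm(2.1, 1.41),
    beta = dist_truncnorm(0.50, 0.26, lo = 0, hi = 1),
    gamma_c = dist_truncnorm(0.0032, 0.00117),
    m1 = dist_truncnorm(270, 102),
    m2 = dist_truncnorm(244, 92),
    k_d1 = dist_truncnorm(1.13, 0.056),
    k_d2 = dist_truncnorm(1.27, 0.051),
    n_pairs = n_pairs
  )
}

#' Initial (pre-calibration) uniform parameter distributions
#'
#' The uniform search ranges the calibration starts from:
#' k_v U[1,10] (both classes), beta U[0.1,0.9], gamma_c U[0.00005,0.0025],
#' m U[100,400] (both classes), k_d1 U[1.025,1.175], k_d2 U[1.20,1.35].
#'
#' @inheritParams table1_spec
#' @return A [gland_spec()].
#' @export
table1_priors <- function(n_pairs = 20) {
  gland_spec(
    k_v1 = dist_uniform(1, 10),
    k_v2 = dist_uniform(1, 10),
    beta = dist_uniform(0.1, 0.9),
    gamma_c = dist_uniform(0.00005, 0.0025),
    m1 = dist_uniform(100, 400),
    m2 = dist_uniform(100, 400),
    k_d1 = dist_uniform(1.025, 1.175),
    k_d2 = dist_uniform(1.20, 1.35),
    n_pairs = n_pairs
  )
}

#' Sample a virtual gland from a specification
#'
#' Draws `n_pairs` sensitive and `n_pairs` insensitive populations. Class
#' parameters come from the class-specific distributions; `beta` and
#' `gamma_c` are drawn per population from their shared distributions.
#' Draws violating `gamma_c < beta` are rejected and redrawn (the pair is
#' resampled jointly).
#'
#' @param spec A [gland_spec()].
#' @param seed Optional integer; if given, `set.seed(seed)` is called so
#'   the gland is reproducible.
#' @param max_retries Rejection-sampling cap for the `gamma_c < beta`
#'   constraint.
#' @return A [gland_model()].
#' @export
sample_gland <- function(spec, seed = NULL, max_retries = 1000) {
  stopifnot(inherits(spec, "gland_spec"))
  if (!is.null(seed)) set.seed(seed)
  np <- spec$n_pairs; n <- 2L * np
  k_v <- c(dist_sample(spec$k_v1, np), dist_sample(spec$k_v2, np))
  m <- c(dist_sample(spec$m1, np), dist_sample(spec$m2, np))
  k_d <- c(dist_sample(spec$k_d1, np), dist_sample(spec$k_d2, np))
  beta <- dist_sample(spec$beta, n)
  gamma_c <- dist_sample(spec$gamma_c, n)
  tries <- 0
  repeat {
    bad <- which(gamma_c >= beta | beta > 1 | gamma_c <= 0 | m <= 0 |
                   k_d <= 0 | k_v < 0)
    if (!length(bad)) break
    tries <- tries + 1
    if (tries > max_retries)
      stop("sample_gland: could not satisfy parameter constraints after ",
           max_retries, " retries")
    beta[bad] <- dist_sample(spec$beta, length(bad))
    gamma_c[bad] <- dist_sample(spec$gamma_c, length(bad))
  }
  sens <- rep(c(TRUE, FALSE), each = np)
  pops <- lapply(seq_len(n), function(i)
    cell_params(k_v[i], beta[i], gamma_c[i], m[i], k_d[i],
                k_deg = spec$k_deg, sensitive = sens[i]))
  gland_model(pops)
}

#' A gland at the specification's mean parameters
#'
#' Deterministic comparator: every population of a class carries that
#' class's distribution means. With `n_pairs = 1` this is the
#' "single-pair" model used in the model-comparison analyses.
#'
#' @inheritParams sample_gland
#' @param n_pairs Overrides the spec's pair count (e.g. 1).
#' @return A [gland_model()].
#' @export
mean_gland <- function(spec, n_pairs = spec$n_pairs) {
  stopifnot(inherits(spec, "gland_spec"))
  mk <- function(sensitive) {
    cell_params(
      dist_mean(if (sensitive) spec$k_v1 else spec$k_v2),
      min(dist_mean(spec$beta), 1),
      dist_mean(spec$gamma_c),
      dist_mean(if (sensitive) spec$m1 else spec$m2),
      dist_mean(if (sensitive) spec$k_d1 else spec$k_d2),
      k_deg = spec$k_deg, sensitive = sensitive)
  }
  pops <- c(replicate(n_pairs, mk(TRUE), simplify = FALSE),
            replicate(n_pairs, mk(FALSE), simplify = FALSE))
  gland_model(pops)
}
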