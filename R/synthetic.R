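#' Specification of a synthetic clamp study
#'
#' Defines a pseudo-experimental study: a ground-truth gland population, a
#' clamp protocol, an observation-noise model and a subject count. Running
#' it with [generate_observations()] produces phase-labelled observation
#' sets with the structure the calibration expects, so the full
#' calibration/validation pipeline is testable without access to the
#' original clinical measurements.
#'
#' @param truth A [gland_spec()] (each subject gets a freshly sampled
#'   gland) or a fixed [gland_model()] (all subjects share it).
#' @param protocol `"A"`, `"B"` or `"C"`, or a `calcium_profile`.
#' @param noise_sd Observation noise SD: a fraction of the true value when
#'   `fractional = TRUE` (default 0.2, matching the relative dispersion of
#'   acute-clamp PTH measurements in small groups of healthy adults), or
#'   absolute PTH units when `fractional = FALSE`.
#' @param fractional Interpret `noise_sd` as a fraction. Default `TRUE`.
#' @param n_subjects Number of simulated individuals. Default 4.
#' @param baseline Baseline calcium (mmol/L) for named protocols.
#' @param dt Integration step for the truth simulations (min).
#' @param seed Optional integer seed; generation is reproducible given it.
#' @return An object of class `synthetic_study`.
#' @export
synthetic_study <- function(truth = table1_spec(), protocol = "A",
                            noise_sd = 0.2, fractional = TRUE,
                            n_subjects = 4, baseline = 1.25, dt = 0.5,
                            seed = NULL) {
  if (!inherits(truth, "gland_spec") && !inherits(truth, "gland_model"))
    stop("synthetic_study: truth must be a gland_spec or gland_model")
  if (noise_sd < 0) stop("synthetic_study: noise_sd must be >= 0")
  if (n_subjects < 1) stop("synthetic_study: need n_subjects >= 1")
  if (is.character(protocol)) {
    layout <- observation_layout(protocol)
    profile <- clamp_protocol(protocol, baseline = baseline)
  } else if (inherits(protocol, "calcium_profile")) {
    profile <- protocol
    layout <- observation_layout("A")
  } else stop("synthetic_study: bad protocol")
  structure(list(truth = truth, profile = profile, layout = layout,
                 noise_sd = noise_sd, fractional = fractional,
                 n_subjects = n_subjects, dt = dt, seed = seed),
            class = "synthetic_study")
}

#' Generate pseudo-experimental observations from a synthetic study
#'
#' Simulates each subject's gland under the study protocol, samples serum
#' PTH at the protocol's phase layout, and adds independent Gaussian noise
#' (truncated at zero; truncations are counted in attribute
#' `"n_truncated"` with a warning). Per-point means and SDs are computed
#' across subjects. With a single subject, or zero noise, the replicate SD
#' degenerates; such SDs are replaced by `max(noise_sd, 1)` model units.
#'
#' @param study A [synthetic_study()].
#' @return An [observation_set()], with the noise-free truth trajectory of
#'   subject means in attribute `"truth"`.
#' @examples
#' st <- synthetic_study(noise_sd = 0.5, n_subjects = 4, seed = 1)
#' generate_observations(st)
#' @export
generate_observations <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!is.null(study$seed)) set.seed(study$seed)
  lay <- study$layout
  vals <- matrix(NA_real_, study$n_subjects, nrow(lay))
  truth <- matrix(NA_real_, study$n_subjects, nrow(lay))
  for (s in seq_len(study$n_subjects)) {
    gland <- if (inherits(study$truth, "gland_spec"))
      sample_gland(study$truth) else study$truth
    sim <- simulate_gland(gland, study$profile, dt = study$dt,
                          t_end = min(study$profile$t_end,
                                      max(lay$time_min) + 2 * study$dt))
    y <- serum_at(sim, lay$time_min)
    truth[s, ] <- y
    sd_here <- if (study$fractional) study$noise_sd * y else
      rep(study$noise_sd, length(y))
    vals[s, ] <- y + stats::rnorm(length(y), 0, sd_here)
  }
  n_trunc <- sum(vals < 0)
  if (n_trunc > 0) {
    warning("generate_observations: ", n_trunc,
            " noisy value(s) truncated at 0")
    vals[vals < 0] <- 0
  }
  m <- colMeans(vals)
  s <- if (study$n_subjects > 1) apply(vals, 2, stats::sd) else
    rep(0, ncol(vals))
  s[!is.finite(s) | s <= 0] <- max(study$noise_sd, 1)
  obs <- observation_set(lay$time_min, m, s, lay$phase)
  attr(obs, "truth") <- colMeans(truth)
  attr(obs, "n_truncated") <- n_trunc
  obs
}
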