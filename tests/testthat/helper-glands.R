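# Small fixture builders used across the suite.

# one sensitive/insensitive pair at the calibrated class means
pair_gland <- function(k_deg = 0.02) {
  gland_model(list(
    cell_params(3.6, 0.5, 0.0032, 270, 1.13, k_deg = k_deg, sensitive = TRUE),
    cell_params(2.1, 0.5, 0.0032, 244, 1.27, k_deg = k_deg, sensitive = FALSE)
  ))
}

# gland with all populations identical (degenerate heterogeneity)
uniform_gland <- function(n_pairs = 3) {
  pops <- lapply(seq_len(2 * n_pairs), function(i)
    cell_params(3, 0.5, 0.0032, 250, 1.2,
                sensitive = i <= n_pairs))
  gland_model(pops)
}

# random but valid cell parameters (for property sweeps)
random_cell <- function() {
  beta <- runif(1, 0.15, 1)
  cell_params(
    k_v = runif(1, 0.5, 10),
    beta = beta,
    gamma_c = runif(1, 1e-5, beta / 3),
    m = runif(1, 5, 400),
    k_d = runif(1, 0.8, 1.6),
    sensitive = runif(1) < 0.5
  )
}

random_gland <- function(n_pairs = 2) {
  pops <- lapply(seq_len(2 * n_pairs), function(i) {
    p <- random_cell()
    p$sensitive <- i <= n_pairs
    p
  })
  gland_model(pops)
}

# constant-calcium profile helper
constant_profile <- function(ca = 1.25, t_end = 300) {
  profile_from_table(c(0, t_end), c(ca, ca))
}
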