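# Shared fixtures: published peanut/cereal-bar estimates and small synthetic
# datasets built in code.

paper_pars <- peanut_cereal_params()

# ground truth used by the generators throughout the suite
truth <- list(
  x = c(meanlog = -3.719, sdlog = 0.747), n_x = 350L,
  y_rate = 0.013, n_y = 24L,
  z_weibull = c(shape = 0.38, scale = 229.6),
  z_lognormal = c(meanlog = 4.09, sdlog = 2.98), n_z = 158L
)

make_challenges <- function(seed, family = "weibull", n = truth$n_z,
                            grid = dose_grid(), keep_latent = FALSE) {
  params <- if (family == "weibull") truth$z_weibull else truth$z_lognormal
  generate_challenge_data(family, params, n, grid = grid, seed = seed,
                          keep_latent = keep_latent)
}

# very fine grid: interval censoring becomes almost exact observation
fine_grid <- function(points = 1000) {
  10^seq(-4, 5, length.out = points)
}
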