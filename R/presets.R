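#' Published input estimates for peanut in cereal bars
#'
#' Point estimates and sampling standard deviations for the package's worked
#' example: accidental peanut contamination of cereal bars, with consumption
#' from three combined European food-consumption surveys (n = 350 eating
#' occasions, log-normal in kg), peanut concentration from 24 published
#' contamination measurements (log-normal in ppm, or exponential with rate
#' about 0.013/ppm), and 158 interval-censored DBPCFC outcomes for the
#' threshold (log-normal or Weibull, mg protein).
#'
#' Two variants of the log-normal parameters are carried: the plug-in fit
#' used without uncertainty (`plugin`) and the slightly different estimates
#' used with frequentist sampling distributions (`sampling`), as published.
#'
#' @return A nested list with elements `n` (sample sizes), `plugin`
#'   (`x`, `y`, `z` log-pairs), `sampling` (`x`, `y`, `z`
#'   [lognormal_params()]), `exponential_y` (rate and its published sampling
#'   SD), and `weibull_z` ([weibull_params()] with published SEs).
#' @export
#' @examples
#' p <- peanut_cereal_params()
#' closed_form_risk(p$plugin$x, p$plugin$y, p$plugin$z)
peanut_cereal_params <- function() {
  n <- c(x = 350L, y = 24L, z = 158L)
  list(
    n = n,
    plugin = list(
      x = c(meanlog = -3.718, sdlog = 0.745),
      y = c(meanlog = 3.504, sdlog = 1.296),
      z = c(meanlog = 4.092, sdlog = 2.982)
    ),
    sampling = list(
      x = lognormal_params(-3.719, 0.747, n = n[["x"]]),
      y = lognormal_params(3.496, 1.283, n = n[["y"]]),
      z = lognormal_params(4.088, 2.987, n = n[["z"]])
    ),
    exponential_y = exponential_params(0.013, n = n[["y"]], se_rate = 0.001),
    weibull_z = weibull_params(0.382, 229.621, se_shape = 0.027,
                               se_scale = 55.099, n = n[["z"]])
  )
}

#' Preset case specifications for the peanut/cereal-bar example
#'
#' Builds a ready-to-run [case_spec()] from the published estimates of
#' [peanut_cereal_params()]:
#' * `"A"` - plug-in triple log-normal, indicator simulation, no parameter
#'   uncertainty (the spread of the result is simulation error only);
#' * `"B_calculated"` - triple log-normal with frequentist parameter draws,
#'   closed-form risk per draw (no inner loop);
#' * `"B_simulated"` - same draws, indicator simulation;
#' * `"C"` - log-normal consumption with frequentist draws, exponential
#'   concentration with normal rate draws, Weibull threshold with normal
#'   shape/scale draws, dose-response risk.
#'
#' Case D (Bayesian) requires data, not just published point estimates -
#' build it with [case_spec()] from [exponential_gamma_posterior()],
#' [weibull_threshold_mcmc()] and [input_empirical()].
#'
#' @param case One of `"A"`, `"B_calculated"`, `"B_simulated"`, `"C"`.
#' @param K,n Replications and iterations per replication.
#' @param seed Optional master seed.
#' @return A [case_spec()].
#' @export
peanut_cereal_case <- function(case = c("A", "B_calculated", "B_simulated",
                                        "C"),
                               K = 1000, n = 10000, seed = NULL) {
  case <- match.arg(case)
  p <- peanut_cereal_params()
  switch(case,
    A = case_spec(
      "A",
      input_lognormal(lognormal_params(p$plugin$x[1], p$plugin$x[2])),
      input_lognormal(lognormal_params(p$plugin$y[1], p$plugin$y[2])),
      input_lognormal(lognormal_params(p$plugin$z[1], p$plugin$z[2])),
      risk_method = "indicator", K = K, n = n, seed = seed
    ),
    B_calculated = case_spec(
      "B",
      input_lognormal(p$sampling$x, "sampling"),
      input_lognormal(p$sampling$y, "sampling"),
      input_lognormal(p$sampling$z, "sampling"),
      risk_method = "closed_form", K = K, n = n, seed = seed
    ),
    B_simulated = case_spec(
      "B",
      input_lognormal(p$sampling$x, "sampling"),
      input_lognormal(p$sampling$y, "sampling"),
      input_lognormal(p$sampling$z, "sampling"),
      risk_method = "indicator", K = K, n = n, seed = seed
    ),
    C = case_spec(
      "C",
      input_lognormal(p$sampling$x, "sampling"),
      input_exponential(p$exponential_y, "normal"),
      input_weibull(p$weibull_z, "normal"),
      risk_method = "dose_response", K = K, n = n, seed = seed
    )
  )
}
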