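#' Closed-form risk for the triple log-normal model
#'
#' When consumption X, concentration Y and threshold Z are all log-normal,
#' the exposure XY is log-normal and the probability of an allergic reaction
#' has the closed form
#' `p = 1 - Phi((mu_z - mu_x - mu_y) / sqrt(sigma_x^2 + sigma_y^2 + sigma_z^2))`,
#' with `Phi` the standard normal CDF. Log units must be consistent:
#' log-kg consumption plus log-ppm concentration gives log-mg exposure,
#' matching thresholds in log-mg.
#'
#' @param x,y,z `(meanlog, sdlog)` pairs or [lognormal_params()] objects for
#'   consumption, concentration and threshold.
#' @return The reaction probability, in `[0, 1]`.
#' @export
#' @examples
#' closed_form_risk(c(-3.718, 0.745), c(3.504, 1.296), c(4.092, 2.982))
closed_form_risk <- function(x, y, z) {
  x <- as_logpair(x, "x")
  y <- as_logpair(y, "y")
  z <- as_logpair(z, "z")
  closed_form_risk_vec(x[1], x[2], y[1], y[2], z[1], z[2])
}

# vectorised core shared with run_case and the delta method
closed_form_risk_vec <- function(mx, sx, my, sy, mz, sz) {
  s2 <- sx^2 + sy^2 + sz^2
  if (any(s2 == 0)) {
    stop("all three log-scale parameters are zero: risk is degenerate")
  }
  stats::pnorm((mz - mx - my) / sqrt(s2), lower.tail = FALSE)
}

#' Monte Carlo risk with the indicator outcome
#'
#' Estimates `P(Z < X*Y)` by simulating `n` independent triples and counting
#' reactions: `U = 1` if the sampled threshold is strictly below the sampled
#' exposure, else 0 (ties count as no reaction). This is the
#' "density-function" route: thresholds are drawn explicitly.
#'
#' @param x_sampler,y_sampler,z_sampler Functions of `n` returning `n`
#'   positive draws of consumption (kg), concentration (ppm) and threshold
#'   (mg) respectively.
#' @param n Number of iterations (>= 1).
#' @param seed Optional integer seed.
#' @return The simulated reaction probability.
#' @export
simulate_risk_indicator <- function(x_sampler, y_sampler, z_sampler, n,
                                    seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  stopifnot(is.function(x_sampler), is.function(y_sampler),
            is.function(z_sampler))
  if (!is.null(seed)) set.seed(seed)
  x <- x_sampler(n)
  y <- y_sampler(n)
  mean(z_sampler(n) < x * y)
}

#' Monte Carlo risk through the dose-response curve
#'
#' Estimates the mean individual reaction probability by evaluating the
#' threshold CDF (the dose-response curve) at each simulated exposure:
#' `mean(F_Z(X*Y))`. Equal in expectation to [simulate_risk_indicator()]
#' with `Z` drawn from the same distribution (law of total expectation), and
#' lower-variance since the threshold is integrated out.
#'
#' @param x_sampler,y_sampler Functions of `n` returning positive draws.
#' @param threshold_cdf Vectorised CDF of the threshold distribution on
#'   positive doses (mg).
#' @param n Number of iterations (>= 1).
#' @param seed Optional integer seed.
#' @return The mean reaction probability.
#' @export
simulate_risk_doseresponse <- function(x_sampler, y_sampler, threshold_cdf,
                                       n, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  stopifnot(is.function(x_sampler), is.function(y_sampler),
            is.function(threshold_cdf))
  if (!is.null(seed)) set.seed(seed)
  mean(threshold_cdf(x_sampler(n) * y_sampler(n)))
}

#' Specification of a risk-assessment case
#'
#' Bundles the three inputs, the risk computation method and the simulation
#' sizes into one reproducible specification for [run_case()]. The four
#' canonical configurations are: plug-in point estimates with no parameter
#' uncertainty (case A); triple log-normal with frequentist sampling
#' distributions, evaluated either in closed form ("calculated") or by
#' indicator simulation (case B); log-normal/exponential/Weibull inputs with
#' normal parameter draws and dose-response risk (case C); and its Bayesian
#' counterpart with bootstrap consumption, conjugate Gamma rate posterior and
#' MCMC threshold posterior (case D).
#'
#' @param case_id Free-form label (e.g. `"A"`, `"B"`, `"C"`, `"D"`).
#' @param consumption,concentration,threshold `risk_input` objects (see
#'   [input_lognormal()], [input_exponential()], [input_weibull()],
#'   [input_empirical()]).
#' @param risk_method `"indicator"`, `"dose_response"`, or `"closed_form"`
#'   (the latter requires three log-normal inputs and skips the inner loop).
#' @param K Number of replications (outer loop, parameter uncertainty).
#' @param n Number of iterations per replication (inner loop, individual
#'   variability); ignored by `"closed_form"`.
#' @param seed Optional master seed; the whole run is reproducible from it.
#' @return An object of class `case_spec`.
#' @export
case_spec <- function(case_id, consumption, concentration, threshold,
                      risk_method = c("indicator", "dose_response",
                                      "closed_form"),
                      K = 1000, n = 10000, seed = NULL) {
  risk_method <- match.arg(risk_method)
  stopifnot(inherits(consumption, "risk_input"),
            inherits(concentration, "risk_input"),
            inherits(threshold, "risk_input"))
  K <- as.integer(K)
  n <- as.integer(n)
  if (is.na(K) || K < 1L) stop("'K' must be a positive integer")
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  if (risk_method == "closed_form" &&
      !(inherits(consumption, "input_lognormal") &&
        inherits(concentration, "input_lognormal") &&
        inherits(threshold, "input_lognormal"))) {
    stop("closed-form risk requires three log-normal inputs")
  }
  if (risk_method == "dose_response" &&
      inherits(threshold, "input_empirical")) {
    stop("dose-response risk needs a parametric threshold input")
  }
  structure(
    list(case_id = case_id, consumption = consumption,
         concentration = concentration, threshold = threshold,
         risk_method = risk_method, K = K, n = n, seed = seed),
    class = "case_spec"
  )
}

# summary container for K per-replication risks
risk_distribution <- function(risks, case_id = NULL, method = NULL,
                              uncertainty = TRUE) {
  stopifnot(is.numeric(risks), length(risks) >= 1L,
            all(risks >= 0 & risks <= 1))
  qs <- if (length(risks) > 1L) {
    stats::quantile(risks, c(0.025, 0.5, 0.975), type = 8, names = FALSE)
  } else rep(risks, 3L)
  structure(
    list(risks = risks, mean = mean(risks),
         sd = if (length(risks) > 1L) stats::sd(risks) else NA_real_,
         p2.5 = qs[1], median = qs[2], p97.5 = qs[3],
         K = length(risks), case_id = case_id, method = method,
         uncertainty = uncertainty),
    class = "risk_distribution"
  )
}

#' @export
print.risk_distribution <- function(x, ...) {
  cat(sprintf("Risk distribution%s (%s, K = %d)\n",
              if (is.null(x$case_id)) "" else paste0(" - case ", x$case_id),
              x$method, x$K))
  cat(sprintf("  mean %.2f%%  sd %.2f%%  2.5%% %.2f%%  median %.2f%%  97.5%% %.2f%%\n",
              100 * x$mean, 100 * x$sd, 100 * x$p2.5, 100 * x$median,
              100 * x$p97.5))
  if (!x$uncertainty) {
    cat("  note: no parameter uncertainty active;",
        "the spread reflects simulation error only\n")
  }
  invisible(x)
}

#' @export
as.data.frame.risk_distribution <- function(x, ...) {
  data.frame(case = if (is.null(x$case_id)) NA_character_ else x$case_id,
             mean = x$mean, sd = x$sd, p2.5 = x$p2.5, median = x$median,
             p97.5 = x$p97.5, stringsAsFactors = FALSE)
}

#' Run a second-order Monte Carlo risk assessment
#'
#' Executes one case: the outer loop draws `K` sets of input-distribution
#' parameters from their uncertainty distributions (point estimates are
#' reused when an input carries no uncertainty), and for each set the inner
#' loop computes one risk, either by indicator simulation over `n`
#' individuals, by averaging the dose-response curve over `n` exposures, or
#' by the closed-form triple log-normal expression (no inner loop). The `K`
#' per-replication risks form the uncertainty distribution of the risk.
#'
#' @param spec A [case_spec()].
#' @return A `risk_distribution` object: the `K` risks plus mean, SD and
#'   2.5/50/97.5 empirical percentiles (median-unbiased interpolation).
#' @export
run_case <- function(spec) {
  stopifnot(inherits(spec, "case_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  K <- spec$K
  n <- spec$n
  px <- draw_input_params(spec$consumption, K)
  py <- draw_input_params(spec$concentration, K)
  pz <- draw_input_params(spec$threshold, K)

  risks <- if (spec$risk_method == "closed_form") {
    closed_form_risk_vec(px$meanlog, px$sdlog, py$meanlog, py$sdlog,
                         pz$meanlog, pz$sdlog)
  } else {
    vapply(seq_len(K), function(k) {
      xs <- sample_input(spec$consumption, px, k, n)
      ys <- sample_input(spec$concentration, py, k, n)
      if (spec$risk_method == "indicator") {
        zs <- sample_input(spec$threshold, pz, k, n)
        mean(zs < xs * ys)
      } else {
        mean(input_cdf(spec$threshold, pz, k)(xs * ys))
      }
    }, numeric(1))
  }
  risk_distribution(
    risks, case_id = spec$case_id, method = spec$risk_method,
    uncertainty = has_uncertainty(spec$consumption) ||
      has_uncertainty(spec$concentration) || has_uncertainty(spec$threshold)
  )
}
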