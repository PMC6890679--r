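# Input-source objects for the second-order risk simulation.
#
# Each input (consumption X, concentration Y, threshold Z) is wrapped in a
# small S3 object that knows three things: how to draw K parameter sets from
# its uncertainty distribution (the outer, "uncertainty" loop), how to sample
# n individuals given one parameter set (the inner, "variability" loop), and
# - for thresholds - its CDF, i.e. the dose-response curve.

new_risk_input <- function(subtype, fields) {
  structure(fields, class = c(subtype, "risk_input"))
}

#' Log-normal risk input
#'
#' A log-normal input distribution for the risk model, with or without
#' frequentist parameter uncertainty (normal draws for the location, scaled
#' chi-square draws for the variance).
#'
#' @param fit A [lognormal_params()] object (needs `n` when
#'   `uncertainty = "sampling"`).
#' @param uncertainty `"none"` (plug-in point estimates) or `"sampling"`
#'   (frequentist sampling-distribution draws).
#' @return A `risk_input` object.
#' @export
input_lognormal <- function(fit, uncertainty = c("none", "sampling")) {
  uncertainty <- match.arg(uncertainty)
  if (is.numeric(fit) && length(fit) == 2L) {
    fit <- lognormal_params(fit[1], fit[2])
  }
  stopifnot(inherits(fit, "lognormal_params"))
  if (uncertainty == "sampling" && is.na(fit$n)) {
    stop("sampling uncertainty requires the sample size 'n'")
  }
  new_risk_input("input_lognormal",
                 list(fit = fit, uncertainty = uncertainty))
}

#' Exponential risk input
#'
#' An exponential input distribution (typically the contamination), with
#' optional parameter uncertainty: normal draws around the rate estimate
#' (positive draws only) or exact conjugate Gamma posterior draws.
#'
#' @param fit An [exponential_params()] object (for `"none"`/`"normal"`) or
#'   a [exponential_gamma_posterior()] result (for `"conjugate"`, in which
#'   case the plug-in rate is the posterior mean).
#' @param uncertainty `"none"`, `"normal"` or `"conjugate"`.
#' @return A `risk_input` object.
#' @export
input_exponential <- function(fit,
                              uncertainty = c("none", "normal", "conjugate")) {
  uncertainty <- match.arg(uncertainty)
  if (uncertainty == "conjugate") {
    stopifnot(inherits(fit, "gamma_posterior"))
    return(new_risk_input("input_exponential",
                          list(posterior = fit, rate = fit$mean,
                               uncertainty = uncertainty)))
  }
  stopifnot(inherits(fit, "exponential_params"))
  if (uncertainty == "normal" && !is.finite(fit$se_rate)) {
    stop("normal uncertainty requires a finite 'se_rate'")
  }
  new_risk_input("input_exponential",
                 list(fit = fit, rate = fit$rate, uncertainty = uncertainty))
}

#' Weibull risk input
#'
#' A Weibull threshold (eliciting-dose) input, with optional parameter
#' uncertainty: independent normal draws around the survival-regression
#' estimates (positive draws only, as the published case specifications
#' prescribe) or reuse of MCMC posterior draws.
#'
#' @param fit A [weibull_params()] object (for `"none"`/`"normal"`) or a
#'   `posterior_draws` object from [weibull_threshold_mcmc()] (for
#'   `"posterior"`, plug-in values are the posterior means).
#' @param uncertainty `"none"`, `"normal"` or `"posterior"`.
#' @return A `risk_input` object.
#' @export
input_weibull <- function(fit,
                          uncertainty = c("none", "normal", "posterior")) {
  uncertainty <- match.arg(uncertainty)
  if (uncertainty == "posterior") {
    stopifnot(inherits(fit, "posterior_draws"))
    return(new_risk_input("input_weibull",
                          list(posterior = fit,
                               shape = mean(fit$draws$shape),
                               scale = mean(fit$draws$scale),
                               uncertainty = uncertainty)))
  }
  stopifnot(inherits(fit, "weibull_params"))
  if (uncertainty == "normal" &&
      (!is.finite(fit$se_shape) || !is.finite(fit$se_scale))) {
    stop("normal uncertainty requires finite shape and scale SEs")
  }
  new_risk_input("input_weibull",
                 list(fit = fit, shape = fit$shape, scale = fit$scale,
                      uncertainty = uncertainty))
}

#' Empirical (bootstrap) risk input
#'
#' A non-parametric input represented by an observed sample and optional
#' survey weights. With `uncertainty = "bootstrap"`, each outer replication
#' resamples the data with replacement (weighted), and the inner loop samples
#' individuals from that resample - so sampling uncertainty enters through
#' the bootstrap. With `"none"`, individuals are drawn from the original
#' weighted sample in every replication.
#'
#' @param sample Non-empty positive sample (e.g. consumption in kg).
#' @param weights Optional non-negative survey weights.
#' @param uncertainty `"none"` or `"bootstrap"`.
#' @return A `risk_input` object.
#' @export
input_empirical <- function(sample, weights = NULL,
                            uncertainty = c("none", "bootstrap")) {
  uncertainty <- match.arg(uncertainty)
  if (!is.numeric(sample) || length(sample) < 1L) {
    stop("'sample' must be a non-empty numeric vector")
  }
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(sample))
    if (sum(weights) == 0) stop("weights must not be all zero")
  }
  new_risk_input("input_empirical",
                 list(sample = sample, weights = weights,
                      uncertainty = uncertainty))
}

# ---- generic surface ------------------------------------------------------

draw_input_params <- function(input, K, ...) UseMethod("draw_input_params")

#' @export
draw_input_params.input_lognormal <- function(input, K, ...) {
  if (input$uncertainty == "none") {
    data.frame(meanlog = rep(input$fit$meanlog, K),
               sdlog = rep(input$fit$sdlog, K))
  } else {
    draw_lognormal_params(input$fit, K)
  }
}

#' @export
draw_input_params.input_exponential <- function(input, K, ...) {
  rate <- switch(input$uncertainty,
    none = rep(input$rate, K),
    normal = draw_normal_params(input$fit$rate, input$fit$se_rate, K,
                                positive = TRUE),
    conjugate = stats::rgamma(K, input$posterior$alpha,
                              input$posterior$beta)
  )
  data.frame(rate = rate)
}

#' @export
draw_input_params.input_weibull <- function(input, K, ...) {
  switch(input$uncertainty,
    none = data.frame(shape = rep(input$shape, K),
                      scale = rep(input$scale, K)),
    normal = data.frame(
      shape = draw_normal_params(input$fit$shape, input$fit$se_shape, K,
                                 positive = TRUE),
      scale = draw_normal_params(input$fit$scale, input$fit$se_scale, K,
                                 positive = TRUE)
    ),
    posterior = {
      d <- input$posterior$draws
      if (nrow(d) < K) {
        stop("posterior holds fewer draws than requested replications")
      }
      idx <- sample.int(nrow(d), K)
      data.frame(shape = d$shape[idx], scale = d$scale[idx])
    }
  )
}

#' @export
draw_input_params.input_empirical <- function(input, K, ...) {
  pr <- data.frame(k = seq_len(K))
  if (input$uncertainty == "bootstrap") {
    n_obs <- length(input$sample)
    attr(pr, "resamples") <- vapply(
      seq_len(K),
      function(k) input$sample[sample.int(n_obs, n_obs, replace = TRUE,
                                          prob = input$weights)],
      numeric(n_obs)
    )
  }
  pr
}

sample_input <- function(input, params, k, n) UseMethod("sample_input")

#' @export
sample_input.input_lognormal <- function(input, params, k, n) {
  stats::rlnorm(n, params$meanlog[k], params$sdlog[k])
}

#' @export
sample_input.input_exponential <- function(input, params, k, n) {
  stats::rexp(n, params$rate[k])
}

#' @export
sample_input.input_weibull <- function(input, params, k, n) {
  stats::rweibull(n, params$shape[k], params$scale[k])
}

#' @export
sample_input.input_empirical <- function(input, params, k, n) {
  rs <- attr(params, "resamples")
  if (is.null(rs)) {
    input$sample[sample.int(length(input$sample), n, replace = TRUE,
                            prob = input$weights)]
  } else {
    rs[sample.int(nrow(rs), n, replace = TRUE), k]
  }
}

input_cdf <- function(input, params, k) UseMethod("input_cdf")

#' @export
input_cdf.input_lognormal <- function(input, params, k) {
  ml <- params$meanlog[k]
  sl <- params$sdlog[k]
  function(q) stats::plnorm(q, ml, sl)
}

#' @export
input_cdf.input_weibull <- function(input, params, k) {
  sh <- params$shape[k]
  sc <- params$scale[k]
  function(q) stats::pweibull(q, sh, sc)
}

#' @export
input_cdf.input_exponential <- function(input, params, k) {
  r <- params$rate[k]
  function(q) stats::pexp(q, r)
}

#' @export
input_cdf.input_empirical <- function(input, params, k) {
  stop("an empirical input has no parametric dose-response curve")
}

# fixed (point-estimate) version of an input: used by the one-at-a-time
# uncertainty decomposition to switch single sources of uncertainty off
fix_input <- function(input) UseMethod("fix_input")

#' @export
fix_input.input_lognormal <- function(input) {
  input$uncertainty <- "none"
  input
}

#' @export
fix_input.input_exponential <- function(input) {
  if (input$uncertainty == "conjugate") {
    return(input_exponential(exponential_params(input$rate), "none"))
  }
  input$uncertainty <- "none"
  input
}

#' @export
fix_input.input_weibull <- function(input) {
  if (input$uncertainty == "posterior") {
    return(input_weibull(weibull_params(input$shape, input$scale), "none"))
  }
  input$uncertainty <- "none"
  input
}

#' @export
fix_input.input_empirical <- function(input) {
  input$uncertainty <- "none"
  input
}

has_uncertainty <- function(input) input$uncertainty != "none"
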