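#' Fit a log-normal distribution
#'
#' Moment fit on the log scale: location = mean of the natural logs, scale =
#' their standard deviation (n - 1 denominator). That pairing is what makes
#' the frequentist sampling laws exact for normal logs: the location estimate
#' is `N(meanlog, sdlog/sqrt(n))` and the variance estimate is
#' `sdlog^2/(n-1) * chi-square(n-1)`.
#'
#' @param sample Positive observations.
#' @param n_override Optional sample size to use for the standard errors
#'   instead of `length(sample)` (e.g. when the sample is a resample of a
#'   survey of different effective size).
#' @return A [lognormal_params()] object.
#' @export
#' @examples
#' fit_lognormal(c(1, exp(2))) # location 1, scale sqrt(2)
fit_lognormal <- function(sample, n_override = NULL) {
  if (!is.numeric(sample) || length(sample) < 2L) {
    stop("need at least 2 observations to fit a log-normal")
  }
  if (any(!is.finite(sample)) || any(sample <= 0)) {
    stop("all observations must be finite and strictly positive")
  }
  lx <- log(sample)
  s <- stats::sd(lx)
  if (s == 0) {
    stop("zero variance on the log scale: constant sample is degenerate")
  }
  n <- if (is.null(n_override)) length(sample) else as.integer(n_override)
  lognormal_params(mean(lx), s, n = n)
}

#' Fit an exponential distribution
#'
#' Maximum-likelihood fit of the contamination rate: `rate = 1/mean(sample)`.
#' The default standard error is the asymptotic MLE value `rate/sqrt(n)`;
#' `se_rate` overrides it when a different published sampling SD must be
#' reproduced.
#'
#' @param sample Positive observations (ppm).
#' @param se_rate Optional explicit standard error for the rate.
#' @return An [exponential_params()] object (retains the data sum for later
#'   conjugate Bayesian updating).
#' @export
fit_exponential <- function(sample, se_rate = NULL) {
  if (!is.numeric(sample) || length(sample) < 1L) {
    stop("need at least 1 observation to fit an exponential")
  }
  if (any(!is.finite(sample)) || any(sample <= 0)) {
    stop("all observations must be finite and strictly positive")
  }
  n <- length(sample)
  rate <- 1 / mean(sample)
  exponential_params(rate, n = n, se_rate = se_rate, data_sum = sum(sample))
}

# internal: validate a challenge record data frame (shared with readers)
validate_challenges <- function(records) {
  req <- c("lower_mg", "upper_mg", "censor")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    stop("challenge records need columns lower_mg, upper_mg, censor")
  }
  bad_type <- !records$censor %in% c("interval", "left", "right")
  if (any(bad_type)) {
    stop("invalid censor type in row(s) ",
         paste(which(bad_type), collapse = ", "),
         " (must be interval, left or right)")
  }
  lo <- records$lower_mg
  up <- records$upper_mg
  is_int <- records$censor == "interval"
  is_left <- records$censor == "left"
  is_right <- records$censor == "right"
  bad <- (is_int & (is.na(lo) | is.na(up) | lo >= up)) |
    (is_left & is.na(up)) |
    (is_right & is.na(lo)) |
    (!is.na(lo) & lo < 0) | (!is.na(up) & up <= 0)
  if (any(bad)) {
    stop("inconsistent challenge bounds in row(s) ",
         paste(which(bad), collapse = ", "))
  }
  records
}

# internal: direct interval-censored log-likelihood (used for diagnostics)
censored_loglik <- function(records, family, par1, par2) {
  cdf <- if (family == "weibull") stats::pweibull else stats::plnorm
  ll <- 0
  i <- records$censor == "interval"
  l <- records$censor == "left"
  r <- records$censor == "right"
  if (any(i)) {
    p <- cdf(records$upper_mg[i], par1, par2) -
      cdf(records$lower_mg[i], par1, par2)
    if (any(p <= 0)) return(-Inf)
    ll <- ll + sum(log(p))
  }
  if (any(l)) {
    p <- cdf(records$upper_mg[l], par1, par2)
    if (any(p <= 0)) return(-Inf)
    ll <- ll + sum(log(p))
  }
  if (any(r)) {
    ll <- ll + sum(cdf(records$lower_mg[r], par1, par2,
                       lower.tail = FALSE, log.p = TRUE))
  }
  ll
}

#' Fit a threshold distribution to interval-censored challenge data
#'
#' Maximum-likelihood survival-regression fit of a Weibull or log-normal
#' eliciting-dose distribution to interval-censored DBPCFC outcomes,
#' maximising `sum log[F(upper) - F(lower)]` with `F(lower) = 0` for
#' left-censored and `F(upper) = 1` for right-censored subjects. The fit is
#' performed with [survival::survreg()] (intercept-only accelerated-failure
#' model) and back-transformed to the natural parametrisation; standard
#' errors come from the inverse observed information via the delta method.
#'
#' @param records Challenge data frame (`lower_mg`, `upper_mg`, `censor`);
#'   a `latent_mg` column, if present, is ignored.
#' @param family `"weibull"` or `"lognormal"`.
#' @return A [weibull_params()] (shape/scale in mg, with SEs and their
#'   covariance) or [lognormal_params()] object.
#' @export
fit_interval_censored <- function(records, family = c("weibull", "lognormal")) {
  family <- match.arg(family)
  records <- validate_challenges(records)
  if (nrow(records) < 2L) stop("need at least 2 challenge records")
  if (all(records$censor == "left") || all(records$censor == "right")) {
    stop("threshold distribution is not identifiable: ",
         "all records censored on the same side")
  }
  lo <- records$lower_mg
  up <- records$upper_mg
  dist <- if (family == "weibull") "weibull" else "lognormal"

  warn <- NULL
  fit <- withCallingHandlers(
    survival::survreg(
      survival::Surv(lo, up, type = "interval2") ~ 1,
      dist = dist, control = survival::survreg.control(maxiter = 200)
    ),
    warning = function(w) {
      warn <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    }
  )
  if (!is.null(warn) && grepl("iterations", warn, ignore.case = TRUE)) {
    stop("interval-censored fit did not converge: ", warn)
  }
  V <- fit$var # (Intercept, Log(scale)) covariance
  if (any(!is.finite(V)) || any(diag(V) <= 0)) {
    stop("interval-censored fit produced a singular information matrix")
  }
  b0 <- unname(stats::coef(fit)[1])
  s0 <- fit$scale
  if (family == "weibull") {
    # survreg AFT: log T = b0 + s0*W  =>  T ~ Weibull(shape 1/s0, scale e^b0)
    shape <- 1 / s0
    scale <- exp(b0)
    se_scale <- scale * sqrt(V[1, 1])
    se_shape <- shape * sqrt(V[2, 2]) # delta method through log(scale)
    cov_ss <- -shape * scale * V[1, 2]
    weibull_params(shape, scale, se_shape = se_shape, se_scale = se_scale,
                   cov_shape_scale = cov_ss, n = nrow(records))
  } else {
    lognormal_params(b0, s0, n = nrow(records),
                     se_meanlog = sqrt(V[1, 1]),
                     se_var = 2 * s0^2 * sqrt(V[2, 2]))
  }
}

#' Draw log-normal parameters from their frequentist sampling distribution
#'
#' The uncertainty half of a second-order simulation for a log-normal input:
#' `K` joint draws of (location, scale) with the location from
#' `N(meanlog, sdlog/sqrt(n))` and the variance from
#' `sdlog^2/(n-1) * chi-square(n-1)` (its square root is used as the scale).
#'
#' @param fit A [lognormal_params()] object with known `n`.
#' @param K Number of parameter sets (>= 1).
#' @param seed Optional integer seed.
#' @return A data frame with `K` rows and columns `meanlog`, `sdlog`.
#' @export
draw_lognormal_params <- function(fit, K, seed = NULL) {
  stopifnot(inherits(fit, "lognormal_params"))
  if (is.na(fit$n)) stop("sample size 'n' required for parameter draws")
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("'K' must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  mu <- stats::rnorm(K, fit$meanlog, fit$sdlog / sqrt(fit$n))
  s2 <- fit$sdlog^2 / (fit$n - 1) * stats::rchisq(K, df = fit$n - 1)
  data.frame(meanlog = mu, sdlog = sqrt(s2))
}

#' Draw a regression parameter from its normal sampling distribution
#'
#' Normal draws `N(estimate, se)` for a parameter estimated by regression
#' (e.g. a Weibull shape from a survival fit). With `positive = TRUE`,
#' non-positive draws are rejected and resampled, which preserves the mean
#' for small rejection rates; when about half or more of the mass lies at or
#' below zero the parametrisation is unsuitable and an error is raised
#' rather than silently biasing the draws.
#'
#' @param estimate Point estimate.
#' @param se Positive standard error.
#' @param K Number of draws (>= 1).
#' @param seed Optional integer seed.
#' @param positive Reject non-positive draws.
#' @return Numeric vector of `K` draws.
#' @export
draw_normal_params <- function(estimate, se, K, seed = NULL,
                               positive = FALSE) {
  stopifnot(is.numeric(estimate), is.numeric(se), length(se) == 1L)
  if (!is.finite(se) || se <= 0) stop("'se' must be strictly positive")
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("'K' must be a positive integer")
  if (positive && stats::pnorm(0, estimate, se) >= 0.45) {
    stop("rejection rate near or above 50%: normal sampling distribution ",
         "unsuitable for a positive parameter (estimate ", estimate,
         ", se ", se, ")")
  }
  if (!is.null(seed)) set.seed(seed)
  draws <- stats::rnorm(K, estimate, se)
  if (positive) {
    while (any(bad <- draws <= 0)) {
      draws[bad] <- stats::rnorm(sum(bad), estimate, se)
    }
  }
  draws
}
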