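#' Log-normal parameter set
#'
#' Container for the location/scale parametrisation of a log-normal input
#' distribution (consumption in log-kg, concentration in log-ppm or threshold
#' in log-mg), together with the sample size and the standard errors that
#' drive its frequentist sampling distribution: the location estimate is
#' normal with standard error `sdlog/sqrt(n)` and the variance estimate is
#' scaled chi-square with `n - 1` degrees of freedom.
#'
#' @param meanlog Location on the natural-log scale.
#' @param sdlog Scale (standard deviation of the logs); must be positive.
#' @param n Sample size behind the estimate (`NA` if unknown; required for
#'   parameter-uncertainty draws).
#' @param se_meanlog Standard error of the location; defaults to
#'   `sdlog / sqrt(n)` when `n` is given.
#' @param se_var Standard deviation of the variance estimator; defaults to
#'   `sdlog^2 * sqrt(2 / (n - 1))`.
#' @return An object of class `lognormal_params`.
#' @seealso [fit_lognormal()], [draw_lognormal_params()]
#' @export
lognormal_params <- function(meanlog, sdlog, n = NA_integer_,
                             se_meanlog = NULL, se_var = NULL) {
  stopifnot(is.numeric(meanlog), length(meanlog) == 1L, is.finite(meanlog),
            is.numeric(sdlog), length(sdlog) == 1L, is.finite(sdlog))
  if (sdlog <= 0) {
    stop("'sdlog' must be strictly positive (degenerate log-normal)")
  }
  n <- as.integer(n)
  if (!is.na(n) && n < 2L) stop("'n' must be at least 2")
  if (is.null(se_meanlog)) {
    se_meanlog <- if (is.na(n)) NA_real_ else sdlog / sqrt(n)
  }
  if (is.null(se_var)) {
    se_var <- if (is.na(n)) NA_real_ else sdlog^2 * sqrt(2 / (n - 1))
  }
  structure(
    list(meanlog = meanlog, sdlog = sdlog, n = n,
         se_meanlog = se_meanlog, se_var = se_var),
    class = "lognormal_params"
  )
}

#' @export
print.lognormal_params <- function(x, ...) {
  cat("Log-normal parameters\n")
  cat(sprintf("  location (log scale): %.4f (SE %.4f)\n",
              x$meanlog, x$se_meanlog))
  cat(sprintf("  scale    (log scale): %.4f\n", x$sdlog))
  cat(sprintf("  n = %s\n", x$n))
  invisible(x)
}

#' Exponential parameter set
#'
#' Rate parametrisation of an exponential contamination distribution
#' (rate in 1/ppm). `data_sum` retains the sufficient statistic so that a
#' conjugate Gamma update can be performed later without the raw data.
#'
#' @param rate Positive rate (1/ppm).
#' @param n Sample size.
#' @param se_rate Standard error of the rate; defaults to the asymptotic
#'   maximum-likelihood value `rate / sqrt(n)`. Published analyses sometimes
#'   report a different sampling SD; pass it here to reproduce them.
#' @param data_sum Sum of the observations (ppm), `n / rate` by default.
#' @return An object of class `exponential_params`.
#' @export
exponential_params <- function(rate, n = NA_integer_, se_rate = NULL,
                               data_sum = NULL) {
  stopifnot(is.numeric(rate), length(rate) == 1L, is.finite(rate))
  if (rate <= 0) stop("'rate' must be strictly positive")
  n <- as.integer(n)
  if (is.null(se_rate)) {
    se_rate <- if (is.na(n)) NA_real_ else rate / sqrt(n)
  }
  if (is.null(data_sum)) {
    data_sum <- if (is.na(n)) NA_real_ else n / rate
  }
  structure(list(rate = rate, n = n, se_rate = se_rate, data_sum = data_sum),
            class = "exponential_params")
}

#' @export
print.exponential_params <- function(x, ...) {
  cat("Exponential parameters\n")
  cat(sprintf("  rate: %.5f (SE %.5f), n = %s\n", x$rate, x$se_rate, x$n))
  invisible(x)
}

#' Weibull parameter set
#'
#' Shape/scale parametrisation of a Weibull threshold (eliciting-dose)
#' distribution, in mg of allergen protein, with the standard errors of the
#' survival-regression fit used for normal parameter-uncertainty draws.
#'
#' @param shape Positive shape parameter (dimensionless).
#' @param scale Positive scale parameter (mg protein).
#' @param se_shape,se_scale Standard errors of the two estimates.
#' @param cov_shape_scale Optional estimated covariance between the two.
#' @param n Number of subjects behind the fit.
#' @return An object of class `weibull_params`.
#' @export
weibull_params <- function(shape, scale, se_shape = NA_real_,
                           se_scale = NA_real_, cov_shape_scale = NA_real_,
                           n = NA_integer_) {
  stopifnot(is.numeric(shape), is.numeric(scale))
  if (shape <= 0 || scale <= 0) {
    stop("Weibull 'shape' and 'scale' must be strictly positive")
  }
  if (!is.na(se_shape) && se_shape <= 0) stop("'se_shape' must be positive")
  if (!is.na(se_scale) && se_scale <= 0) stop("'se_scale' must be positive")
  structure(
    list(shape = shape, scale = scale, se_shape = se_shape,
         se_scale = se_scale, cov_shape_scale = cov_shape_scale,
         n = as.integer(n)),
    class = "weibull_params"
  )
}

#' @export
print.weibull_params <- function(x, ...) {
  cat("Weibull parameters\n")
  cat(sprintf("  shape: %.4f (SE %.4f)\n", x$shape, x$se_shape))
  cat(sprintf("  scale: %.3f mg (SE %.3f)\n", x$scale, x$se_scale))
  invisible(x)
}

# internal: coerce a lognormal_params object or a (meanlog, sdlog) pair
as_logpair <- function(p, what = "parameter") {
  if (inherits(p, "lognormal_params")) {
    return(c(p$meanlog, p$sdlog))
  }
  if (is.numeric(p) && length(p) == 2L && all(is.finite(p))) {
    return(unname(p))
  }
  stop(sprintf("'%s' must be a lognormal_params object or a numeric ",
               what), "(meanlog, sdlog) pair")
}
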