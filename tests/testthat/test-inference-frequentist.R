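test_that("log-normal fit matches hand-computed log moments", {
  f <- fit_lognormal(c(1, exp(2)))
  expect_equal(f$meanlog, 1)
  expect_equal(f$sdlog, sqrt(2))
  expect_equal(f$se_meanlog, sqrt(2) / sqrt(2))

  expect_error(fit_lognormal(rep(exp(1), 4)), "zero variance")
  expect_error(fit_lognormal(c(1, -2, 3)), "positive")
  expect_error(fit_lognormal(2), "at least 2")
})

test_that("log-normal location is recovered within sampling error", {
  # 3-SE coverage of the true location across independent datasets
  hits <- vapply(1:40, function(s) {
    fit <- fit_lognormal(generate_consumption(truth$x, truth$n_x, seed = s))
    abs(fit$meanlog - truth$x[["meanlog"]]) <
      3 * truth$x[["sdlog"]] / sqrt(truth$n_x)
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("exponential fit is the reciprocal sample mean", {
  y <- c(70, 77, 84) # mean 77
  f <- fit_exponential(y)
  expect_equal(f$rate, 1 / 77)
  expect_equal(round(f$rate, 3), 0.013)
  expect_equal(f$data_sum, 231)
  expect_equal(fit_exponential(1)$rate, 1)
  # asymptotic MLE standard error at the published sample size
  f24 <- fit_exponential(rep(77, 24))
  expect_equal(f24$se_rate, (1 / 77) / sqrt(24), tolerance = 1e-12)
  expect_equal(f24$se_rate, 0.00265, tolerance = 0.01)
  # explicit override for reproducing published sampling SDs
  expect_equal(fit_exponential(rep(77, 24), se_rate = 0.001)$se_rate, 0.001)
  expect_error(fit_exponential(numeric(0)), "at least 1")
})

test_that("log-normal parameter draws follow their sampling laws", {
  fit <- paper_pars$sampling$x # (-3.719, 0.747), n = 350
  d <- draw_lognormal_params(fit, K = 1e5, seed = 41)
  expect_equal(sd(d$meanlog), 0.747 / sqrt(350), tolerance = 0.02)
  expect_equal(mean(d$meanlog), -3.719, tolerance = 1e-3)
  # chi-square identity: the drawn variances are unbiased for sdlog^2
  expect_equal(mean(d$sdlog^2), 0.747^2, tolerance = 0.01)
  expect_true(all(d$sdlog > 0))
  # location draws symmetric about the estimate
  ctr <- d$meanlog - mean(d$meanlog)
  skew <- mean(ctr^3) / sd(d$meanlog)^3
  expect_lt(abs(skew), 0.05)

  # huge n: draws collapse onto the point estimate
  tight <- draw_lognormal_params(lognormal_params(-3.719, 0.747, n = 1e8),
                                 K = 100, seed = 42)
  expect_equal(tight$meanlog, rep(-3.719, 100), tolerance = 1e-3)
  expect_equal(tight$sdlog, rep(0.747, 100), tolerance = 1e-3)
})

test_that("normal parameter draws respect positivity and the published band", {
  d <- draw_normal_params(0.382, 0.027, K = 1e5, seed = 43)
  q <- quantile(d, c(0.025, 0.975), names = FALSE)
  # published 95% band for the Weibull shape
  expect_equal(q[1], 0.331, tolerance = 0.02)
  expect_equal(q[2], 0.438, tolerance = 0.02)

  tight <- draw_normal_params(5, 1e-9, K = 10, seed = 44)
  expect_equal(tight, rep(5, 10), tolerance = 1e-6)

  pos <- draw_normal_params(0.1, 0.08, K = 1e4, seed = 45, positive = TRUE)
  expect_true(all(pos > 0))
  expect_error(draw_normal_params(0.001, 1, K = 10, positive = TRUE),
               "rejection rate")
  expect_error(draw_normal_params(1, 0, K = 10), "positive")
})

test_that("interval-censored Weibull MLE matches a direct likelihood search", {
  ch <- make_challenges(seed = 51)
  fit <- fit_interval_censored(ch, "weibull")
  # independent oracle: direct optimisation of the censored log-likelihood
  nll <- function(th) {
    -allergenrisk:::censored_loglik(ch, "weibull", exp(th[1]), exp(th[2]))
  }
  opt <- optim(c(0, 5), nll)
  expect_equal(fit$shape, exp(opt$par[1]), tolerance = 1e-3)
  expect_equal(fit$scale, exp(opt$par[2]), tolerance = 1e-3)
  expect_true(fit$se_shape > 0 && fit$se_scale > 0)
})

test_that("interval-censored MLE approaches the uncensored fit on a fine grid", {
  ch <- generate_challenge_data("weibull", truth$z_weibull, 500,
                                grid = fine_grid(), seed = 52,
                                keep_latent = TRUE)
  cens <- fit_interval_censored(ch, "weibull")
  direct <- survival::survreg(survival::Surv(latent_mg) ~ 1, data = ch,
                              dist = "weibull")
  expect_equal(cens$shape, 1 / direct$scale, tolerance = 0.01)
  expect_equal(cens$scale, exp(coef(direct)[[1]]), tolerance = 0.01)
})

test_that("Weibull shape is recovered across seeded challenge studies", {
  shapes <- vapply(1:20, function(s) {
    fit_interval_censored(make_challenges(seed = 100 + s), "weibull")$shape
  }, numeric(1))
  expect_equal(mean(shapes), truth$z_weibull[["shape"]], tolerance = 0.1)
})

test_that("log-normal threshold fit reports the expected location SE", {
  fit <- fit_interval_censored(make_challenges(seed = 53,
                                               family = "lognormal"),
                               "lognormal")
  # about sigma/sqrt(n) = 2.98/sqrt(158)
  expect_equal(fit$se_meanlog, 0.24, tolerance = 0.25)
})

test_that("degenerate challenge data are rejected", {
  all_left <- data.frame(lower_mg = NA_real_, upper_mg = 0.1,
                         censor = "left")[rep(1, 10), ]
  expect_error(fit_interval_censored(all_left, "weibull"),
               "not identifiable")
  all_right <- data.frame(lower_mg = 1000, upper_mg = NA_real_,
                          censor = "right")[rep(1, 10), ]
  expect_error(fit_interval_censored(all_right, "weibull"),
               "not identifiable")
  one <- data.frame(lower_mg = 1, upper_mg = 2, censor = "interval")
  expect_error(fit_interval_censored(one, "weibull"), "at least 2")
})
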