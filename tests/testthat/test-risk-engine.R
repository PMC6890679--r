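test_that("closed-form risk behaves like 1 - Phi of the standardised gap", {
  # symmetric configuration: exposure and threshold balance exactly
  expect_equal(closed_form_risk(c(1, 1), c(2, 1), c(3, 1)), 0.5)
  # limits in the threshold location
  expect_lt(closed_form_risk(c(1, 1), c(2, 1), c(50, 1)), 1e-10)
  expect_gt(closed_form_risk(c(1, 1), c(2, 1), c(-50, 1)), 1 - 1e-10)
  # degenerate: all scales zero
  expect_error(closed_form_risk(c(1, 0), c(2, 0), c(3, 0)), "degenerate")
  # monotone in each location parameter
  base <- closed_form_risk(c(-3.7, 0.7), c(3.5, 1.3), c(4.1, 3.0))
  expect_gt(closed_form_risk(c(-3.2, 0.7), c(3.5, 1.3), c(4.1, 3.0)), base)
  expect_gt(closed_form_risk(c(-3.7, 0.7), c(4.0, 1.3), c(4.1, 3.0)), base)
  expect_lt(closed_form_risk(c(-3.7, 0.7), c(3.5, 1.3), c(4.6, 3.0)), base)
})

test_that("indicator simulation agrees with the closed form", {
  p <- paper_pars$plugin
  exact <- closed_form_risk(p$x, p$y, p$z)
  n <- 1e6
  sim <- simulate_risk_indicator(
    function(m) rlnorm(m, p$x[1], p$x[2]),
    function(m) rlnorm(m, p$y[1], p$y[2]),
    function(m) rlnorm(m, p$z[1], p$z[2]),
    n = n, seed = 81
  )
  expect_lt(abs(sim - exact), 3 * sqrt(exact * (1 - exact) / n))
})

test_that("indicator handles degenerate thresholds", {
  xs <- function(m) rlnorm(m, -3.7, 0.7)
  ys <- function(m) rlnorm(m, 3.5, 1.3)
  expect_equal(simulate_risk_indicator(xs, ys, function(m) rep(0, m),
                                       n = 1000, seed = 82), 1)
  expect_equal(simulate_risk_indicator(xs, ys, function(m) rep(Inf, m),
                                       n = 1000, seed = 83), 0)
  expect_error(simulate_risk_indicator(xs, ys, xs, n = 0), "positive")
})

test_that("dose-response risk evaluates the threshold CDF at the exposure", {
  w <- truth$z_weibull
  # fixed exposure of 1.87 mg: risk is the CDF value, by the Weibull formula
  expected <- 1 - exp(-(1.87 / w[["scale"]])^w[["shape"]])
  got <- simulate_risk_doseresponse(
    function(m) rep(1.87, m), function(m) rep(1, m),
    function(q) pweibull(q, w[["shape"]], w[["scale"]]),
    n = 100, seed = 84
  )
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(simulate_risk_doseresponse(
    function(m) rep(1, m), function(m) rep(1, m),
    function(q) rep(1, length(q)), n = 10, seed = 85), 1)
})

test_that("indicator and dose-response estimators agree in expectation", {
  p <- paper_pars$sampling
  w <- truth$z_weibull
  n <- 1e6
  xs <- function(m) rlnorm(m, p$x$meanlog, p$x$sdlog)
  ys <- function(m) rexp(m, truth$y_rate)
  ind <- simulate_risk_indicator(
    xs, ys, function(m) rweibull(m, w[["shape"]], w[["scale"]]),
    n = n, seed = 86
  )
  set.seed(87)
  fz <- pweibull(xs(n) * ys(n), w[["shape"]], w[["scale"]])
  dr <- mean(fz)
  se_ind <- sqrt(ind * (1 - ind) / n)
  se_dr <- sd(fz) / sqrt(n)
  expect_lt(abs(ind - dr), 3 * sqrt(se_ind^2 + se_dr^2))
})

test_that("run_case with K = 1 and no uncertainty equals one plain simulation", {
  spec <- peanut_cereal_case("A", K = 1, n = 5000, seed = 88)
  res <- run_case(spec)
  p <- paper_pars$plugin
  direct <- simulate_risk_indicator(
    function(m) rlnorm(m, p$x[1], p$x[2]),
    function(m) rlnorm(m, p$y[1], p$y[2]),
    function(m) rlnorm(m, p$z[1], p$z[2]),
    n = 5000, seed = 88
  )
  expect_equal(res$risks, direct)
  expect_equal(res$K, 1L)
  expect_false(res$uncertainty)
})

test_that("second-order runs are reproducible and order-consistent", {
  spec <- peanut_cereal_case("B_simulated", K = 50, n = 1000, seed = 89)
  a <- run_case(spec)
  b <- run_case(spec)
  expect_identical(a$risks, b$risks)
  expect_true(all(a$risks >= 0 & a$risks <= 1))
  expect_lte(a$p2.5, a$median)
  expect_lte(a$median, a$p97.5)
  # summary is invariant to the order of replications
  perm <- allergenrisk:::risk_distribution(sample(a$risks), "B", "indicator")
  expect_equal(perm$mean, a$mean)
  expect_equal(perm$p97.5, a$p97.5)
})

test_that("risk responds monotonically to stochastically larger inputs", {
  shift <- function(dx = 0, dy = 0, dz = 0) {
    p <- peanut_cereal_params()$sampling
    run_case(case_spec(
      "shift",
      input_lognormal(lognormal_params(p$x$meanlog + dx, p$x$sdlog,
                                       n = 350), "sampling"),
      input_lognormal(lognormal_params(p$y$meanlog + dy, p$y$sdlog,
                                       n = 24), "sampling"),
      input_lognormal(lognormal_params(p$z$meanlog + dz, p$z$sdlog,
                                       n = 158), "sampling"),
      risk_method = "closed_form", K = 400, seed = 90
    ))$mean
  }
  base <- shift()
  expect_gt(shift(dx = 0.5), base)
  expect_gt(shift(dy = 0.5), base)
  expect_lt(shift(dz = 0.5), base)
})

test_that("case specifications are validated", {
  p <- paper_pars$sampling
  ln <- input_lognormal(p$x, "sampling")
  exp_in <- input_exponential(paper_pars$exponential_y, "normal")
  wb <- input_weibull(paper_pars$weibull_z, "normal")
  expect_error(case_spec("bad", ln, exp_in, wb,
                         risk_method = "closed_form"),
               "three log-normal")
  expect_error(case_spec("bad", ln, ln, ln, K = 0), "positive integer")
  emp <- input_empirical(1:10, uncertainty = "bootstrap")
  expect_error(case_spec("bad", ln, exp_in, emp,
                         risk_method = "dose_response"),
               "parametric threshold")
})
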