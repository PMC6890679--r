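test_that("consumption generator reproduces the log-normal law", {
  x <- generate_consumption(truth$x, n = 1e6, seed = 11)
  # closed-form log-normal median exp(meanlog); MC error on the median is
  # well below 1% at this n
  expect_equal(median(x), exp(truth$x[["meanlog"]]), tolerance = 0.01)
  expect_true(all(x > 0))

  # refit recovers the location within 3 standard errors
  fit <- fit_lognormal(generate_consumption(truth$x, n = truth$n_x,
                                            seed = 12))
  expect_lt(abs(fit$meanlog - truth$x[["meanlog"]]),
            3 * truth$x[["sdlog"]] / sqrt(truth$n_x))
})

test_that("consumption generator rejects invalid arguments", {
  expect_error(generate_consumption(c(0, 1), n = 0), "positive integer")
  expect_error(generate_consumption(c(0, -1), n = 10), "positive")
  expect_error(generate_consumption(c(0, 0), n = 10), "positive")
})

test_that("heavy-tail mixture inflates the upper tail only when requested", {
  base <- generate_consumption(truth$x, n = 2e4, seed = 13)
  heavy <- generate_consumption(truth$x, n = 2e4, seed = 13,
                                tail_weight = 0.1, tail_scale = 3)
  expect_gt(quantile(heavy, 0.995), quantile(base, 0.995))
  expect_equal(median(heavy), median(base), tolerance = 0.05)
})

test_that("concentration generator matches family moments", {
  y <- generate_concentration("exponential", truth$y_rate, n = 2e5,
                              seed = 21)
  expect_equal(mean(y), 1 / truth$y_rate, tolerance = 0.01)
  # rate refit is 1/sample-mean by construction
  f <- fit_exponential(generate_concentration("exponential", truth$y_rate,
                                              n = 24, seed = 22))
  expect_gt(f$rate, 0)

  # log-normal mean formula exp(mu + sigma^2/2), independent of rlnorm
  yl <- generate_concentration("lognormal", c(3.496, 1.283), n = 1e6,
                               seed = 23)
  expect_equal(mean(yl), exp(3.496 + 1.283^2 / 2), tolerance = 0.01)
  expect_error(generate_concentration("gamma", 1, n = 10))
})

test_that("challenge records bracket their latent thresholds", {
  ch <- make_challenges(seed = 31, keep_latent = TRUE)
  lo <- ifelse(is.na(ch$lower_mg), -Inf, ch$lower_mg)
  up <- ifelse(is.na(ch$upper_mg), Inf, ch$upper_mg)
  expect_true(all(ch$latent_mg > lo & ch$latent_mg <= up))
  expect_true(all(ch$censor %in% c("interval", "left", "right")))
  # censor flags consistent with the bounds
  expect_true(all(is.na(ch$lower_mg[ch$censor == "left"])))
  expect_true(all(is.na(ch$upper_mg[ch$censor == "right"])))
})

test_that("thresholds outside the dose grid are censored at the grid edges", {
  grid <- dose_grid(c(10, 100))
  # scale far below the first dose: almost everything reacts at dose one
  low <- generate_challenge_data("weibull", c(2, 0.1), 50, grid = grid,
                                 seed = 32, keep_latent = TRUE)
  below <- low$latent_mg < 10
  expect_true(all(low$censor[below] == "left"))
  expect_true(all(low$upper_mg[below] == 10))
  # scale far above the last dose: almost everything is right-censored
  high <- generate_challenge_data("weibull", c(2, 1e4), 50, grid = grid,
                                  seed = 33, keep_latent = TRUE)
  above <- high$latent_mg > 100
  expect_true(all(high$censor[above] == "right"))
  expect_true(all(high$lower_mg[above] == 100))
})

test_that("latent thresholds converge to the target CDF", {
  for (n in c(200, 5000)) {
    ch <- generate_challenge_data("weibull", truth$z_weibull, n,
                                  seed = 34, keep_latent = TRUE)
    d <- suppressWarnings(ks.test(
      ch$latent_mg, pweibull,
      truth$z_weibull[["shape"]], truth$z_weibull[["scale"]]
    ))$statistic
    assign(paste0("d", n), unname(d))
  }
  expect_lt(d5000, d200)
  expect_lt(d5000, 0.03)
})

test_that("generators are reproducible and extensible by subject", {
  a <- make_challenges(seed = 35, n = 50)
  b <- make_challenges(seed = 35, n = 50)
  expect_identical(a, b)
  # per-subject streams: adding subjects leaves earlier rows unchanged
  longer <- make_challenges(seed = 35, n = 80)
  expect_identical(longer[1:50, ], a)
})

test_that("dose grids are validated", {
  expect_error(dose_grid(5), "at least 2")
  expect_error(dose_grid(c(1, 1)), "strictly increasing")
  expect_error(dose_grid(c(-1, 2)), "positive")
  expect_length(dose_grid(), 10)
})
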