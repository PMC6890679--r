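#' Challenge dose grid
#'
#' Validates the ordered set of doses administered in a (synthetic)
#' double-blind placebo-controlled food challenge (DBPCFC) protocol. Latent
#' individual thresholds are only observed through the interval between
#' consecutive doses, which is what makes the challenge data
#' interval-censored. The default grid is a geometric series of 10 doses from
#' 0.1 mg to 1000 mg protein, spanning the scale of published peanut
#' eliciting-dose fits with realistic challenge spacing.
#'
#' @param doses Strictly increasing positive doses (mg protein), length >= 2.
#' @return The validated numeric dose vector.
#' @export
#' @examples
#' dose_grid()
#' dose_grid(c(0.3, 1, 3, 10, 30, 100, 300))
dose_grid <- function(doses = 10^seq(-1, 3, length.out = 10)) {
  if (!is.numeric(doses) || length(doses) < 2L) {
    stop("a dose grid needs at least 2 numeric doses")
  }
  if (any(!is.finite(doses)) || any(doses <= 0)) {
    stop("all challenge doses must be finite and positive")
  }
  if (any(diff(doses) <= 0)) {
    stop("challenge doses must be strictly increasing")
  }
  doses
}

#' Generate single-occasion consumption amounts
#'
#' Draws consumption amounts (kg of product per eating occasion) from a
#' log-normal distribution, optionally contaminated with a heavier-tailed
#' log-normal component: survey consumption data are typically
#' heavier-tailed than their log-normal fit, and the mixture lets the
#' generator mimic that when needed. The default (`tail_weight = 0`) is a
#' pure log-normal.
#'
#' @param params Log-scale `(meanlog, sdlog)` pair or [lognormal_params()]
#'   object (log-kg).
#' @param n Number of eating occasions to draw (>= 1).
#' @param seed Optional integer seed.
#' @param tail_weight Probability mass of the heavy-tail component, in
#'   `[0, 1)`; 0 disables the mixture.
#' @param tail_scale Multiplier (> 1) applied to `sdlog` in the tail
#'   component.
#' @return Numeric vector of `n` positive amounts (kg).
#' @export
#' @examples
#' x <- generate_consumption(c(-3.719, 0.747), n = 350, seed = 1)
#' median(x) # about exp(-3.719) = 0.024 kg
generate_consumption <- function(params, n, seed = NULL,
                                 tail_weight = 0, tail_scale = 3) {
  p <- as_logpair(params, "params")
  if (p[2] <= 0) stop("log-normal scale must be strictly positive")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  stopifnot(tail_weight >= 0, tail_weight < 1, tail_scale >= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rlnorm(n, p[1], p[2])
  if (tail_weight > 0) {
    in_tail <- stats::runif(n) < tail_weight
    if (any(in_tail)) {
      x[in_tail] <- stats::rlnorm(sum(in_tail), p[1], p[2] * tail_scale)
    }
  }
  x
}

#' Generate allergen concentration measurements
#'
#' Draws allergen concentrations in the contaminated product (ppm = mg
#' allergen per kg product) from either an exponential or a log-normal
#' contamination model.
#'
#' @param family `"exponential"` or `"lognormal"`.
#' @param params For `"exponential"`, a single positive rate (1/ppm); for
#'   `"lognormal"`, a `(meanlog, sdlog)` pair or [lognormal_params()] object.
#' @param n Number of measurements (>= 1).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` positive concentrations (ppm).
#' @export
#' @examples
#' y <- generate_concentration("exponential", 0.013, n = 24, seed = 1)
generate_concentration <- function(family = c("exponential", "lognormal"),
                                   params, n, seed = NULL) {
  family <- match.arg(family)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  switch(family,
    exponential = {
      rate <- if (inherits(params, "exponential_params")) params$rate
              else params
      stopifnot(is.numeric(rate), length(rate) == 1L)
      if (!is.finite(rate) || rate <= 0) {
        stop("exponential rate must be strictly positive")
      }
      stats::rexp(n, rate)
    },
    lognormal = {
      p <- as_logpair(params, "params")
      if (p[2] <= 0) stop("log-normal scale must be strictly positive")
      stats::rlnorm(n, p[1], p[2])
    }
  )
}

# internal: one latent threshold draw for the requested family
r_threshold <- function(family, params) {
  switch(family,
    weibull = {
      if (inherits(params, "weibull_params")) {
        stats::rweibull(1L, params$shape, params$scale)
      } else {
        stopifnot(is.numeric(params), length(params) == 2L)
        if (any(params <= 0)) stop("Weibull parameters must be positive")
        stats::rweibull(1L, params[1], params[2])
      }
    },
    lognormal = {
      p <- as_logpair(params, "params")
      if (p[2] <= 0) stop("log-normal scale must be strictly positive")
      stats::rlnorm(1L, p[1], p[2])
    }
  )
}

#' Generate interval-censored food-challenge data
#'
#' Simulates a DBPCFC study: each subject has a latent eliciting dose drawn
#' from the threshold distribution, observed only through the challenge dose
#' grid. The reported lower bound is the largest dose strictly below the
#' latent threshold (the subject's NOAEL) and the upper bound the smallest
#' dose at or above it (the LOAEL). A threshold below the first dose yields a
#' left-censored record, above the last dose a right-censored one.
#'
#' Each subject consumes an independent random stream derived from `seed` by
#' counter offset, so increasing `n_subjects` extends the dataset without
#' reshuffling earlier subjects.
#'
#' @param threshold_family `"weibull"` or `"lognormal"`.
#' @param params Family parameters: `(shape, scale)` pair /
#'   [weibull_params()], or `(meanlog, sdlog)` pair / [lognormal_params()]
#'   (mg protein).
#' @param n_subjects Number of challenged subjects (>= 1).
#' @param grid Challenge [dose_grid()].
#' @param seed Optional integer seed (per-subject streams are `seed + i - 1`).
#' @param keep_latent Keep the latent thresholds in a `latent_mg` column.
#'   Intended for testing only; fitting functions ignore the column.
#' @return A data frame with columns `lower_mg`, `upper_mg`, `censor`
#'   (`"interval"`, `"left"` or `"right"`) and optionally `latent_mg`.
#'   Left-censored rows have `lower_mg = NA`, right-censored rows
#'   `upper_mg = NA`.
#' @export
#' @examples
#' ch <- generate_challenge_data("weibull", c(0.38, 229.6), 158, seed = 7)
#' table(ch$censor)
generate_challenge_data <- function(threshold_family = c("weibull", "lognormal"),
                                    params, n_subjects, grid = dose_grid(),
                                    seed = NULL, keep_latent = FALSE) {
  threshold_family <- match.arg(threshold_family)
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L) {
    stop("'n_subjects' must be a positive integer")
  }
  grid <- dose_grid(grid)
  r_threshold(threshold_family, params) # validate params before looping
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (seed + n_subjects >= .Machine$integer.max) {
      stop("'seed' too large for per-subject offsets")
    }
  }
  latent <- vapply(seq_len(n_subjects), function(i) {
    if (!is.null(seed)) set.seed(seed + i - 1L)
    r_threshold(threshold_family, params)
  }, numeric(1))

  n_below <- vapply(latent, function(t) sum(grid < t), integer(1))
  m <- length(grid)
  lower <- ifelse(n_below >= 1L, grid[pmax(n_below, 1L)], NA_real_)
  upper <- ifelse(n_below < m, grid[pmin(n_below + 1L, m)], NA_real_)
  censor <- ifelse(n_below == 0L, "left",
                   ifelse(n_below == m, "right", "interval"))
  out <- data.frame(lower_mg = lower, upper_mg = upper, censor = censor,
                    stringsAsFactors = FALSE)
  if (keep_latent) out$latent_mg <- latent
  out
}
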