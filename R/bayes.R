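#' Conjugate Gamma posterior for an exponential rate
#'
#' Exact Bayesian update for the contamination rate: with an
#' `Exponential(rate)` likelihood and a `Gamma(alpha, beta)` prior, the
#' posterior is `Gamma(alpha + n, beta + sum(y))`. The default prior is the
#' vague `Gamma(1e-3, 1e-3)`.
#'
#' @param sample Non-negative concentration observations (ppm); may be empty,
#'   in which case the posterior equals the prior.
#' @param prior_alpha,prior_beta Positive prior shape and rate.
#' @return An object of class `gamma_posterior` with fields `alpha`, `beta`,
#'   `mean` (`alpha/beta`) and `sd` (`sqrt(alpha)/beta`).
#' @export
#' @examples
#' post <- exponential_gamma_posterior(rep(77, 24))
#' post$mean # 24.001 / 1848.001
exponential_gamma_posterior <- function(sample, prior_alpha = 1e-3,
                                        prior_beta = 1e-3) {
  stopifnot(is.numeric(prior_alpha), is.numeric(prior_beta))
  if (prior_alpha <= 0 || prior_beta <= 0) {
    stop("prior parameters must be strictly positive")
  }
  if (length(sample) > 0) {
    if (!is.numeric(sample) || any(!is.finite(sample)) || any(sample < 0)) {
      stop("observations must be finite and non-negative")
    }
  }
  alpha <- prior_alpha + length(sample)
  beta <- prior_beta + sum(sample)
  structure(
    list(alpha = alpha, beta = beta,
         mean = alpha / beta, sd = sqrt(alpha) / beta,
         prior = c(alpha = prior_alpha, beta = prior_beta),
         n = length(sample)),
    class = "gamma_posterior"
  )
}

#' @export
print.gamma_posterior <- function(x, ...) {
  cat(sprintf("Gamma posterior for exponential rate: Gamma(%.4g, %.4g)\n",
              x$alpha, x$beta))
  cat(sprintf("  mean %.5f, sd %.5f (n = %d)\n", x$mean, x$sd, x$n))
  invisible(x)
}

# internal: split-chain potential scale reduction factor (one parameter)
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(ch) {
    h <- length(ch) %/% 2L
    list(ch[seq_len(h)], ch[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' MCMC posterior for an interval-censored Weibull threshold distribution
#'
#' Samples the posterior of the Weibull eliciting-dose parameters given
#' interval-censored challenge outcomes, with independent vague Gamma priors
#' on shape and scale (both positive). The target density is the censored
#' likelihood of [fit_interval_censored()] times the priors; the sampler is
#' an adaptive random-walk Metropolis on `(log shape, log scale)` with the
#' Jacobian correction, run as multiple dispersed chains. Convergence is
#' monitored by the split-chain potential scale reduction factor; a value
#' above `rhat_threshold` attaches a warning to the result rather than
#' failing silently.
#'
#' @param records Challenge data frame (see [generate_challenge_data()]).
#' @param K Number of pooled post-burn-in draws to return (>= 1).
#' @param prior_shape,prior_scale Length-2 `(shape, rate)` Gamma prior
#'   parameters for the Weibull shape and scale; default vague
#'   `Gamma(1e-3, 1e-3)`.
#' @param n_iter Iterations per chain.
#' @param n_burnin Burn-in iterations per chain (adaptation happens here).
#' @param n_chains Number of chains (>= 2 for the diagnostic).
#' @param seed Optional integer seed.
#' @param rhat_threshold Convergence threshold for the diagnostic.
#' @return An object of class `posterior_draws`: list with `draws` (data
#'   frame, columns `shape` and `scale`), `rhat`, `accept_rate`, `n_chains`,
#'   `n_burnin`, `thinning`, `converged`.
#' @export
weibull_threshold_mcmc <- function(records, K = 1000,
                                   prior_shape = c(1e-3, 1e-3),
                                   prior_scale = c(1e-3, 1e-3),
                                   n_iter = 20000, n_burnin = 5000,
                                   n_chains = 2, seed = NULL,
                                   rhat_threshold = 1.05) {
  records <- validate_challenges(records)
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("'K' must be a positive integer")
  stopifnot(n_iter > n_burnin, n_burnin >= 1, n_chains >= 2,
            all(prior_shape > 0), all(prior_scale > 0))
  if (all(records$censor == "left") || all(records$censor == "right")) {
    stop("threshold posterior is not identifiable: ",
         "all records censored on the same side")
  }
  kept_per_chain <- n_iter - n_burnin
  if (n_chains * kept_per_chain < K) {
    stop("chains too short to return K post-burn-in draws")
  }
  if (!is.null(seed)) set.seed(seed)

  log_post <- function(th) {
    a <- exp(th[1])
    b <- exp(th[2])
    ll <- censored_loglik(records, "weibull", a, b)
    if (!is.finite(ll)) return(-Inf)
    ll +
      stats::dgamma(a, prior_shape[1], prior_shape[2], log = TRUE) +
      stats::dgamma(b, prior_scale[1], prior_scale[2], log = TRUE) +
      th[1] + th[2] # Jacobian of the log transform
  }

  # crude moment start from interval midpoints (censored rows imputed)
  mid <- ifelse(records$censor == "interval",
                sqrt(records$lower_mg * records$upper_mg),
                ifelse(records$censor == "left",
                       records$upper_mg / 2, records$lower_mg * 2))
  start0 <- c(log(0.5), log(max(mean(mid), 1e-6)))

  chains <- vector("list", n_chains)
  acc_total <- 0L
  for (c_idx in seq_len(n_chains)) {
    th <- start0 + stats::rnorm(2, 0, 0.5) # dispersed starts
    lp <- log_post(th)
    if (!is.finite(lp)) {
      th <- start0
      lp <- log_post(th)
    }
    step <- c(0.2, 0.2)
    out <- matrix(NA_real_, kept_per_chain, 2L)
    acc_batch <- 0L
    batch <- 0L
    for (it in seq_len(n_iter)) {
      prop <- th + stats::rnorm(2) * step
      lp_prop <- log_post(prop)
      if (is.finite(lp_prop) &&
          log(stats::runif(1)) < lp_prop - lp) {
        th <- prop
        lp <- lp_prop
        acc_batch <- acc_batch + 1L
        if (it > n_burnin) acc_total <- acc_total + 1L
      }
      if (it <= n_burnin && it %% 50L == 0L) {
        batch <- batch + 1L
        rate <- acc_batch / 50
        step <- step * exp((rate - 0.3) / sqrt(batch))
        acc_batch <- 0L
      }
      if (it > n_burnin) out[it - n_burnin, ] <- th
    }
    chains[[c_idx]] <- out
  }

  rhat <- c(
    shape = split_rhat(lapply(chains, function(m) m[, 1])),
    scale = split_rhat(lapply(chains, function(m) m[, 2]))
  )
  pooled <- exp(do.call(rbind, chains))
  thin_by <- max(1L, nrow(pooled) %/% K)
  idx <- seq(1L, nrow(pooled), by = thin_by)[seq_len(K)]
  draws <- data.frame(shape = pooled[idx, 1], scale = pooled[idx, 2])

  res <- structure(
    list(draws = draws, rhat = rhat,
         accept_rate = acc_total / (n_chains * kept_per_chain),
         n_chains = n_chains, n_burnin = n_burnin, thinning = thin_by,
         converged = all(is.finite(rhat)) & all(rhat < rhat_threshold)),
    class = "posterior_draws"
  )
  if (!res$converged) {
    warning("MCMC convergence diagnostic above threshold (max Rhat = ",
            signif(max(rhat), 4), ")")
  }
  res
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("Posterior draws: %d retained (%d chains, burn-in %d, thin %d)\n",
              nrow(x$draws), x$n_chains, x$n_burnin, x$thinning))
  cat(sprintf("  shape: mean %.4f sd %.4f (Rhat %.3f)\n",
              mean(x$draws$shape), stats::sd(x$draws$shape), x$rhat["shape"]))
  cat(sprintf("  scale: mean %.3f sd %.3f (Rhat %.3f)\n",
              mean(x$draws$scale), stats::sd(x$draws$scale), x$rhat["scale"]))
  cat(sprintf("  acceptance %.2f, converged: %s\n",
              x$accept_rate, x$converged))
  invisible(x)
}

#' Weighted bootstrap resample
#'
#' Sampling with replacement from an observed sample, with selection
#' probability proportional to optional survey weights (uniform when
#' absent). Used to propagate consumption uncertainty when no parametric
#' consumption model is assumed.
#'
#' @param sample Non-empty numeric sample.
#' @param weights Optional non-negative weights, same length as `sample`,
#'   not all zero.
#' @param size Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of `size` resampled values.
#' @export
bootstrap_sample <- function(sample, weights = NULL, size, seed = NULL) {
  if (!is.numeric(sample) || length(sample) < 1L) {
    stop("'sample' must be a non-empty numeric vector")
  }
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(sample))
    if (any(weights < 0) || any(!is.finite(weights))) {
      stop("weights must be finite and non-negative")
    }
    if (sum(weights) == 0) stop("weights must not be all zero")
  }
  size <- as.integer(size)
  if (is.na(size) || size < 1L) stop("'size' must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  sample[sample.int(length(sample), size, replace = TRUE, prob = weights)]
}
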