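---
title: "Probabilistic food allergen risk assessment with allergenrisk"
author: "allergenrisk authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic food allergen risk assessment with allergenrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allergenrisk)
```

## The model

Precautionary allergen labelling ("may contain ...") should rest on a
quantitative assessment of the health risk that accidental cross-contact
poses to allergic consumers. `allergenrisk` implements the standard
population-level model for that assessment. For one eating occasion by an
allergic consumer of a contaminated product, three independent random
quantities determine the outcome:

* $X$ — the amount of product consumed on the occasion (kg),
* $Y$ — the allergen concentration in the product (ppm, mg allergen per kg
  product),
* $Z$ — the consumer's eliciting dose (mg allergen protein), i.e. the
  minimum dose provoking an objective reaction.

The exposure is $XY$ (mg), a reaction occurs when $Z < XY$, and the
population risk per eating occasion is

$$p \;=\; P(Z < XY).$$

Two equivalent Monte Carlo estimators are provided. The *indicator* route
draws a threshold for each simulated individual and counts exceedances
($U = \mathbf{1}\{Z < XY\}$, strictly; a tie counts as no reaction — a
measure-zero event for continuous inputs). The *dose–response* route
evaluates the threshold CDF (the dose–response curve) at each simulated
exposure and averages, $\hat p = \frac1n \sum_i F_Z(X_i Y_i)$. By the law of
total expectation the two have the same expectation; the dose–response
estimator has smaller Monte Carlo variance because the threshold is
integrated out. `test-risk-engine.R` verifies their agreement within
combined Monte Carlo error at $n = 10^6$.

When all three inputs are log-normal the risk is available in closed form:
with location/scale $(\mu_x,\sigma_x)$ etc. on the natural-log scale,

$$p \;=\; 1 - \Phi\!\left(\frac{\mu_z - \mu_x - \mu_y}
{\sqrt{\sigma_x^2 + \sigma_y^2 + \sigma_z^2}}\right).$$

Units must be consistent: log-kg consumption plus log-ppm concentration
gives log-mg exposure, matched against thresholds in log-mg protein. The
package adopts this convention throughout and states it in every relevant
help page, because it is easy to lose a factor of $10^3$ here.

## Variability versus uncertainty: second-order Monte Carlo

A single Monte Carlo loop mixes two very different things: *variability*
(individuals differ) and *uncertainty* (the input parameters are estimated
from finite samples). `run_case()` separates them with a nested,
second-order design: an outer loop draws $K$ parameter sets from the
uncertainty distribution of each input, and an inner loop of $n$
individuals yields one risk per parameter set. The $K$ per-replication
risks form the uncertainty distribution of the risk, summarised by the mean,
SD and 2.5/50/97.5 empirical percentiles (median-unbiased interpolation,
`type = 8`; the convention matters little at $K = 1000$ but is fixed for
reproducibility). Defaults are $K = 1000$ replications and $n = 10\,000$
iterations, a widely used compromise between accuracy and cost for this
model class.

Four canonical configurations (built by `peanut_cereal_case()` for the
worked example, or assembled freely with `case_spec()`) differ in where the
parameter uncertainty comes from:

* **A** — plug-in: point estimates only. The spread of the $K$ risks then
  reflects simulation error, not input uncertainty, and the result object
  says so when printed.
* **B** — triple log-normal with frequentist sampling distributions: the
  location is drawn from $\mathcal N(\hat\mu, \hat\sigma/\sqrt{n})$ and the
  variance from $\hat\sigma^2 \chi^2_{n-1}/(n-1)$ — exact laws for normal
  logs, which is why the fit uses the $n-1$ denominator. Case B can be
  *calculated* (closed form per parameter draw; no inner loop, roughly four
  orders of magnitude faster) or *simulated* (indicator inner loop); the two
  agree within half a percentage point on the worked example.
* **C** — log-normal consumption, exponential concentration and Weibull
  thresholds, with regression-style normal draws
  $\mathcal N(\hat\theta, \widehat{se})$ for the rate, shape and scale
  (positive draws only), and dose–response risk.
* **D** — the Bayesian counterpart of C: bootstrap resampling of the
  consumption sample (weighted, if survey weights exist), the conjugate
  Gamma posterior for the exponential rate, and an MCMC posterior for the
  Weibull threshold parameters.

## Fitting the inputs

`fit_lognormal()` and `fit_exponential()` are moment/ML fits with the
standard errors stated above. The exponential rate SE defaults to the
asymptotic $\hat\lambda/\sqrt{n}$ but accepts an explicit override, because
published analyses sometimes report a different sampling SD for the rate
and reproducing them requires using their value.

Thresholds are only observed as intervals: a food challenge administers an
increasing dose series, and a subject's latent eliciting dose lies between
the highest tolerated dose (NOAEL) and the first reactive dose (LOAEL) —
below the first dose (left-censored) or above the last (right-censored) at
the extremes. `fit_interval_censored()` maximises the censored likelihood
$\sum_i \log[F(u_i) - F(l_i)]$ through `survival::survreg()`
(intercept-only accelerated-failure model, Weibull or log-normal), with
delta-method back-transformation of the standard errors to the natural
shape/scale parametrisation. Non-convergence and singular information are
errors, not silent results; data censored entirely on one side are rejected
as non-identifiable. A direct `optim()` maximisation of the same likelihood
serves as an independent cross-check in the test suite.

`weibull_threshold_mcmc()` targets the same censored likelihood times
independent vague $\text{Gamma}(10^{-3}, 10^{-3})$ priors on shape and
scale. Sampling is adaptive random-walk Metropolis on
$(\log a, \log b)$ with the Jacobian correction — any correct sampler for
this posterior is acceptable, so the package fixes the target density and
the convergence criterion rather than a particular engine. Two dispersed
chains (20 000 iterations, 5 000 burn-in with step-size adaptation) are the
default; convergence is monitored by the split-chain potential scale
reduction factor with threshold 1.05, and a violation attaches a warning to
the result. At $n = 5000$ subjects on a fine dose grid the posterior mean
matches the MLE within 2% (a Bernstein–von Mises check in the tests).
Repeated-study coverage checks in the acceptance tests use shortened chains
(2 × 4000, burn-in 1000): the two-parameter posterior at $n = 158$ is
well-conditioned and 6000 pooled draws give stable 95% intervals.

## Uncertainty propagation and decomposition

For the triple log-normal case the sampling error of the six parameter
estimates propagates through the closed form analytically.
`delta_method_variance()` implements the first-order expansion

$$\operatorname{Var}(\hat p) \;\approx\; \sum_{i \in \{X,Y,Z\}} K_1
\frac{\sigma_i^2}{n_i} \;+\; \sum_{i \in \{X,Y,Z\}} K_2
\frac{2\sigma_i^4}{n_i - 1},$$

with $d = (\mu_z-\mu_x-\mu_y)/s$, $s^2 = \sigma_x^2+\sigma_y^2+\sigma_z^2$,
$K_1 = [\varphi(d)/s]^2$ and $K_2 = [\varphi(d)(\mu_z-\mu_x-\mu_y)/(2s^3)]^2$
($\varphi$ the standard normal density). The first sum carries the location
uncertainty, the second the variance uncertainty; the joint variance is
their total, so this decomposition is additive by construction. The method
is deliberately restricted to the triple log-normal configuration — the
expansion is derived for that model and silently reusing it elsewhere would
be wrong.

For any case, `oat_decomposition()` measures the same thing by simulation,
one input at a time: three runs activate a single input's parameter
uncertainty while the others are held at their point estimates (posterior
means for Bayesian inputs — the central value is not dictated by the
scheme, and the posterior mean mirrors the frequentist plug-in), and a
fourth activates all three jointly. Each run contributes the variance of
its $K$ per-replication risks ($n-1$ denominator). Under input independence
the three individual variances approximately sum to the joint one; the
worked example satisfies $|{\rm sum} - {\rm joint}|/{\rm joint} \le 0.2$
and preserves the rank order *threshold > contamination > consumption* in
every method. `decomposition_report()` renders the five-row grid with
variances in units of $10^{-4}$ on the proportion scale (equivalently
$10^{-2}$ squared percent), which lines up with a risk SD of about 2%.

## The synthetic-data generators

The survey and challenge datasets behind the worked example are not public, so the
package generates statistically equivalent ones with known ground truth:

* consumption: log-normal with location $-3.719$ and scale $0.747$ (log-kg;
  median about 24 g), $n = 350$ eating occasions. An optional two-component
  mixture (`tail_weight`, `tail_scale`) produces the heavier upper tail
  real survey data show; the default is the pure log-normal, because that
  is the model every downstream stage assumes.
* concentration: exponential with rate $0.013$/ppm (mean 77 ppm),
  $n = 24$ measurements; a log-normal alternative is available.
* thresholds: Weibull with shape $0.38$ and scale $229.6$ mg (or log-normal
  with location $4.09$, scale $2.98$), $n = 158$ subjects, observed through
  a challenge dose grid. The default grid is a geometric series of 10 doses
  from 0.1 mg to 1000 mg protein — the source studies' actual dose series
  are not published, so this grid is a realistic stand-in spanning the
  threshold scale, not a reconstruction. With it, roughly 20% of subjects
  are right-censored and a few percent left-censored at these parameters.

Each subject consumes a random stream derived from the seed by counter
offset, so enlarging a study extends it without reshuffling existing
subjects, and identical seeds give byte-identical files. Latent thresholds
can be retained in a `latent_mg` debug column that all fitting functions
ignore.

What passing tests on these data do **not** show: that real consumption is
log-normal (its tail is heavier), that real contamination is homogeneous
within a lot, or that consumption and individual thresholds are independent
— an assumption the model makes and individual-level data could contradict.

## Numerical choices and degenerate inputs

* Strict inequality $Z < XY$ defines a reaction; ties count as no reaction.
* Positivity of normally drawn rates/shapes/scales is enforced by
  rejection-resampling, which preserves the mean for small rejection rates;
  when about half or more of the normal mass is non-positive the function
  refuses to proceed rather than bias the draws.
* Constant samples (zero log-variance), empty samples, all-zero bootstrap
  weights, non-identifiable censoring patterns and zero summed log-variance
  in the closed form are all explicit errors.
* `run_case()` seeds the R RNG once from the master seed and consumes it
  sequentially (outer draws first, then each replication's inner draws);
  together with one-integer seeds everywhere this makes every result,
  including whole pipeline runs, reproducible bit for bit. The per-subject
  counter streams are reserved for the challenge generator, where stability
  under study enlargement is the property that matters.
* Weibull shape and scale draws are independent normals by default,
  matching the published case specifications; the fitted covariance is
  retained in `weibull_params` for users who want a joint draw.

## The worked example

```{r example, eval = FALSE}
p <- peanut_cereal_params()

# plug-in closed form
100 * closed_form_risk(p$plugin$x, p$plugin$y, p$plugin$z)

# second-order Monte Carlo, calculated and simulated
run_case(peanut_cereal_case("B_calculated", seed = 1))
run_case(peanut_cereal_case("B_simulated", seed = 2))
run_case(peanut_cereal_case("C", seed = 3))

# uncertainty decomposition
delta_method_variance(p$sampling$x, p$sampling$y, p$sampling$z)
oat_decomposition(peanut_cereal_case("B_simulated", seed = 4))
```

On the peanut-in-cereal-bars inputs the plug-in risk is about 9.8% per
eating occasion; with parameter uncertainty the triple log-normal risk is
about 9.9–10.1% (SD ≈ 2.1–2.2 percentage points), and the
exponential/Weibull configuration gives about 13.7–13.9% — the Weibull
threshold fit, not the simulation method, drives the difference. These
numbers are recomputed, not quoted, by `scripts/acceptance.R` and the test
suite.

## Problem sizes used in the tests

The default $K = 1000 \times n = 10\,000$ runs appear directly in the
acceptance tests (a few seconds each, vectorised). Property-style tests use
smaller designs chosen for statistical resolution: 20–40 seeds for
parameter-recovery loops, 100 replicate studies for the interval-coverage
checks, $10^6$ draws for estimator-equivalence checks.

## Known limitations

* The delta method covers the triple log-normal model only.
* Multipliers such as the proportion of contaminated products or allergy
  prevalence are out of scope; the model conditions on an allergic consumer
  eating a contaminated product.
* Thresholds are treated as fixed per individual; intra-individual
  variation over time is not modelled.
* No goodness-of-fit selection between candidate input families is
  performed; the families are inputs to the analysis.
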