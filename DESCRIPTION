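Package: allergenrisk
Title: Probabilistic Food Allergen Risk Assessment with Uncertainty
    Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates the population risk of an allergic reaction after
    accidental exposure to an undeclared food allergen, p = P(Z < X*Y),
    from the amount of contaminated product consumed (X), the allergen
    concentration in the product (Y) and the distribution of individual
    eliciting doses (Z). Provides a closed-form solution for the triple
    log-normal model, second-order Monte Carlo simulation separating
    variability from parameter uncertainty (frequentist sampling
    distributions or Bayesian posteriors, including interval-censored
    survival fits of food-challenge data), delta-method error
    propagation, and a one-at-a-time decomposition attributing the risk
    uncertainty to the three inputs. Includes generators for synthetic
    consumption, contamination and interval-censored food-challenge
    datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
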