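# container shared by the delta-method and simulation decompositions
uncertainty_decomposition <- function(var_consumption, var_contamination,
                                      var_threshold, var_joint, method,
                                      case_id = NULL) {
  comps <- c(var_consumption, var_contamination, var_threshold)
  stopifnot(all(comps >= 0), var_joint >= 0)
  structure(
    list(var_consumption = var_consumption,
         var_contamination = var_contamination,
         var_threshold = var_threshold,
         sum_individual = sum(comps),
         var_joint = var_joint,
         method = method, case_id = case_id),
    class = "uncertainty_decomposition"
  )
}

#' @export
print.uncertainty_decomposition <- function(x, ...) {
  cat(sprintf("Uncertainty decomposition (%s%s), variances x 1e-4:\n",
              x$method,
              if (is.null(x$case_id)) "" else paste0(", case ", x$case_id)))
  v <- c(Consumption = x$var_consumption,
         Contamination = x$var_contamination,
         Threshold = x$var_threshold,
         Sum = x$sum_individual,
         All = x$var_joint) * 1e4
  for (nm in names(v)) cat(sprintf("  %-14s %8.3f\n", nm, v[[nm]]))
  invisible(x)
}

#' Delta-method variance of the triple log-normal risk
#'
#' First-order propagation of the sampling error of the six log-normal
#' parameter estimates through the closed-form risk. Writing
#' `d = (mu_z - mu_x - mu_y)/s` with `s^2` the summed log-variances, the
#' risk variance is approximately
#' `sum_i K1 * sigma_i^2 / n_i + sum_i K2 * 2 sigma_i^4 / (n_i - 1)`
#' over the three inputs, with `K1 = (phi(d)/s)^2` and
#' `K2 = (phi(d) * (mu_z - mu_x - mu_y) / (2 s^3))^2` (`phi` the standard
#' normal density). The first sum propagates the location uncertainty, the
#' second the chi-square variance uncertainty; the joint variance is their
#' total, so this decomposition is additive by construction. It is defined
#' for the triple log-normal configuration only.
#'
#' @param x,y,z [lognormal_params()] objects with known sample sizes.
#' @return An `uncertainty_decomposition` (method `"delta"`) whose
#'   components are variances of the risk on the proportion scale.
#' @export
delta_method_variance <- function(x, y, z) {
  stopifnot(inherits(x, "lognormal_params"),
            inherits(y, "lognormal_params"),
            inherits(z, "lognormal_params"))
  ns <- c(x$n, y$n, z$n)
  if (any(is.na(ns)) || any(ns < 2)) {
    stop("all three inputs need a sample size of at least 2")
  }
  sig <- c(x$sdlog, y$sdlog, z$sdlog)
  s2 <- sum(sig^2)
  if (s2 == 0) stop("degenerate model: all log-scales are zero")
  s <- sqrt(s2)
  num <- z$meanlog - x$meanlog - y$meanlog
  d <- num / s
  K1 <- (stats::dnorm(d) / s)^2
  K2 <- (stats::dnorm(d) * num / (2 * s^3))^2
  comp <- K1 * sig^2 / ns + K2 * 2 * sig^4 / (ns - 1)
  dec <- uncertainty_decomposition(comp[1], comp[2], comp[3], sum(comp),
                                   method = "delta")
  dec$K1 <- K1
  dec$K2 <- K2
  dec
}

#' One-at-a-time simulation decomposition of the risk uncertainty
#'
#' Attributes the uncertainty of the risk estimate to the three inputs by
#' running four second-order simulations: in each of the first three, the
#' parameter uncertainty of a single input is active while the other two are
#' held at their point estimates (posterior means for Bayesian inputs); the
#' fourth activates all three jointly. Each run contributes the variance of
#' its `K` per-replication risks (n - 1 denominator). Under input
#' independence the three individual variances should approximately add up
#' to the joint one. If an input (or all of them) carries no parameter
#' uncertainty, its component reflects pure simulation noise - the
#' binomial floor `p(1-p)/n` for the indicator method - which makes the
#' all-fixed configuration a useful noise-floor diagnostic.
#'
#' @param spec A [case_spec()] in which every input carries an uncertainty
#'   method.
#' @param seed Optional master seed (overrides `spec$seed`).
#' @return An `uncertainty_decomposition` (method `"simulation"`), with the
#'   four `risk_distribution` objects attached as attribute `"runs"`.
#' @export
oat_decomposition <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "case_spec"))
  if (!is.null(seed)) spec$seed <- seed
  if (is.null(spec$seed)) stop("a seed is required for a reproducible ",
                               "decomposition")
  inputs <- spec[c("consumption", "concentration", "threshold")]
  variant <- function(active, seed_offset) {
    sp <- spec
    for (nm in names(inputs)) {
      if (!nm %in% active) sp[[nm]] <- fix_input(sp[[nm]])
    }
    sp$seed <- spec$seed + seed_offset
    run_case(sp)
  }
  runs <- list(
    consumption = variant("consumption", 1L),
    contamination = variant("concentration", 2L),
    threshold = variant("threshold", 3L),
    joint = variant(names(inputs), 4L)
  )
  vars <- vapply(runs, function(r) stats::var(r$risks), numeric(1))
  dec <- uncertainty_decomposition(vars[["consumption"]],
                                   vars[["contamination"]],
                                   vars[["threshold"]], vars[["joint"]],
                                   method = "simulation",
                                   case_id = spec$case_id)
  attr(dec, "runs") <- runs
  dec
}

#' Tabulate uncertainty decompositions
#'
#' Renders one or more decompositions as a five-row grid (consumption,
#' contamination, threshold, sum of the three, jointly propagated), one
#' column per method, with variances reported in units of `1e-4` on the
#' proportion scale (equivalently `1e-2` squared-percent).
#'
#' @param ... Named `uncertainty_decomposition` objects (names become column
#'   labels; unnamed arguments use their method).
#' @param scale Multiplier applied to the variances (default `1e4`).
#' @return A data frame with a `component` column plus one column per
#'   decomposition.
#' @export
decomposition_report <- function(..., scale = 1e4) {
  decs <- list(...)
  decs <- decs[!vapply(decs, is.null, logical(1))]
  if (length(decs) == 0L) stop("no decompositions supplied")
  stopifnot(all(vapply(decs, inherits, logical(1),
                       "uncertainty_decomposition")))
  labels <- names(decs)
  if (is.null(labels)) labels <- rep("", length(decs))
  labels <- ifelse(labels == "",
                   vapply(decs, function(d) d$method, character(1)), labels)
  out <- data.frame(
    component = c("Consumption (X)", "Contamination (Y)", "Threshold (Z)",
                  "Sum of individual", "All parameters"),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(decs)) {
    d <- decs[[i]]
    out[[labels[i]]] <- scale * c(d$var_consumption, d$var_contamination,
                                  d$var_threshold, d$sum_individual,
                                  d$var_joint)
  }
  out
}
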