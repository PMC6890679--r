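# Dataset readers/writers and the end-to-end pipeline. All files are plain
# CSV with a header row; writers keep full double precision so a write/read
# round trip is exact.

#' Write / read a consumption dataset
#'
#' `consumption.csv` holds one eating occasion per row: `amount_kg` plus an
#' optional survey `weight` column.
#'
#' @param x Positive amounts (kg).
#' @param path File path.
#' @param weights Optional non-negative survey weights.
#' @return `write_consumption()` returns `path` invisibly;
#'   `read_consumption()` returns a data frame with columns `amount_kg` and
#'   `weight`, plus attribute `uniform_weights` (`TRUE` when the file had no
#'   weight column).
#' @export
write_consumption <- function(x, path, weights = NULL) {
  df <- data.frame(amount_kg = x)
  if (!is.null(weights)) df$weight <- weights
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_consumption
#' @export
read_consumption <- function(path) {
  if (!file.exists(path)) stop("consumption file not found: ", path)
  df <- utils::read.csv(path)
  if (!"amount_kg" %in% names(df)) {
    stop("consumption file must have an 'amount_kg' column: ", path)
  }
  bad <- !is.finite(df$amount_kg) | df$amount_kg <= 0
  if (any(bad)) {
    stop("non-positive or missing consumption amount in row(s) ",
         paste(which(bad), collapse = ", "))
  }
  uniform <- !"weight" %in% names(df)
  if (uniform) {
    df$weight <- 1
  } else if (any(!is.finite(df$weight) | df$weight < 0)) {
    stop("negative or missing survey weight in row(s) ",
         paste(which(!is.finite(df$weight) | df$weight < 0), collapse = ", "))
  }
  structure(df[c("amount_kg", "weight")], uniform_weights = uniform)
}

#' Write / read a concentration dataset
#'
#' `concentration.csv` holds one contamination measurement (ppm) per row.
#'
#' @param y Positive concentrations (ppm).
#' @param path File path.
#' @return `write_concentration()` returns `path` invisibly;
#'   `read_concentration()` returns the numeric vector of concentrations.
#' @export
write_concentration <- function(y, path) {
  utils::write.csv(data.frame(ppm = y), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_concentration
#' @export
read_concentration <- function(path) {
  if (!file.exists(path)) stop("concentration file not found: ", path)
  df <- utils::read.csv(path)
  if (!"ppm" %in% names(df)) {
    stop("concentration file must have a 'ppm' column: ", path)
  }
  bad <- !is.finite(df$ppm) | df$ppm <= 0
  if (any(bad)) {
    stop("non-positive or missing concentration in row(s) ",
         paste(which(bad), collapse = ", "))
  }
  df$ppm
}

#' Write / read an interval-censored challenge dataset
#'
#' `challenges.csv` holds one DBPCFC subject per row: `lower_mg`,
#' `upper_mg`, `censor` (one of `interval`, `left`, `right`) and an optional
#' `latent_mg` debug column that fitting functions ignore.
#'
#' @param records Challenge data frame (see [generate_challenge_data()]).
#' @param path File path.
#' @return `write_challenges()` returns `path` invisibly;
#'   `read_challenges()` returns the validated data frame.
#' @export
write_challenges <- function(records, path) {
  validate_challenges(records)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_challenges
#' @export
read_challenges <- function(path) {
  if (!file.exists(path)) stop("challenge file not found: ", path)
  validate_challenges(utils::read.csv(path))
}

#' Serialise fitted parameters in report form
#'
#' Summarises a data frame of parameter draws as the usual reporting grid:
#' mean, SD and 2.5/50/97.5 empirical percentiles per parameter.
#'
#' @param draws Data frame, one column per parameter, one row per draw.
#' @param distribution Distribution label repeated on every row.
#' @return A data frame with columns `distribution`, `parameter`, `mean`,
#'   `sd`, `p2.5`, `median`, `p97.5`.
#' @export
summarize_param_draws <- function(draws, distribution = "") {
  stopifnot(is.data.frame(draws), nrow(draws) >= 2L)
  do.call(rbind, lapply(names(draws), function(nm) {
    v <- draws[[nm]]
    qs <- stats::quantile(v, c(0.025, 0.5, 0.975), type = 8, names = FALSE)
    data.frame(distribution = distribution, parameter = nm,
               mean = mean(v), sd = stats::sd(v),
               p2.5 = qs[1], median = qs[2], p97.5 = qs[3],
               stringsAsFactors = FALSE)
  }))
}

#' Run the full risk-assessment pipeline
#'
#' Generates (or reads) the three datasets, fits the input distributions,
#' runs the requested cases and writes the report files to `out_dir`:
#' `fitted_params.csv` (parameter summaries over the uncertainty draws, with
#' full-precision `_raw` columns beside the rounded report columns),
#' `risk_summary.csv` (per-case risk mean/SD/percentiles as percentages),
#' `uncertainty_report.csv` (delta-method and one-at-a-time variance grid
#' for the triple log-normal case) and `manifest.txt` (seed and
#' configuration echo, sufficient to reproduce every table bit-identically).
#'
#' @param config A list with elements: `seed` (required), `out_dir`
#'   (required), `K`, `n` (default 1000 and 10000), `cases` (subset of
#'   `c("A", "B_calculated", "B_simulated", "C")`), and either
#'   `consumption_csv`/`concentration_csv`/`challenges_csv` paths or
#'   `synth = TRUE` with optional ground-truth overrides `synth_x`
#'   (log-pair), `synth_y_rate`, `synth_z` (Weibull pair).
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config$seed is mandatory")
  if (is.null(config$out_dir)) stop("config$out_dir is mandatory")
  seed <- as.integer(config$seed)
  K <- if (is.null(config$K)) 1000L else as.integer(config$K)
  n <- if (is.null(config$n)) 10000L else as.integer(config$n)
  cases <- if (is.null(config$cases)) {
    c("A", "B_calculated", "B_simulated", "C")
  } else config$cases
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- data stage ---------------------------------------------------------
  if (isTRUE(config$synth)) {
    gx <- if (is.null(config$synth_x)) c(-3.719, 0.747) else config$synth_x
    gy <- if (is.null(config$synth_y_rate)) 0.013 else config$synth_y_rate
    gz <- if (is.null(config$synth_z)) c(0.38, 229.6) else config$synth_z
    cons <- generate_consumption(gx, 350, seed = seed + 101L)
    conc <- generate_concentration("exponential", gy, 24, seed = seed + 102L)
    chal <- generate_challenge_data("weibull", gz, 158, seed = seed + 103L)
  } else {
    for (nm in c("consumption_csv", "concentration_csv", "challenges_csv")) {
      if (is.null(config[[nm]])) stop("config$", nm, " is required when ",
                                      "synth is not set")
    }
    cons <- read_consumption(config$consumption_csv)$amount_kg
    conc <- read_concentration(config$concentration_csv)
    chal <- read_challenges(config$challenges_csv)
  }

  # --- fitting stage ------------------------------------------------------
  fit_x <- fit_lognormal(cons)
  fit_y_ln <- fit_lognormal(conc)
  fit_y_exp <- fit_exponential(conc)
  fit_z_ln <- fit_interval_censored(chal, "lognormal")
  fit_z_wb <- fit_interval_censored(chal, "weibull")

  set.seed(seed + 201L)
  fitted <- rbind(
    summarize_param_draws(draw_lognormal_params(fit_x, K),
                          "lognormal consumption"),
    summarize_param_draws(draw_lognormal_params(fit_y_ln, K),
                          "lognormal concentration"),
    summarize_param_draws(draw_lognormal_params(fit_z_ln, K),
                          "lognormal threshold"),
    summarize_param_draws(
      data.frame(rate = draw_normal_params(fit_y_exp$rate,
                                           fit_y_exp$se_rate, K,
                                           positive = TRUE)),
      "exponential concentration"),
    summarize_param_draws(
      data.frame(
        shape = draw_normal_params(fit_z_wb$shape, fit_z_wb$se_shape, K,
                                   positive = TRUE),
        scale = draw_normal_params(fit_z_wb$scale, fit_z_wb$se_scale, K,
                                   positive = TRUE)
      ),
      "weibull threshold")
  )
  num <- vapply(fitted, is.numeric, logical(1))
  rounded <- fitted
  rounded[num] <- lapply(fitted[num], round, 3)
  names(fitted)[num] <- paste0(names(fitted)[num], "_raw")
  utils::write.csv(cbind(rounded, fitted[num]),
                   file.path(out_dir, "fitted_params.csv"),
                   row.names = FALSE)

  # --- risk stage ---------------------------------------------------------
  build <- function(case) {
    switch(case,
      A = case_spec("A",
                    input_lognormal(lognormal_params(fit_x$meanlog,
                                                     fit_x$sdlog)),
                    input_lognormal(lognormal_params(fit_y_ln$meanlog,
                                                     fit_y_ln$sdlog)),
                    input_lognormal(lognormal_params(fit_z_ln$meanlog,
                                                     fit_z_ln$sdlog)),
                    risk_method = "indicator", K = K, n = n,
                    seed = seed + 301L),
      B_calculated = case_spec("B_calculated",
                               input_lognormal(fit_x, "sampling"),
                               input_lognormal(fit_y_ln, "sampling"),
                               input_lognormal(fit_z_ln, "sampling"),
                               risk_method = "closed_form", K = K, n = n,
                               seed = seed + 302L),
      B_simulated = case_spec("B_simulated",
                              input_lognormal(fit_x, "sampling"),
                              input_lognormal(fit_y_ln, "sampling"),
                              input_lognormal(fit_z_ln, "sampling"),
                              risk_method = "indicator", K = K, n = n,
                              seed = seed + 303L),
      C = case_spec("C",
                    input_lognormal(fit_x, "sampling"),
                    input_exponential(fit_y_exp, "normal"),
                    input_weibull(fit_z_wb, "normal"),
                    risk_method = "dose_response", K = K, n = n,
                    seed = seed + 304L),
      stop("unknown case: ", case)
    )
  }
  dists <- lapply(cases, function(cs) run_case(build(cs)))
  risk_tab <- do.call(rbind, lapply(dists, as.data.frame))
  pct <- c("mean", "sd", "p2.5", "median", "p97.5")
  raw <- risk_tab[pct]
  names(raw) <- paste0(pct, "_raw")
  risk_tab[pct] <- lapply(risk_tab[pct], function(v) round(100 * v, 2))
  utils::write.csv(cbind(risk_tab, raw),
                   file.path(out_dir, "risk_summary.csv"), row.names = FALSE)

  # --- uncertainty stage (triple log-normal configuration) ---------------
  delta <- delta_method_variance(fit_x, fit_y_ln, fit_z_ln)
  sim <- oat_decomposition(build("B_simulated"), seed = seed + 401L)
  utils::write.csv(decomposition_report(calculation = delta,
                                        simulation = sim),
                   file.path(out_dir, "uncertainty_report.csv"),
                   row.names = FALSE)

  # --- manifest -----------------------------------------------------------
  writeLines(c(
    "allergenrisk run manifest",
    paste0("package_version: ",
           as.character(utils::packageVersion("allergenrisk"))),
    paste0("r_version: ", R.version.string),
    paste0("seed: ", seed),
    paste0("K: ", K),
    paste0("n: ", n),
    paste0("cases: ", paste(cases, collapse = ",")),
    paste0("synth: ", isTRUE(config$synth)),
    paste0("n_consumption: ", length(cons)),
    paste0("n_concentration: ", length(conc)),
    paste0("n_challenges: ", nrow(chal))
  ), file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
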