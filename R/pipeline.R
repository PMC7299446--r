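#' Build a region configuration
#'
#' A region configuration bundles everything one analysis needs: the region
#' name and population, one benchmark model per row (label, endpoint count,
#' multiplier mean and SE, both on the proportion scale), and the simulation
#' settings. An optional `repeat_visit_fraction` is applied via
#' [adjust_repeat_events()] to any model whose `adjust_repeat_visits` column
#' is `TRUE`, for endpoints supplied as raw event counts rather than
#' person counts.
#'
#' @param region_name Region label.
#' @param population Regional population (positive integer).
#' @param models A model table ([multiplier_models()]); may carry optional
#'   columns `adjust_repeat_visits` (logical) and `data_year`.
#' @param n_iter Monte Carlo iterations (default 10000).
#' @param seed Master integer seed (default 1).
#' @param averaging_scheme Averaging scheme, see [average_models()].
#' @param repeat_visit_fraction Optional proportion of repeat events in
#'   `[0, 1)`.
#' @return A list of class `region_config`.
#' @export
region_config <- function(region_name, population, models, n_iter = 10000,
                          seed = 1,
                          averaging_scheme = c("comonotonic", "independent",
                                               "model_selection"),
                          repeat_visit_fraction = NULL) {
  averaging_scheme <- match.arg(averaging_scheme)
  if (!is.numeric(population) || length(population) != 1 || population <= 0) {
    abort("population: must be a single positive number")
  }
  if (!is.numeric(n_iter) || n_iter < 1) abort("n_iter: must be >= 1")
  if (!is.null(repeat_visit_fraction) &&
      (repeat_visit_fraction < 0 || repeat_visit_fraction >= 1)) {
    abort("repeat_visit_fraction: must lie in [0, 1)")
  }
  models <- validate_models(models)
  structure(
    list(region_name = as.character(region_name), population = population,
         models = models, n_iter = as.integer(n_iter),
         seed = as.integer(seed), averaging_scheme = averaging_scheme,
         repeat_visit_fraction = repeat_visit_fraction),
    class = "region_config"
  )
}

#' Read a region configuration from YAML
#'
#' The file mirrors [region_config()]: scalar fields `region_name`,
#' `population`, `n_iter`, `seed`, `averaging_scheme`,
#' `repeat_visit_fraction` (optional), and a `models` list whose entries have
#' `label`, `endpoint_count`, `multiplier_mean`, `multiplier_se` and the
#' optional per-model fields. Validation errors name the offending field.
#'
#' @param path Path to a YAML file.
#' @return A `region_config`.
#' @export
read_region_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (field in c("region_name", "population", "models")) {
    if (is.null(raw[[field]])) {
      abort(sprintf("config file %s: missing field '%s'", path, field))
    }
  }
  models <- bind_rows(lapply(raw$models, as_tibble))
  args <- list(region_name = raw$region_name, population = raw$population,
               models = models)
  for (field in c("n_iter", "seed", "averaging_scheme",
                  "repeat_visit_fraction")) {
    if (!is.null(raw[[field]])) args[[field]] <- raw[[field]]
  }
  do.call(region_config, args)
}

#' Packaged Cincinnati CBSA configuration and model table
#'
#' The configuration for the 14-county Cincinnati Core Based Statistical
#' Area, 2017: population 2 165 139; benchmark endpoints 996 fatal overdoses,
#' 2752 treatment admissions, and 7342 non-fatal ED overdose visits (already
#' deduplicated for repeat visits); pooled multipliers 7.182% (SE 0.533%),
#' 21.376% (SE 2.142%), and 40.890% (SE 5.111%) respectively.
#'
#' @return `cincinnati_config()`: a `region_config`; `cincinnati_models()`:
#'   its model table; `cincinnati_population()`: the CBSA population.
#' @examples
#' cincinnati_models()
#' @export
cincinnati_config <- function() {
  read_region_config(system.file("extdata", "cincinnati.yaml",
                                 package = "prevmult", mustWork = TRUE))
}

#' @rdname cincinnati_config
#' @export
cincinnati_models <- function() cincinnati_config()$models

#' @rdname cincinnati_config
#' @export
cincinnati_population <- function() cincinnati_config()$population

#' Run the full multiplier pipeline on a region configuration
#'
#' Executes, per model: repeat-event adjustment (if flagged), beta
#' method-of-moments fit, analytic reciprocal-multiplier moments, and the
#' Monte Carlo simulation; then model averaging, summary rows, and the
#' mean ± 1 SE prevalence band. Deterministic given the config's seed.
#'
#' @param config A `region_config`, or a path to a YAML config file.
#' @param keep_draws Keep the full draw tables on the returned object
#'   (default `FALSE`; summaries are always kept).
#' @param verbose Log fitted beta parameters and analytic oracle moments via
#'   `message()`.
#' @return An object of class `mm_report`: list with `config`, `models` (the
#'   fitted model table incl. `alpha`, `beta`, `inv_mean`, `inv_sd`, and the
#'   analytic prevalence moments `analytic_mean`, `analytic_sd`), `summary`
#'   (per-model rows plus the averaged row), `band`, and optionally `draws`,
#'   `averaged_draws`. Supports [tidy()], [glance()], `print()`, and
#'   [autoplot()].
#' @examples
#' report <- run_pipeline(cincinnati_config())
#' glance(report)
#' @export
run_pipeline <- function(config, keep_draws = FALSE, verbose = FALSE) {
  if (is.character(config)) config <- read_region_config(config)
  if (!inherits(config, "region_config")) {
    abort("config must be a region_config or a path to a YAML config file")
  }
  models <- config$models
  if ("adjust_repeat_visits" %in% names(models) &&
      any(models$adjust_repeat_visits %in% TRUE)) {
    if (is.null(config$repeat_visit_fraction)) {
      abort(paste("repeat_visit_fraction: required when a model has",
                  "adjust_repeat_visits = TRUE"))
    }
    flagged <- models$adjust_repeat_visits %in% TRUE
    models$endpoint_count[flagged] <- adjust_repeat_events(
      models$endpoint_count[flagged], config$repeat_visit_fraction)
  }
  models <- inverse_beta_moments(fit_beta_moments(models))
  models <- mutate(models,
                   analytic_mean = .data$endpoint_count * .data$inv_mean,
                   analytic_sd = .data$endpoint_count * .data$inv_sd)
  if (verbose) {
    message(sprintf("region %s: population %s, %d models, %d iterations, seed %d",
                    config$region_name, format(config$population, big.mark = " "),
                    nrow(models), config$n_iter, config$seed))
    for (i in seq_len(nrow(models))) {
      message(sprintf(
        "  %s: A = %s, beta fit alpha = %.3f, beta = %.3f; analytic C: mean = %.1f, sd = %.1f",
        models$label[i], format(models$endpoint_count[i], big.mark = " "),
        models$alpha[i], models$beta[i],
        models$analytic_mean[i], models$analytic_sd[i]))
    }
  }
  draws <- simulate_models(models, n_iter = config$n_iter, seed = config$seed)
  averaged <- average_models(draws, scheme = config$averaging_scheme,
                             seed = config$seed)
  summary <- bind_rows(summarize_draws(draws), summarize_draws(averaged))
  band <- prevalence_band(summary[summary$label == "Model Average", ],
                          config$population)
  out <- list(config = config, models = models, summary = summary,
              band = band)
  if (keep_draws) {
    out$draws <- draws
    out$averaged_draws <- averaged
  }
  structure(out, class = "mm_report")
}

#' Write a pipeline report to CSV and JSON
#'
#' The CSV mirrors the standard report layout (`label`, `min`, `p10`, `p50`,
#' `p90`, `max`, `mean`, `se`) with counts rounded to integers; the JSON
#' carries the full-precision summary, the band, and the configuration.
#' Re-running the same configuration produces byte-identical files.
#'
#' @param report An `mm_report`.
#' @param dir Output directory (created if absent).
#' @param basename File stem (default `"report"`).
#' @return Invisibly, the paths of the two files written.
#' @export
write_report <- function(report, dir, basename = "report") {
  if (!inherits(report, "mm_report")) abort("report must be an mm_report")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv_path <- file.path(dir, paste0(basename, ".csv"))
  json_path <- file.path(dir, paste0(basename, ".json"))
  rounded <- mutate(report$summary,
                    across(c("min", "p10", "p50", "p90", "max", "mean", "se"),
                           ~ round(.x)))
  readr::write_csv(rounded, csv_path)
  payload <- list(
    region_name = report$config$region_name,
    population = report$config$population,
    n_iter = report$config$n_iter,
    seed = report$config$seed,
    averaging_scheme = report$config$averaging_scheme,
    models = report$models,
    summary = report$summary,
    band = report$band
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}

#' @export
print.mm_report <- function(x, ...) {
  cat(sprintf("Multiplier-model prevalence report: %s\n",
              x$config$region_name))
  cat(sprintf("  population %s | %d models | %d iterations | seed %d | %s averaging\n\n",
              format(x$config$population, big.mark = " "),
              nrow(x$models), x$config$n_iter, x$config$seed,
              x$config$averaging_scheme))
  rounded <- mutate(x$summary,
                    across(c("min", "p10", "p50", "p90", "max", "mean", "se"),
                           ~ round(.x)))
  print(as.data.frame(rounded), row.names = FALSE)
  cat(sprintf(
    "\nEstimated hidden population: %d (SE %d); mean +/- SE band %d-%d (%.2f%%-%.2f%% of population)\n",
    round(x$summary$mean[x$summary$label == "Model Average"]),
    round(x$summary$se[x$summary$label == "Model Average"]),
    round(x$band$count_low), round(x$band$count_high),
    x$band$pct_low, x$band$pct_high))
  invisible(x)
}

#' Tidy a pipeline report into summary rows
#'
#' @param x An `mm_report`.
#' @param ... Unused.
#' @return The full-precision summary tibble: one row per model plus the
#'   averaged row, columns `label`, `min`, `p10`, `p50`, `p90`, `max`,
#'   `mean`, `se`.
#' @export
tidy.mm_report <- function(x, ...) x$summary

#' One-row overview of a pipeline report
#'
#' @param x An `mm_report`.
#' @param ... Unused.
#' @return A one-row tibble: region, population, settings, averaged mean and
#'   SE, band endpoints and percentages.
#' @export
glance.mm_report <- function(x, ...) {
  avg <- x$summary[x$summary$label == "Model Average", ]
  tibble(
    region_name = x$config$region_name,
    population = x$config$population,
    n_models = nrow(x$models),
    n_iter = x$config$n_iter,
    seed = x$config$seed,
    averaging_scheme = x$config$averaging_scheme,
    mean = avg$mean,
    se = avg$se,
    count_low = x$band$count_low,
    count_high = x$band$count_high,
    pct_low = x$band$pct_low,
    pct_high = x$band$pct_high
  )
}
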