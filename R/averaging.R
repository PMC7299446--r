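#' Average per-model prevalence draws into one distribution
#'
#' Combines the Monte Carlo draw sets of several benchmark models into a
#' single model-averaged prevalence distribution, with equal model weights.
#' Three coupling schemes express different treatments of the structural
#' uncertainty:
#'
#' * `"comonotonic"` (default, common random numbers): iteration `i` of every
#'   model sits at the same uniform quantile, and the averaged draw is the
#'   arithmetic mean of the per-model draws at that quantile. Every quantile
#'   of the average then equals the average of the models' quantiles, and the
#'   SD of the average equals the mean of the per-model SDs.
#' * `"independent"`: models keep their independent streams; draws are
#'   averaged per iteration. The averaged SD is smaller (variance of a mean
#'   of weakly coupled variables).
#' * `"model_selection"`: each iteration picks one model uniformly at random
#'   and takes its draw, mixing the model distributions instead of averaging
#'   draws.
#'
#' @param draws An `mm_draws` table from [simulate_models()] containing every
#'   model to combine; all models must share `n_iter`.
#' @param scheme Coupling scheme, one of `"comonotonic"`, `"independent"`,
#'   `"model_selection"`.
#' @param seed Integer seed for the scheme's own randomness (ordering of the
#'   comonotonic quantiles, model selection); defaults to the seed stored on
#'   `draws`.
#' @param label Label given to the averaged draw set.
#' @return An `mm_draws` table with the single averaged model. The `u` column
#'   holds the common uniform quantile under the comonotonic scheme and `NA`
#'   otherwise.
#' @examples
#' m <- cincinnati_models()
#' d <- simulate_models(m, n_iter = 2000, seed = 1)
#' avg <- average_models(d)
#' mean(avg$value)
#' @export
average_models <- function(draws,
                           scheme = c("comonotonic", "independent",
                                      "model_selection"),
                           seed = attr(draws, "seed"),
                           label = "Model Average") {
  scheme <- match.arg(scheme)
  if (is.null(seed)) abort("seed must be supplied or stored on draws")
  labels <- unique(draws$label)
  if (length(labels) == 0 || nrow(draws) == 0) {
    abort("draws must contain at least one model")
  }
  by_model <- lapply(labels, function(l) draws$value[draws$label == l])
  lens <- lengths(by_model)
  if (length(unique(lens)) != 1) {
    abort("all models must share the same number of iterations")
  }
  n <- lens[[1]]
  mat <- do.call(cbind, by_model) # n_iter x k, original iteration order
  u <- rep(NA_real_, n)
  if (scheme == "comonotonic") {
    # monotone rearrangement: sort each model descending (C = A/B decreases
    # in u), average order statistics, then place each averaged order
    # statistic at the rank of a common uniform stream
    avg_desc <- rowMeans(apply(mat, 2, sort, decreasing = TRUE))
    set.seed(stream_seed(seed, paste0(label, "|comonotonic")))
    u <- runif(n)
    value <- avg_desc[rank(u, ties.method = "first")]
  } else if (scheme == "independent") {
    value <- rowMeans(mat)
  } else {
    set.seed(stream_seed(seed, paste0(label, "|selection")))
    pick <- sample.int(ncol(mat), n, replace = TRUE)
    value <- mat[cbind(seq_len(n), pick)]
  }
  new_draws(tibble(label = label, iter = seq_len(n), u = u, value = value),
            n_iter = n, seed = seed)
}

#' Summarise prevalence draws into report rows
#'
#' Produces, per model label, the row shape used for reporting: minimum,
#' empirical 10th/50th/90th percentiles (linear interpolation between order
#' statistics), maximum, mean, and SE taken as the sample standard deviation
#' of the draws. Values are kept at full precision; rounding is left to the
#' presentation layer.
#'
#' @param draws An `mm_draws` table (one or several labels).
#' @return A tibble with columns `label`, `min`, `p10`, `p50`, `p90`, `max`,
#'   `mean`, `se`, one row per label in order of first appearance.
#' @export
summarize_draws <- function(draws) {
  if (is.null(draws) || nrow(draws) == 0) abort("draws must be non-empty")
  draws |>
    mutate(label = factor(.data$label, levels = unique(.data$label))) |>
    group_by(.data$label) |>
    summarise(
      min = min(.data$value),
      p10 = quantile(.data$value, 0.10, names = FALSE, type = 7),
      p50 = quantile(.data$value, 0.50, names = FALSE, type = 7),
      p90 = quantile(.data$value, 0.90, names = FALSE, type = 7),
      max = max(.data$value),
      mean = mean(.data$value),
      se = if (n() > 1) sd(.data$value) else 0,
      .groups = "drop"
    ) |>
    mutate(label = as.character(.data$label))
}

#' Prevalence band from a summary row
#'
#' Converts summary rows into a mean ± 1 SE band of hidden-population counts
#' and the corresponding percentages of the regional population. The band is
#' a ±1 standard error spread, not a 95% interval.
#'
#' @param summary A summary tibble from [summarize_draws()] (any subset of
#'   rows; the band is computed per row).
#' @param population Regional population size (positive integer).
#' @return A tibble with columns `label`, `count_low`, `count_high`
#'   (unrounded `mean -/+ se`), `pct_low`, `pct_high` (percentages of
#'   `population`, rounded to two decimals), and `population`.
#' @examples
#' prevalence_band(
#'   tibble::tibble(label = "Model Average", mean = 15067, se = 1556),
#'   population = 2165139
#' )
#' @export
prevalence_band <- function(summary, population) {
  if (!is.numeric(population) || length(population) != 1 || population <= 0) {
    abort("population must be a single positive number")
  }
  if (!all(c("mean", "se") %in% names(summary))) {
    abort("summary must have columns mean and se")
  }
  tibble(
    label = if ("label" %in% names(summary)) summary$label else "model",
    count_low = summary$mean - summary$se,
    count_high = summary$mean + summary$se,
    pct_low = round(100 * (summary$mean - summary$se) / population, 2),
    pct_high = round(100 * (summary$mean + summary$se) / population, 2),
    population = population
  )
}
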