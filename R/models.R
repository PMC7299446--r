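#' Build a table of benchmark multiplier models
#'
#' A benchmark model pairs an observed endpoint count `A` (e.g. fatal
#' overdoses in a year) with a multiplier estimate `B`: the proportion of the
#' hidden population experiencing that endpoint annually, summarised as a mean
#' and standard error on the proportion scale. The hidden-population size is
#' then `C = A / B`.
#'
#' @param label Character vector of model names.
#' @param endpoint_count Non-negative counts, one per model (symbol A).
#' @param multiplier_mean Multiplier means in (0, 1), one per model.
#' @param multiplier_se Non-negative standard errors on the proportion scale.
#'   A zero SE denotes a degenerate (point-mass) multiplier.
#'
#' @return A tibble with one row per model and the four columns above,
#'   validated against the model invariants.
#' @examples
#' multiplier_models(
#'   label = c("Fatal Overdose", "Treatment Admission"),
#'   endpoint_count = c(996, 2752),
#'   multiplier_mean = c(0.07182, 0.21376),
#'   multiplier_se = c(0.00533, 0.02142)
#' )
#' @export
multiplier_models <- function(label, endpoint_count, multiplier_mean,
                              multiplier_se) {
  out <- tibble(
    label = as.character(label),
    endpoint_count = as.numeric(endpoint_count),
    multiplier_mean = as.numeric(multiplier_mean),
    multiplier_se = as.numeric(multiplier_se)
  )
  validate_models(out)
}

#' Validate a benchmark-model table
#'
#' Checks the invariants required for a proper beta fit of each multiplier:
#' endpoint counts non-negative, means strictly inside (0, 1), SEs
#' non-negative, and `se^2 < mean * (1 - mean)` whenever `se > 0`.
#'
#' @param data A data frame with columns `label`, `endpoint_count`,
#'   `multiplier_mean`, `multiplier_se`.
#' @return `data` as a tibble, invisibly unchanged, or an error naming the
#'   offending field and row.
#' @export
validate_models <- function(data) {
  required <- c("label", "endpoint_count", "multiplier_mean", "multiplier_se")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    abort(paste0("model table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  data <- as_tibble(data)
  if (nrow(data) == 0) abort("model table must contain at least one model")
  check <- function(ok, field) {
    if (!all(ok)) {
      bad <- data$label[!ok]
      abort(sprintf("invalid %s for model(s): %s",
                    field, paste(bad, collapse = ", ")))
    }
  }
  check(is.finite(data$endpoint_count) & data$endpoint_count >= 0,
        "endpoint_count (must be a non-negative count)")
  check(is.finite(data$multiplier_mean) &
          data$multiplier_mean > 0 & data$multiplier_mean < 1,
        "multiplier_mean (must lie strictly in (0, 1))")
  check(is.finite(data$multiplier_se) & data$multiplier_se >= 0,
        "multiplier_se (must be non-negative)")
  check(data$multiplier_se^2 <
          data$multiplier_mean * (1 - data$multiplier_mean),
        "multiplier_se (se^2 must be < mean * (1 - mean) for a beta fit)")
  data
}

#' Remove repeat events from a raw endpoint count
#'
#' Endpoint counts must count *individuals*, not events. When a raw count
#' includes repeat events by the same person (e.g. multiple emergency
#' department visits in a year), it is deflated by the estimated repeat
#' fraction before entering a multiplier model.
#'
#' @param raw_count Non-negative event count(s).
#' @param repeat_fraction Proportion of events that are repeats, in `[0, 1)`.
#' @return `round(raw_count * (1 - repeat_fraction))`, rounding halves away
#'   from zero, as a non-negative integer-valued numeric.
#' @examples
#' adjust_repeat_events(1000, 0.35) # 650
#' @export
adjust_repeat_events <- function(raw_count, repeat_fraction) {
  if (any(!is.finite(raw_count)) || any(raw_count < 0)) {
    abort("raw_count must be non-negative")
  }
  if (any(!is.finite(repeat_fraction)) ||
      any(repeat_fraction < 0) || any(repeat_fraction >= 1)) {
    abort("repeat_fraction must lie in [0, 1)")
  }
  # round half away from zero (counts are non-negative, so +0.5 then floor)
  floor(raw_count * (1 - repeat_fraction) + 0.5)
}
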