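#' Patient-weighted pooling of study-level multiplier estimates
#'
#' Pools study-level proportions into one multiplier estimate per benchmark
#' model, weighting each study by its patient count:
#' `m = sum(n_i * p_i) / sum(n_i)`. Two standard errors are offered, since
#' reported SEs of pooled multipliers in this literature are typically far
#' larger than the binomial SE on the pooled patient total:
#'
#' * `"between_study_weighted"` (default): the patient-weighted SD of the
#'   study proportions around the pooled mean, divided by `sqrt(k)` for `k`
#'   studies — `sqrt(sum(n_i (p_i - m)^2) / sum(n_i)) / sqrt(k)`. Captures
#'   between-study heterogeneity. For a single study, that study's own `se`
#'   is returned (an error if it has none).
#' * `"binomial"`: `sqrt(m (1 - m) / sum(n_i))`, the SE if all patients were
#'   one homogeneous sample.
#'
#' @param studies A study table with columns `n_patients` (positive integer)
#'   and `proportion` (in (0, 1)); optional `se` and `citation_tag`.
#' @param se_method SE method, see above.
#' @param label Label carried onto the pooled estimate.
#' @return A one-row tibble: `label`, `multiplier_mean`, `multiplier_se`,
#'   `n_studies`, `n_patients`, `se_method` — directly usable as the
#'   multiplier columns of a model table.
#' @examples
#' studies <- tibble::tibble(n_patients = c(100, 300),
#'                           proportion = c(0.2, 0.4))
#' pool_estimates(studies) # pooled mean 0.35
#' @export
pool_estimates <- function(studies,
                           se_method = c("between_study_weighted", "binomial"),
                           label = "pooled") {
  se_method <- match.arg(se_method)
  if (is.null(studies) || nrow(studies) == 0) {
    abort("studies must contain at least one record")
  }
  if (!all(c("n_patients", "proportion") %in% names(studies))) {
    abort("studies must have columns n_patients and proportion")
  }
  n <- as.numeric(studies$n_patients)
  p <- as.numeric(studies$proportion)
  if (any(!is.finite(n)) || any(n < 1)) abort("n_patients must be >= 1")
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("proportion must lie strictly in (0, 1)")
  }
  k <- length(p)
  m <- sum(n * p) / sum(n)
  if (se_method == "binomial") {
    se <- sqrt(m * (1 - m) / sum(n))
  } else if (k == 1) {
    if (!"se" %in% names(studies) || is.na(studies$se[1])) {
      abort(paste("between-study SE is undefined for a single study without",
                  "its own se; supply se or use se_method = \"binomial\""))
    }
    se <- as.numeric(studies$se[1])
  } else {
    se <- sqrt(sum(n * (p - m)^2) / sum(n)) / sqrt(k)
  }
  tibble(label = label, multiplier_mean = m, multiplier_se = se,
         n_studies = k, n_patients = sum(n), se_method = se_method)
}

#' Read a study table from CSV
#'
#' Expects columns `citation_tag`, `n_patients`, `proportion`, and optionally
#' `se`, matching the table layout produced by a literature review.
#'
#' @param path Path to a CSV file.
#' @return A validated study tibble for [pool_estimates()].
#' @export
read_study_table <- function(path) {
  studies <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("n_patients", "proportion") %in% names(studies))) {
    abort("study CSV must have columns n_patients and proportion")
  }
  studies
}
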