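#' Fit beta distributions to multiplier moments
#'
#' Each multiplier is modelled as beta-distributed on (0, 1); the shape
#' parameters are chosen by the method of moments so the distribution's mean
#' and standard deviation reproduce the reported mean `m` and standard error
#' `s` exactly. With `nu = m (1 - m) / s^2 - 1`, the fit is
#' `alpha = m * nu`, `beta = (1 - m) * nu`. A zero SE yields a degenerate
#' point mass at `m` (`alpha`/`beta` are set to `NA` and ignored).
#'
#' @param data A model table with columns `multiplier_mean` and
#'   `multiplier_se` (see [multiplier_models()]); other columns pass through.
#' @return `data` with columns `alpha`, `beta` and logical `degenerate`
#'   appended.
#' @examples
#' fit_beta_moments(tibble::tibble(
#'   label = "Fatal Overdose", endpoint_count = 996,
#'   multiplier_mean = 0.07182, multiplier_se = 0.00533
#' ))
#' @export
fit_beta_moments <- function(data) {
  if (!all(c("multiplier_mean", "multiplier_se") %in% names(data))) {
    abort("data must have columns multiplier_mean and multiplier_se")
  }
  m <- data$multiplier_mean
  s <- data$multiplier_se
  if (any(!is.finite(m)) || any(m <= 0) || any(m >= 1)) {
    abort("multiplier_mean must lie strictly in (0, 1)")
  }
  if (any(!is.finite(s)) || any(s < 0)) {
    abort("multiplier_se must be non-negative")
  }
  if (any(s^2 >= m * (1 - m))) {
    abort("no beta distribution has these moments: need se^2 < mean * (1 - mean)")
  }
  degenerate <- s == 0
  nu <- ifelse(degenerate, NA_real_, m * (1 - m) / s^2 - 1)
  mutate(as_tibble(data),
         alpha = m * nu,
         beta = (1 - m) * nu,
         degenerate = degenerate)
}

#' Analytic moments of the reciprocal multiplier
#'
#' For `B ~ Beta(alpha, beta)` the prevalence draw is `C = A / B`, so the
#' moments of `1/B` give closed-form oracles for the Monte Carlo simulation:
#' `E[1/B] = (alpha + beta - 1) / (alpha - 1)` (defined for `alpha > 1`) and
#' `E[1/B^2] = (alpha + beta - 1)(alpha + beta - 2) /
#' ((alpha - 1)(alpha - 2))` (defined for `alpha > 2`), from which the SD of
#' `1/B` follows. Degenerate multipliers give `(1/m, 0)`.
#'
#' @param data A model table; if `alpha`/`beta` are absent it is passed
#'   through [fit_beta_moments()] first.
#' @return `data` with columns `inv_mean` and `inv_sd` appended. Undefined
#'   moments (`alpha <= 1` for the mean, `alpha <= 2` for the SD) are returned
#'   as `NA` with a warning.
#' @export
inverse_beta_moments <- function(data) {
  if (!all(c("alpha", "beta", "degenerate") %in% names(data))) {
    data <- fit_beta_moments(data)
  }
  a <- data$alpha
  b <- data$beta
  deg <- data$degenerate
  inv_mean <- ifelse(deg, 1 / data$multiplier_mean,
                     ifelse(a > 1, (a + b - 1) / (a - 1), NA_real_))
  m2 <- ifelse(a > 2, (a + b - 1) * (a + b - 2) / ((a - 1) * (a - 2)),
               NA_real_)
  inv_sd <- ifelse(deg, 0, sqrt(pmax(m2 - inv_mean^2, 0)))
  if (any(!deg & a <= 1)) {
    warn("mean of 1/B undefined for alpha <= 1; returning NA")
  }
  if (any(!deg & a > 1 & a <= 2)) {
    warn("SD of 1/B undefined for alpha <= 2; returning NA")
  }
  mutate(as_tibble(data), inv_mean = inv_mean, inv_sd = inv_sd)
}
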