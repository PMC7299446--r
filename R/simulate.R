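#' Derive a per-label random stream seed from a master seed
#'
#' Each model's uniform stream is seeded from the master seed and its label,
#' so adding or removing a model never perturbs the draws of the others.
#' The label is hashed with a small polynomial rolling hash modulo
#' 2^31 - 1; all intermediates stay within the exactly-representable double
#' range.
#'
#' @param seed Master integer seed.
#' @param label Character scalar.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
stream_seed <- function(seed, label) {
  p <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 31 + ch) %% p
  s <- as.numeric(seed) %% p
  as.integer((h * 69069 + s * 3) %% p)
}

new_draws <- function(data, n_iter, seed) {
  structure(as_tibble(data), class = c("mm_draws", class(as_tibble(data))),
            n_iter = n_iter, seed = seed)
}

#' Monte Carlo simulation of prevalence draws per benchmark model
#'
#' For each model, draws `n_iter` uniform quantiles `u` from a per-label
#' stream and transforms them through the inverse CDF of the fitted beta
#' multiplier: `C_i = A / qbeta(u_i, alpha, beta)`. The inverse-CDF form (as
#' opposed to direct beta sampling) exposes the uniforms, which the averaging
#' step needs to impose common random numbers across models. Degenerate
#' multipliers yield the constant `A / m` (their uniforms are still drawn, to
#' keep streams aligned).
#'
#' @param data A model table (see [multiplier_models()]); fitted via
#'   [fit_beta_moments()] first if `alpha` is absent.
#' @param n_iter Number of Monte Carlo iterations per model (default 10000).
#' @param seed Master integer seed; per-model streams derive from
#'   `(seed, label)`.
#' @return A draw table of class `mm_draws`: columns `label`, `iter`, `u`,
#'   `value`, with `n_iter` and `seed` attributes. Identical inputs give
#'   bit-identical draws.
#' @examples
#' m <- multiplier_models("Fatal Overdose", 996, 0.07182, 0.00533)
#' d <- simulate_models(m, n_iter = 1000, seed = 1)
#' mean(d$value)
#' @export
simulate_models <- function(data, n_iter = 10000, seed) {
  if (missing(seed)) abort("seed must be supplied")
  if (!is.numeric(n_iter) || length(n_iter) != 1 || n_iter < 1) {
    abort("n_iter must be a positive integer")
  }
  n_iter <- as.integer(n_iter)
  if (!all(c("alpha", "beta", "degenerate") %in% names(data))) {
    data <- fit_beta_moments(validate_models(data))
  }
  rows <- lapply(seq_len(nrow(data)), function(i) {
    lab <- data$label[i]
    set.seed(stream_seed(seed, lab))
    u <- runif(n_iter)
    if (data$degenerate[i]) {
      value <- rep(data$endpoint_count[i] / data$multiplier_mean[i], n_iter)
    } else {
      value <- data$endpoint_count[i] / qbeta(u, data$alpha[i], data$beta[i])
    }
    tibble(label = lab, iter = seq_len(n_iter), u = u, value = value)
  })
  new_draws(bind_rows(rows), n_iter = n_iter, seed = seed)
}
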