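# Benchmark-model table used across tests: the three Cincinnati CBSA models
# (endpoint counts and pooled multipliers), built in code so unit tests do
# not depend on the packaged config file.
cincy_tbl <- function() {
  multiplier_models(
    label = c("Fatal Overdose", "Treatment Admissions",
              "Non-Fatal ED Overdoses"),
    endpoint_count = c(996, 2752, 7342),
    multiplier_mean = c(0.07182, 0.21376, 0.40890),
    multiplier_se = c(0.00533, 0.02142, 0.05111)
  )
}

CINCY_POP <- 2165139

# Analytic mean/SD of a Beta(alpha, beta) distribution — the independent
# moment-recovery oracle for the method-of-moments fit.
beta_moments <- function(alpha, beta) {
  m <- alpha / (alpha + beta)
  v <- alpha * beta / ((alpha + beta)^2 * (alpha + beta + 1))
  c(mean = m, sd = sqrt(v))
}

# Numerical-integration oracle for moments of 1/B under Beta(alpha, beta).
integrate_inv_moments <- function(alpha, beta) {
  m1 <- stats::integrate(function(b) stats::dbeta(b, alpha, beta) / b,
                         0, 1, rel.tol = 1e-10)$value
  m2 <- stats::integrate(function(b) stats::dbeta(b, alpha, beta) / b^2,
                         0, 1, rel.tol = 1e-10)$value
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

# Wrap a plain value vector as a draw table for summarize_draws().
draws_tbl <- function(values, label = "model") {
  tibble::tibble(label = label, iter = seq_along(values),
                 u = NA_real_, value = values)
}
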