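test_that("method-of-moments fit recovers its input moments to 1e-10", {
  # property over a grid of feasible (mean, se) pairs
  grid <- expand.grid(m = c(0.01, 0.07182, 0.21376, 0.4089, 0.5, 0.9),
                      rel = c(0.02, 0.074, 0.2))
  fit <- fit_beta_moments(tibble::tibble(multiplier_mean = grid$m,
                                         multiplier_se = grid$m * grid$rel))
  for (i in seq_len(nrow(fit))) {
    mom <- beta_moments(fit$alpha[i], fit$beta[i])
    expect_equal(mom[["mean"]], fit$multiplier_mean[i], tolerance = 1e-10)
    expect_equal(mom[["sd"]], fit$multiplier_se[i], tolerance = 1e-10)
  }
})

test_that("fitted shapes match hand-derived values for the pooled multipliers", {
  fit <- fit_beta_moments(cincy_tbl())
  # frozen from the moment formulas alpha = m*nu, beta = (1-m)*nu,
  # nu = m(1-m)/s^2 - 1, cross-checked by the moment-recovery oracle above
  expect_equal(fit$alpha[1], 168.455, tolerance = 1e-4)
  expect_equal(fit$beta[1], 2177.059, tolerance = 1e-4)
  expect_equal(fit$alpha[2], 78.088, tolerance = 1e-4)
  expect_equal(fit$beta[2], 287.217, tolerance = 1e-4)
  expect_false(any(fit$degenerate))
})

test_that("zero standard error yields a degenerate point mass", {
  fit <- fit_beta_moments(tibble::tibble(multiplier_mean = 0.5,
                                         multiplier_se = 0))
  expect_true(fit$degenerate)
  expect_true(is.na(fit$alpha))
})

test_that("infeasible or invalid moments are rejected", {
  expect_error(
    fit_beta_moments(tibble::tibble(multiplier_mean = 0.5,
                                    multiplier_se = 0.5)),
    "se\\^2"
  )
  expect_error(
    fit_beta_moments(tibble::tibble(multiplier_mean = 1.2,
                                    multiplier_se = 0.01)),
    "strictly in"
  )
  expect_error(
    fit_beta_moments(tibble::tibble(multiplier_mean = 0.5,
                                    multiplier_se = -0.1)),
    "non-negative"
  )
})

test_that("analytic reciprocal moments agree with numerical integration", {
  inv <- inverse_beta_moments(cincy_tbl())
  fit <- fit_beta_moments(cincy_tbl())
  for (i in seq_len(nrow(inv))) {
    oracle <- integrate_inv_moments(fit$alpha[i], fit$beta[i])
    expect_equal(inv$inv_mean[i], oracle[["mean"]], tolerance = 1e-8)
    expect_equal(inv$inv_sd[i], oracle[["sd"]], tolerance = 1e-6)
  }
  # frozen values from the integration oracle
  expect_equal(inv$inv_mean[1], 14.00088, tolerance = 1e-5)
  expect_equal(inv$inv_mean[3], 2.485272, tolerance = 1e-5)
})

test_that("degenerate multiplier has reciprocal moments (1/m, 0)", {
  inv <- inverse_beta_moments(tibble::tibble(multiplier_mean = 0.5,
                                             multiplier_se = 0))
  expect_equal(inv$inv_mean, 2)
  expect_equal(inv$inv_sd, 0)
})

test_that("undefined reciprocal moments warn and return NA", {
  # alpha < 1: mean and SD both undefined
  low <- tibble::tibble(multiplier_mean = 0.01, multiplier_se = 0.09)
  expect_warning(inv <- inverse_beta_moments(low), "alpha <= 1")
  expect_true(is.na(inv$inv_mean))
  expect_true(is.na(inv$inv_sd))
  # 1 < alpha <= 2: mean defined, SD not
  mid <- tibble::tibble(multiplier_mean = 0.5, multiplier_se = 0.28)
  expect_warning(inv2 <- inverse_beta_moments(mid), "alpha <= 2")
  expect_false(is.na(inv2$inv_mean))
  expect_true(is.na(inv2$inv_sd))
})

test_that("repeat-event adjustment deflates counts with half-up rounding", {
  expect_identical(adjust_repeat_events(1000, 0.35), 650)
  expect_identical(adjust_repeat_events(0, 0.35), 0)
  # a raw ED event count of ~11295 deduplicates to the person count 7342
  expect_identical(adjust_repeat_events(11295, 0.35), 7342)
  expect_identical(adjust_repeat_events(c(10, 11), 0.35), c(7, 7))
  expect_error(adjust_repeat_events(100, 1), "\\[0, 1\\)")
  expect_error(adjust_repeat_events(-5, 0.2), "non-negative")
})
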