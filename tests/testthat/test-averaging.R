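test_that("comonotonic averaging: percentiles add, SDs nearly add", {
  d <- simulate_models(cincy_tbl(), n_iter = 4000, seed = 2)
  avg <- average_models(d, scheme = "comonotonic")
  per_model <- summarize_draws(d)
  s_avg <- summarize_draws(avg)
  # each reported quantile of the average equals the mean of the models'
  # quantiles (exact for min/max; interpolation error only for percentiles)
  for (col in c("min", "p10", "p50", "p90", "max")) {
    expect_equal(s_avg[[col]], mean(per_model[[col]]), tolerance = 1e-3)
  }
  expect_equal(s_avg$min, mean(per_model$min), tolerance = 1e-12)
  expect_equal(s_avg$max, mean(per_model$max), tolerance = 1e-12)
  # comonotone coupling: SD of the average ~ mean of the per-model SDs
  expect_equal(s_avg$se, mean(per_model$se), tolerance = 5e-3)
  # the mean is scheme-free: mean of the per-model means
  expect_equal(s_avg$mean, mean(per_model$mean), tolerance = 1e-12)
})

test_that("averaging a model with itself reproduces its distribution", {
  d <- simulate_models(cincy_tbl()[1, ], n_iter = 1000, seed = 4)
  for (scheme in c("comonotonic", "independent", "model_selection")) {
    avg <- average_models(d, scheme = scheme)
    expect_equal(sort(avg$value), sort(d$value))
  }
})

test_that("averaging degenerate constants gives their midpoint everywhere", {
  m <- multiplier_models(c("a", "b"), c(100, 300), c(0.5, 0.5), c(0, 0))
  d <- simulate_models(m, n_iter = 100, seed = 1)
  avg <- average_models(d) # constants 200 and 600
  expect_true(all(avg$value == 400))
})

test_that("independent coupling shrinks the averaged SD below comonotonic", {
  d <- simulate_models(cincy_tbl(), n_iter = 5000, seed = 6)
  sd_como <- sd(average_models(d, scheme = "comonotonic")$value)
  sd_indep <- sd(average_models(d, scheme = "independent")$value)
  expect_lt(sd_indep, sd_como)
})

test_that("model selection mixes the models: grand mean, inflated SD", {
  d <- simulate_models(cincy_tbl(), n_iter = 10000, seed = 8)
  per_model <- summarize_draws(d)
  sel <- average_models(d, scheme = "model_selection")
  grand_mean <- mean(per_model$mean)
  # Monte Carlo error of the mixture mean
  mix_sd <- sqrt(mean(per_model$se^2) + stats::var(per_model$mean))
  expect_lt(abs(mean(sel$value) - grand_mean), 4 * mix_sd / sqrt(10000))
  # between-model spread is large here, so mixing beats comonotonic SD
  sd_como <- sd(average_models(d, scheme = "comonotonic")$value)
  expect_gt(sd(sel$value), sd_como)
})

test_that("averaging is invariant to model order", {
  d <- simulate_models(cincy_tbl(), n_iter = 500, seed = 9)
  rev_tbl <- cincy_tbl()[3:1, ]
  d_rev <- simulate_models(rev_tbl, n_iter = 500, seed = 9)
  a1 <- average_models(d, scheme = "comonotonic", seed = 9)
  a2 <- average_models(d_rev, scheme = "comonotonic", seed = 9)
  expect_identical(a1$value, a2$value)
})

test_that("mismatched iteration counts and empty input are rejected", {
  d1 <- simulate_models(cincy_tbl()[1, ], n_iter = 100, seed = 1)
  d2 <- simulate_models(cincy_tbl()[2, ], n_iter = 200, seed = 1)
  both <- dplyr::bind_rows(d1, d2)
  expect_error(average_models(both, seed = 1), "same number of iterations")
  empty <- draws_tbl(numeric(0))[0, ]
  expect_error(average_models(empty, seed = 1), "at least one")
})

test_that("summary rows report order statistics, mean, and sample SD", {
  # uniform integer grid has closed-form summaries
  grid <- draws_tbl(sample(1:10000)) # order of draws must not matter
  s <- summarize_draws(grid)
  expect_equal(s$mean, 5000.5)
  expect_equal(s$p50, 5000.5)
  expect_equal(s$min, 1)
  expect_equal(s$max, 10000)
  expect_equal(s$p10, quantile(1:10000, 0.1, names = FALSE))
  expect_equal(s$se, sd(1:10000))
  # constant draws collapse every field
  s2 <- summarize_draws(draws_tbl(rep(7, 25)))
  expect_true(all(unlist(s2[c("min", "p10", "p50", "p90", "max", "mean")]) == 7))
  expect_equal(s2$se, 0)
  expect_error(summarize_draws(grid[0, ]), "non-empty")
})

test_that("summary rows are monotone across reported quantiles", {
  d <- simulate_models(cincy_tbl(), n_iter = 1000, seed = 10)
  s <- summarize_draws(d)
  expect_true(all(s$min <= s$p10 & s$p10 <= s$p50 &
                    s$p50 <= s$p90 & s$p90 <= s$max))
  expect_true(all(s$se >= 0))
})

test_that("prevalence band is mean +/- SE with percentages of population", {
  row <- tibble::tibble(label = "Model Average", mean = 15067, se = 1556)
  band <- prevalence_band(row, population = CINCY_POP)
  expect_equal(band$count_low, 13511)
  expect_equal(band$count_high, 16623)
  expect_equal(band$pct_low, 0.62)
  expect_equal(band$pct_high, 0.77)
  zero <- prevalence_band(tibble::tibble(mean = 100, se = 0), 10000)
  expect_equal(zero$count_low, 100)
  expect_equal(zero$count_high, 100)
  expect_equal(zero$pct_low, 1)
  expect_error(prevalence_band(row, population = 0), "positive")
})
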