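test_that("doubling time follows the generation formula", {
  expect_equal(round(doubling_time(100, 1, 74), 2), 16.10)
  expect_equal(round(doubling_time(150, 1, 76), 2), 24.01)
  expect_equal(doubling_time(37, 1, 2), 37)      # one doubling
  expect_true(is.na(doubling_time(10, 5, 5)))    # undefined
  expect_true(is.na(doubling_time(10, 5, 3)))
})

test_that("growth rate and doubling time are exact inverses", {
  expect_equal(signif(growth_rate(100, 74), 3), 0.0621)
  expect_equal(growth_rate(10, 1), 0)
  expect_equal(growth_rate(1, 2), 1)
  for (Bn in c(2, 3, 10, 74, 76, 85, 1000)) {
    for (t in c(1, 50, 100, 400)) {
      expect_equal(doubling_time(t, 1, Bn) * growth_rate(t, Bn), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("doubling time decreases with the final count", {
  g <- doubling_time(100, 1, c(2, 5, 20, 74, 200))
  expect_true(all(diff(g) < 0))
})

test_that("normalisation reproduces the cross-species ratios", {
  expect_equal(normalize_times(26, 17), 1.53)
  expect_equal(normalize_times(66, 17), 3.88)
  expect_equal(normalize_times(17, 17), 1.00)
  expect_error(normalize_times(1, 0), "> 0")
})

test_that("the closed-form estimator recovers a known rate", {
  K <- 0.05   # natural-log units per minute
  tt <- 0:80
  cen <- growth_census(tibble::tibble(run = 1, iteration = tt,
                                      cells = exp(K * tt)))
  fit <- fit_growth(cen, "exponential")
  expect_lt(abs(fit$parameters[["K"]] - K) / K, 0.01)
})

test_that("gompertz parameters are recovered from noiseless data", {
  tt <- seq(0, 60, by = 2)
  A <- 4; mu <- 0.5; lambda <- 10
  y <- A * exp(-exp(mu * exp(1) / A * (lambda - tt) + 1))
  cen <- growth_census(tibble::tibble(run = 1, iteration = tt,
                                      cells = exp(y)))
  fit <- fit_growth(cen, "gompertz")
  expect_true(fit$converged)
  expect_lt(abs(fit$parameters[["A"]] - A) / A, 0.01)
  expect_lt(abs(fit$parameters[["mu"]] - mu) / mu, 0.01)
  expect_lt(abs(fit$parameters[["lambda"]] - lambda) / lambda, 0.01)
})

test_that("logistic data prefers the logistic model", {
  tt <- seq(0, 60, by = 2)
  A <- 4; mu <- 0.5; lambda <- 10
  y <- A / (1 + exp(4 * mu / A * (lambda - tt) + 2))
  cen <- growth_census(tibble::tibble(run = 1, iteration = tt,
                                      cells = exp(y)))
  f_log <- fit_growth(cen, "logistic")
  f_gom <- fit_growth(cen, "gompertz")
  expect_true(f_log$converged)
  expect_lte(f_log$rss, f_gom$rss)
})

test_that("a constant census is flagged degenerate, never silent", {
  cen <- growth_census(tibble::tibble(run = 1, iteration = 0:10, cells = 1))
  fit <- fit_growth(cen, "gompertz")
  expect_true(fit$degenerate)
  expect_equal(fit$parameters[["mu"]], 0)
})

test_that("fits refuse too-short series", {
  cen <- growth_census(tibble::tibble(run = 1, iteration = 0:2,
                                      cells = c(1, 2, 4)))
  expect_error(fit_growth(cen, "gompertz"), "4 time points")
})

test_that("tidy and glance summarise fits in broom style", {
  fx <- make_fixture("gompertz_demo")
  fit <- fit_growth(fx, "gompertz")
  td <- tidy(fit)
  expect_setequal(td$term, c("A", "mu", "lambda"))
  gl <- glance(fit)
  expect_equal(gl$model, "gompertz")
  expect_true(gl$converged)
  expect_equal(length(predict(fit)), nrow(fit$data))
})
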