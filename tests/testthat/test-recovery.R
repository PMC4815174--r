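# Closed-form OLS via the normal equations, kept independent of lm()
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)
}

test_that("regression coefficients match the normal-equation oracle", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.1, 2.9, 4.2, 4.8, 6.1)
  rec <- tibble::tibble(
    iteration = 1:5, parameter = "mu",
    true = x, clean = x, noisy = y,
    clean_converged = TRUE, noisy_converged = TRUE
  )
  class(rec) <- c("recovery_records", class(rec))
  reg <- regress_noisy_on_clean(rec)
  beta <- ols_oracle(x, y)
  expect_equal(reg$intercept, beta[1], tolerance = 1e-10)
  expect_equal(reg$slope, beta[2], tolerance = 1e-10)
  # significance flags keyed to the CIs excluding 0 / 1
  expect_identical(reg$intercept_sig, reg$intercept_ci_low > 0 | reg$intercept_ci_high < 0)
  expect_identical(reg$slope_sig, reg$slope_ci_low > 1 | reg$slope_ci_high < 1)
})

test_that("identity records give intercept 0, slope 1, both non-significant", {
  set.seed(41)
  v <- runif(20, 400, 600)
  rec <- tibble::tibble(
    iteration = 1:20, parameter = "mu",
    true = v, clean = v + rnorm(20), noisy = NA_real_,
    clean_converged = TRUE, noisy_converged = TRUE
  )
  rec$noisy <- rec$clean
  class(rec) <- c("recovery_records", class(rec))
  reg <- regress_noisy_on_clean(rec)
  expect_equal(reg$intercept, 0, tolerance = 1e-10)
  expect_equal(reg$slope, 1, tolerance = 1e-10)
  expect_false(reg$intercept_sig)
  expect_false(reg$slope_sig)
})

test_that("degenerate inputs are rejected", {
  rec <- tibble::tibble(
    iteration = 1:5, parameter = "mu",
    true = 1:5, clean = rep(2, 5), noisy = rnorm(5),
    clean_converged = TRUE, noisy_converged = TRUE
  )
  class(rec) <- c("recovery_records", class(rec))
  expect_error(regress_noisy_on_clean(rec), "Degenerate")
  expect_error(regress_noisy_on_clean(rec[1:2, ]), "3 usable")
})

test_that("zero-width noise makes the noisy fit equal the clean fit", {
  rec <- run_recovery("exgauss",
    iterations = 8, noise = noise_spec(0, 0), seed = 7
  )
  expect_identical(rec$clean, rec$noisy)
})

test_that("recovery runs are reproducible and keep the pairing invariant", {
  r1 <- run_recovery("exgauss", iterations = 6, seed = 123)
  r2 <- run_recovery("exgauss", iterations = 6, seed = 123)
  expect_identical(r1$clean, r2$clean)
  expect_identical(r1$noisy, r2$noisy)
  expect_equal(nrow(r1), 6 * 3)
  expect_setequal(unique(r1$parameter), c("mu", "sigma", "tau"))
})

test_that("noise sweep is reproducible and rejects bad bounds", {
  s1 <- run_noise_sweep(c(50, 100), iterations = 12, seed = 9)
  s2 <- run_noise_sweep(c(50, 100), iterations = 12, seed = 9)
  expect_identical(s1$intercept, s2$intercept)
  expect_equal(nrow(s1), 2 * 3)
  expect_error(run_noise_sweep(c(10, 50), iterations = 5, seed = 1))
})

test_that("mu intercept trends upward with the noise bound", {
  sw <- run_noise_sweep(c(50, 100, 150, 200), iterations = 120, seed = 14)
  mu_int <- sw |>
    dplyr::filter(parameter == "mu") |>
    dplyr::mutate(wid = intercept_ci_high - intercept_ci_low)
  trend <- meta_regression_wls(mu_int, noise_high, intercept, wid)
  expect_gt(trend$slope, 0)
})

test_that("weighted least squares matches the weighted normal equations", {
  lev <- c(50, 100, 150, 200)
  est <- c(31, 55, 82, 101)
  wid <- c(8, 11, 15, 22)
  d <- tibble::tibble(lev, est, wid)
  res <- meta_regression_wls(d, lev, est, wid)
  W <- diag(1 / wid)
  X <- cbind(1, lev)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% est)
  expect_equal(res$intercept, beta[1], tolerance = 1e-10)
  expect_equal(res$slope, beta[2], tolerance = 1e-10)
  # equal widths reduce to ordinary least squares
  d2 <- tibble::tibble(lev, est, wid = 5)
  res2 <- meta_regression_wls(d2, lev, est, wid)
  b2 <- ols_oracle(lev, est)
  expect_equal(res2$slope, b2[2], tolerance = 1e-10)
  # a dominant weight forces the line through that point
  d3 <- tibble::tibble(
    lev = c(0, 1, 2), est = c(0, 5, 1), wid = c(1, 1e-6, 1)
  )
  res3 <- meta_regression_wls(d3, lev, est, wid)
  expect_lt(abs(res3$intercept + res3$slope * 1 - 5), 1e-5)
  expect_error(meta_regression_wls(
    tibble::tibble(lev = 1:3, est = 1:3, wid = c(1, 0, 1)), lev, est, wid
  ))
})
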