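# Frozen oracle value: quadrature convolution of normal(500, 50) with
# exponential(mean 100) at x = 520,
#   integrate(function(y) dnorm(520 - y, 500, 50) * dexp(y, 1/100), 0, Inf,
#             rel.tol = 1e-12)$value
PDF_520 <- 0.004269216968875

test_that("density matches the convolution oracle and normalizes", {
  expect_equal(dexgauss(520, 500, 50, 100), PDF_520, tolerance = 1e-6)
  # recompute the oracle in-test for a second point
  oracle <- function(x, mu, sigma, tau) {
    integrate(function(y) dnorm(x - y, mu, sigma) * dexp(y, 1 / tau),
      0, Inf,
      rel.tol = 1e-12
    )$value
  }
  expect_equal(dexgauss(650, 480, 30, 120), oracle(650, 480, 30, 120),
    tolerance = 1e-6
  )
  # normalization and mean over the prior-box grid
  for (mu in c(450, 550)) {
    for (sigma in c(25, 75)) {
      for (tau in c(50, 150)) {
        z <- integrate(function(x) dexgauss(x, mu, sigma, tau),
          -Inf, Inf,
          rel.tol = 1e-10
        )$value
        expect_equal(z, 1, tolerance = 1e-8)
      }
    }
  }
  m <- integrate(function(x) x * dexgauss(x, 500, 50, 100), -Inf, Inf)$value
  expect_equal(m, 600, tolerance = 1e-6)
})

test_that("density is non-negative and stable far into the tails", {
  x <- seq(-2000, 5000, by = 50)
  d <- dexgauss(x, 500, 50, 100)
  expect_true(all(d >= 0))
  expect_true(all(is.finite(dexgauss(x, 500, 50, 100, log = TRUE)[d > 0] |>
    suppressWarnings())))
  # extreme sigma/tau ratio must not overflow or produce spurious values
  expect_true(is.finite(dexgauss(500, 500, 50, 1e-6, log = TRUE)))
  expect_true(dexgauss(500, 500, 1e6, 100, log = TRUE) < -10)
  expect_error(dexgauss(Inf, 500, 50, 100))
  expect_error(dexgauss(500, 500, -1, 100))
  expect_error(dexgauss(500, 500, 50, 0))
})

test_that("small-tau limit recovers the normal shape", {
  mu <- 500
  sigma <- 50
  tau <- 1e-3 * sigma
  x <- seq(mu - 3 * sigma, mu + 3 * sigma, length.out = 121)
  # the limiting distribution is normal with mean mu + tau; matching the
  # mean isolates shape convergence
  rel <- dexgauss(x, mu, sigma, tau) / dnorm(x, mu + tau, sigma) - 1
  expect_lt(max(abs(rel)), 1e-3)
  # pointwise convergence to normal(mu, sigma) as tau decreases
  err <- function(tt) max(abs(dexgauss(x, mu, sigma, tt) / dnorm(x, mu, sigma) - 1))
  expect_lt(err(1e-4 * sigma), err(1e-3 * sigma))
  expect_lt(err(1e-4 * sigma), 1e-3)
})

test_that("log-likelihood is the sum of log densities", {
  expect_equal(
    exgauss_loglik(600, 500, 50, 100),
    base::log(dexgauss(600, 500, 50, 100))
  )
  set.seed(5)
  x <- rexgauss(40, 500, 50, 100)
  ll <- exgauss_loglik(x, 500, 50, 100)
  expect_equal(exgauss_loglik(c(x, x), 500, 50, 100), 2 * ll)
  expect_true(is.finite(exgauss_loglik(500 + 10 * 112, 500, 50, 100)))
  expect_error(exgauss_loglik(numeric(0), 500, 50, 100))
})

test_that("log-likelihood peaks near the generating mu on a coarse grid", {
  set.seed(17)
  x <- rexgauss(5000, 500, 50, 100)
  grid <- seq(400, 600, by = 10)
  ll <- vapply(grid, function(m) exgauss_loglik(x, m, 50, 100), numeric(1))
  expect_lt(abs(grid[which.max(ll)] - 500), 15)
})

test_that("ML fit recovers parameters from a large sample", {
  set.seed(42)
  x <- rexgauss(1e5, 500, 50, 100)
  fit <- fit_exgauss(x)
  expect_true(fit$converged)
  expect_lt(abs(fit$mu / 500 - 1), 0.02)
  expect_lt(abs(fit$sigma / 50 - 1), 0.02)
  expect_lt(abs(fit$tau / 100 - 1), 0.02)
})

test_that("fit is deterministic and idempotent", {
  set.seed(8)
  x <- rexgauss(80, 520, 40, 90)
  f1 <- fit_exgauss(x)
  f2 <- fit_exgauss(x)
  expect_identical(f1, f2)
  f3 <- fit_exgauss(x, start = c(f1$mu, f1$sigma, f1$tau))
  expect_gte(f3$loglik, f1$loglik - 1e-6)
})

test_that("fit rejects degenerate input", {
  expect_error(fit_exgauss(rep(500, 30)), "variance")
  expect_error(fit_exgauss(c(1, 2, 3)), "at least 10")
  expect_error(fit_exgauss(c(rep(500, 20), NA)))
})

test_that("tidy and glance methods expose the fit as tibbles", {
  set.seed(9)
  fit <- fit_exgauss(rexgauss(100, 500, 50, 100))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("mu", "sigma", "tau"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$converged)
  expect_equal(gl$nobs, 100L)
})
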