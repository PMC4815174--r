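test_that("driftless symmetric diffusion matches closed forms", {
  set.seed(101)
  # fine step: the Euler boundary-overshoot bias in the exit time is O(sqrt(dt))
  tr <- simulate_ddm(50000, a = 0.2, v = 0, ter = 0, z = 0.1, dt = 1e-4)
  p_up <- mean(tr$response == "upper")
  expect_lt(abs(p_up - 0.5), 3 * sqrt(0.25 / 50000) + 0.005)
  # mean exit time z(a - z)/s^2 = 1 s
  expect_lt(abs(mean(tr$rt) - 1), 0.02)
})

test_that("absorption probabilities match the analytic formula", {
  set.seed(102)
  p_closed <- ddm_absorption_prob(0.25, 0.25, z = 0.125, boundary = "upper")
  tr <- simulate_ddm(20000, a = 0.25, v = 0.25, ter = 0, dt = 5e-4)
  p_sim <- mean(tr$response == "upper")
  expect_lt(abs(p_sim - p_closed), 4 * sqrt(p_closed * (1 - p_closed) / 20000))
  # monotone increasing in v
  vgrid <- seq(-0.2, 0.25, by = 0.05)
  pv <- vapply(vgrid, function(v) {
    ddm_absorption_prob(0.2, v, boundary = "upper")
  }, numeric(1))
  expect_true(all(diff(pv) > 0))
})

test_that("non-decision time shifts every quantile without changing shape", {
  set.seed(103)
  tr1 <- simulate_ddm(2000, a = 0.2, v = 0.2, ter = 0.20)
  set.seed(103)
  tr2 <- simulate_ddm(2000, a = 0.2, v = 0.2, ter = 0.25)
  expect_identical(tr1$response, tr2$response)
  expect_equal(tr2$rt, tr1$rt + 0.05)
})

test_that("simulator warns on a coarse step and validates parameters", {
  expect_warning(simulate_ddm(5, a = 0.2, v = 0.2, ter = 0.2, dt = 0.01))
  expect_error(simulate_ddm(5, a = -0.1, v = 0.2, ter = 0.2))
  expect_error(simulate_ddm(5, a = 0.2, v = 0.2, ter = 0.2, z = 0.3))
})

test_that("defective densities integrate to their absorption probabilities", {
  for (a in c(0.15, 0.25)) {
    for (v in c(0.15, 0.25)) {
      pu <- integrate(function(t) ddm_fpt_density(t, a, v, boundary = "upper"),
        0, Inf,
        rel.tol = 1e-9
      )$value
      pl <- integrate(function(t) ddm_fpt_density(t, a, v, boundary = "lower"),
        0, Inf,
        rel.tol = 1e-9
      )$value
      expect_equal(pu + pl, 1, tolerance = 1e-6)
      expect_equal(pu, ddm_absorption_prob(a, v, boundary = "upper"),
        tolerance = 1e-6
      )
    }
  }
})

test_that("small-time and large-time series agree in their overlap region", {
  t <- seq(0.08, 0.8, by = 0.04)
  for (bd in c("upper", "lower")) {
    fs <- ddm_fpt_density(t, 0.2, 0.2, boundary = bd, representation = "small")
    fl <- ddm_fpt_density(t, 0.2, 0.2, boundary = bd, representation = "large")
    expect_lt(max(abs(fs - fl)), 1e-8)
  }
})

test_that("distribution function matches the integrated density", {
  for (tt in c(0.1, 0.3, 1)) {
    num <- integrate(function(x) ddm_fpt_density(x, 0.2, 0.18, boundary = "upper"),
      0, tt,
      rel.tol = 1e-10
    )$value
    expect_equal(ddm_fpt_cdf(tt, 0.2, 0.18, boundary = "upper"), num,
      tolerance = 1e-8
    )
  }
  expect_equal(
    ddm_fpt_cdf(60, 0.2, 0.18, boundary = "upper") +
      ddm_fpt_cdf(60, 0.2, 0.18, boundary = "lower"),
    1,
    tolerance = 1e-8
  )
  expect_equal(ddm_fpt_cdf(c(-1, 0), 0.2, 0.18, boundary = "upper"), c(0, 0))
})

test_that("density matches a fine-step simulation", {
  set.seed(104)
  n <- 200000
  tr <- simulate_ddm(n, a = 0.2, v = 0.2, ter = 0, dt = 1e-4)
  up <- tr$rt[tr$response == "upper"]
  # Kolmogorov-Smirnov distance between empirical and model CDFs,
  # both defective (normalised by n, not by the upper-trial count)
  tg <- seq(0.05, 3, by = 0.01)
  emp <- vapply(tg, function(t) mean(tr$rt <= t & tr$response == "upper"),
    numeric(1)
  )
  mod <- ddm_fpt_cdf(tg, 0.2, 0.2, boundary = "upper")
  expect_lt(max(abs(emp - mod)), 0.005)
})

test_that("quantile fit recovers parameters from a large sample", {
  set.seed(105)
  tr <- simulate_ddm(10000, a = 0.20, v = 0.20, ter = 0.20, dt = 1e-4)
  fit <- fit_ddm(tr)
  expect_true(fit$converged)
  expect_lt(abs(fit$a / 0.20 - 1), 0.03)
  expect_lt(abs(fit$v / 0.20 - 1), 0.03)
  expect_lt(abs(fit$ter / 0.20 - 1), 0.03)
  # continuous-ML objective agrees at large n
  fml <- fit_ddm(tr, method = "ml")
  expect_lt(abs(fml$a / 0.20 - 1), 0.03)
  expect_lt(abs(fml$v / 0.20 - 1), 0.03)
  expect_lt(abs(fml$ter / 0.20 - 1), 0.03)
})

test_that("fit is idempotent and shift-equivariant in ter", {
  set.seed(106)
  tr <- simulate_ddm(10000, a = 0.2, v = 0.2, ter = 0.2)
  f1 <- fit_ddm(tr)
  f2 <- fit_ddm(tr, start = c(f1$a, f1$v, f1$ter))
  expect_gte(f2$loglik, f1$loglik - 1e-6)
  shifted <- tr
  shifted$rt <- shifted$rt + 0.05
  f3 <- fit_ddm(shifted)
  expect_lt(abs(f3$ter - (f1$ter + 0.05)), 0.002)
})

test_that("degenerate trial sets are flagged, not silently accepted", {
  set.seed(107)
  tr <- simulate_ddm(40, a = 0.2, v = 0.2, ter = 0.2)
  f <- fit_ddm(tr)
  expect_true("fewer than 50 trials" %in% f$flags)
  one_sided <- tibble::tibble(rt = tr$rt, response = "upper")
  f2 <- fit_ddm(one_sided)
  expect_true(any(grepl("one boundary", f2$flags)))
  expect_error(fit_ddm(tibble::tibble(rt = c(-1, 0.5), response = c("upper", "lower"))))
})
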