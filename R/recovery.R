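#' Run a parameter-recovery simulation with and without technical noise
#'
#' The core Monte-Carlo loop of the package. Each iteration (i) draws a
#' parameter set from the uniform prior, (ii) generates one data set of
#' `n_trials` reaction times from the model, (iii) constructs a noisy copy
#' of that same data set by adding an independent U(low, high) ms delay to
#' every trial, and (iv) maximum-likelihood fits the model separately to the
#' clean and the noisy version. The clean and noisy fits always refer to the
#' same underlying clean draw — the noisy set is never an independent
#' redraw. Defaults reproduce the study conditions: ex-Gaussian with 80
#' trials, or diffusion with 100 trials, priors as in [exgauss_prior()] /
#' [ddm_prior()], U(10, 100) ms noise, 500 iterations.
#'
#' Reproducibility: the master `seed` deterministically spawns one substream
#' seed per iteration, so iterations are independent and could be run
#' concurrently with results identical to serial execution.
#'
#' @param model `"exgauss"` or `"ddm"`.
#' @param iterations Number of Monte-Carlo iterations.
#' @param n_trials Trials per simulated data set; defaults to 80
#'   (ex-Gaussian) or 100 (diffusion).
#' @param prior A [exgauss_prior()] / [ddm_prior()]; defaults to the study
#'   priors for the chosen model.
#' @param noise A [noise_spec()]; U(10, 100) ms by default.
#' @param seed Master seed (integer) for the whole run; `NULL` continues the
#'   current RNG stream.
#' @param dt Euler step for diffusion simulation (seconds).
#' @return A tibble of class `recovery_records` in long format: one row per
#'   iteration x parameter with columns `iteration`, `parameter`, `true`,
#'   `clean`, `noisy`, `clean_converged`, `noisy_converged`.
#' @examples
#' rec <- run_recovery("exgauss", iterations = 20, seed = 1)
#' regress_noisy_on_clean(rec)
#' @export
run_recovery <- function(model = c("exgauss", "ddm"),
                         iterations = 500,
                         n_trials = NULL,
                         prior = NULL,
                         noise = noise_spec(10, 100),
                         seed = NULL,
                         dt = 5e-4) {
  model <- match.arg(model)
  stopifnot(iterations >= 1)
  if (is.null(n_trials)) n_trials <- if (model == "exgauss") 80 else 100
  if (is.null(prior)) {
    prior <- if (model == "exgauss") exgauss_prior() else ddm_prior()
  }
  seeds <- derive_seeds(seed, iterations)
  pars <- if (model == "exgauss") c("mu", "sigma", "tau") else c("a", "v", "ter")

  out <- purrr::map_dfr(seq_len(iterations), function(i) {
    set.seed(seeds[i])
    params <- sample_params(prior)
    if (model == "exgauss") {
      clean <- generate_exgauss_trials(params, n_trials)
      noisy <- add_noise(clean, noise)
      fc <- fit_exgauss(clean)
      fn <- fit_exgauss(noisy)
    } else {
      clean <- simulate_ddm(n_trials,
        a = params$a, v = params$v, ter = params$ter, dt = dt
      )
      noisy <- add_noise(clean, noise)
      fc <- fit_ddm(clean)
      fn <- fit_ddm(noisy)
    }
    tibble::tibble(
      iteration = i,
      parameter = pars,
      true = unlist(params[pars], use.names = FALSE),
      clean = unlist(unclass(fc)[pars], use.names = FALSE),
      noisy = unlist(unclass(fn)[pars], use.names = FALSE),
      clean_converged = fc$converged,
      noisy_converged = fn$converged
    )
  })
  class(out) <- c("recovery_records", class(out))
  attr(out, "model") <- model
  attr(out, "noise") <- noise
  attr(out, "n_trials") <- n_trials
  attr(out, "seed") <- seed
  out
}

# OLS of y on x with t-based 95% CIs; the slope is additionally tested
# against the null value 1 (noise-free recovery), and against 0 for
# transparency. Records with a failed fit in either version are dropped
# pairwise, with the count reported.
regress_pair <- function(df, xcol, ycol, conf = 0.95) {
  ok <- df$clean_converged & df$noisy_converged
  n_excluded <- sum(!ok)
  df <- df[ok, ]
  if (nrow(df) < 3) abort("Need at least 3 usable records.")
  x <- df[[xcol]]
  y <- df[[ycol]]
  if (sd(x) == 0) abort("Degenerate predictor: zero variance.")
  fit <- lm(y ~ x)
  est <- coef(fit)
  # suppressWarnings: an exact fit (identity noise) triggers the harmless
  # "essentially perfect fit" warning inside summary.lm
  se <- sqrt(diag(suppressWarnings(vcov(fit))))
  ci <- suppressWarnings(confint(fit, level = conf))
  dfree <- fit$df.residual
  p_int <- 2 * pt(-abs(est[1] / se[1]), dfree)
  p_slope1 <- 2 * pt(-abs((est[2] - 1) / se[2]), dfree)
  p_slope0 <- 2 * pt(-abs(est[2] / se[2]), dfree)
  # numerical guard: an exact fit (e.g. identity noise) leaves roundoff-sized
  # coefficients with roundoff-sized CIs; those must not read as significant
  eps_int <- 1e-8 * max(1, abs(mean(y)))
  eps_slope <- 1e-8
  tibble::tibble(
    n_used = nrow(df),
    n_excluded = n_excluded,
    intercept = unname(est[1]),
    intercept_ci_low = ci[1, 1],
    intercept_ci_high = ci[1, 2],
    intercept_p = unname(p_int),
    intercept_sig = ci[1, 1] > eps_int | ci[1, 2] < -eps_int,
    slope = unname(est[2]),
    slope_ci_low = ci[2, 1],
    slope_ci_high = ci[2, 2],
    slope_p_vs1 = unname(p_slope1),
    slope_p_vs0 = unname(p_slope0),
    slope_sig = ci[2, 1] > 1 + eps_slope | ci[2, 2] < 1 - eps_slope
  )
}

#' Quantify noise-induced bias by regression of noisy on clean estimates
#'
#' For each model parameter, ordinary least squares of the noisy-data
#' estimates on the clean-data estimates across iterations. Under no noise
#' effect the line is the identity, so the intercept is flagged significant
#' when its 95% CI excludes 0 and the slope when its 95% CI excludes 1
#' (p-values for the slope are reported against both null values 1 and 0).
#' Iterations with a failed fit in either version are dropped pairwise and
#' counted in `n_excluded`.
#'
#' @param records A `recovery_records` tibble from [run_recovery()].
#' @param parameter Optional subset of parameter names.
#' @param conf Confidence level for the intervals.
#' @return A tibble of class `bias_regression`, one row per parameter.
#' @export
regress_noisy_on_clean <- function(records, parameter = NULL, conf = 0.95) {
  regress_records(records, "clean", "noisy", parameter, conf)
}

#' @description `regress_clean_on_true()` applies the same regression to the
#'   clean-data estimates against the generating (veridical) values — the
#'   recovery-quality check; with an unbiased fitter its CIs cover 0 and 1.
#' @rdname regress_noisy_on_clean
#' @export
regress_clean_on_true <- function(records, parameter = NULL, conf = 0.95) {
  regress_records(records, "true", "clean", parameter, conf)
}

regress_records <- function(records, xcol, ycol, parameter = NULL,
                            conf = 0.95) {
  stopifnot(inherits(records, "recovery_records") || is.data.frame(records))
  if (!is.null(parameter)) {
    records <- dplyr::filter(records, .data$parameter %in% !!parameter)
  }
  out <- records |>
    dplyr::group_by(.data$parameter) |>
    dplyr::group_modify(~ regress_pair(.x, xcol, ycol, conf)) |>
    dplyr::ungroup()
  class(out) <- c("bias_regression", class(out))
  out
}

#' Reshape a bias regression into a coefficient table
#'
#' Long format mirroring the usual reporting layout: one row per
#' parameter x term (intercept/slope) with the estimate, 95% CI bounds,
#' the p-value against the term's null (0 for intercepts, 1 for slopes) and
#' the significance flag.
#'
#' @param reg A `bias_regression` tibble.
#' @return A tibble with columns `parameter`, `term`, `estimate`, `ci_low`,
#'   `ci_high`, `p`, `significant`.
#' @export
bias_summary_table <- function(reg) {
  dplyr::bind_rows(
    dplyr::transmute(reg, .data$parameter,
      term = "intercept",
      estimate = .data$intercept, ci_low = .data$intercept_ci_low,
      ci_high = .data$intercept_ci_high, p = .data$intercept_p,
      significant = .data$intercept_sig
    ),
    dplyr::transmute(reg, .data$parameter,
      term = "slope",
      estimate = .data$slope, ci_low = .data$slope_ci_low,
      ci_high = .data$slope_ci_high, p = .data$slope_p_vs1,
      significant = .data$slope_sig
    )
  ) |>
    dplyr::arrange(.data$parameter, .data$term)
}

#' Sweep the upper bound of the noise distribution
#'
#' Repeats the ex-Gaussian recovery simulation for a series of noise
#' distributions U(`noise_low`, `b`) with `b` taken from `upper_bounds`
#' (study default: 50 to 200 ms in steps of 10, 1000 iterations per level),
#' returning the per-parameter bias regression at every level. With
#' `share_clean = TRUE` all levels reuse the same substream seeds, hence the
#' same clean data sets; the default redraws everything independently per
#' level.
#'
#' @param upper_bounds Noise upper bounds (ms), all above `noise_low`.
#' @param iterations Iterations per noise level.
#' @param n_trials Trials per data set.
#' @param noise_low Fixed lower bound of the noise distribution (ms).
#' @param prior Parameter prior.
#' @param seed Master seed for the sweep.
#' @param share_clean Reuse identical clean data across levels.
#' @return A tibble of class `noise_sweep`: the [regress_noisy_on_clean()]
#'   columns plus `noise_high`.
#' @export
run_noise_sweep <- function(upper_bounds = seq(50, 200, by = 10),
                            iterations = 1000,
                            n_trials = 80,
                            noise_low = 10,
                            prior = exgauss_prior(),
                            seed = NULL,
                            share_clean = FALSE) {
  if (any(upper_bounds <= noise_low)) {
    abort("All `upper_bounds` must exceed `noise_low`.")
  }
  level_seeds <- derive_seeds(seed, length(upper_bounds))
  if (share_clean) level_seeds <- rep(level_seeds[1], length(upper_bounds))
  out <- purrr::map2_dfr(upper_bounds, level_seeds, function(b, s) {
    rec <- run_recovery("exgauss",
      iterations = iterations, n_trials = n_trials,
      prior = prior, noise = noise_spec(noise_low, b), seed = s
    )
    dplyr::mutate(regress_noisy_on_clean(rec), noise_high = b, .before = 1)
  })
  class(out) <- c("noise_sweep", class(out))
  attr(out, "seed") <- seed
  out
}

#' Weighted least-squares trend across noise levels
#'
#' Summarises how a regression coefficient changes with the noise upper
#' bound: weighted least squares of the per-level estimates on the noise
#' level, each level weighted inversely to the width of its confidence
#' interval (the proportionality constant does not affect the fit).
#'
#' @param data A data frame, e.g. a filtered [run_noise_sweep()] result.
#' @param level,estimate,ci_width Columns (tidy-eval) holding the noise
#'   level, the coefficient estimate, and its CI width; all CI widths must
#'   be positive.
#' @return A one-row tibble with `intercept`, `slope` and their standard
#'   errors.
#' @examples
#' d <- tibble::tibble(b = c(50, 100, 150), est = c(30, 56, 80), w = c(9, 11, 13))
#' meta_regression_wls(d, b, est, w)
#' @export
meta_regression_wls <- function(data, level, estimate, ci_width) {
  df <- tibble::tibble(
    level = dplyr::pull(data, {{ level }}),
    estimate = dplyr::pull(data, {{ estimate }}),
    ci_width = dplyr::pull(data, {{ ci_width }})
  )
  if (nrow(df) < 3) abort("Need at least 3 levels.")
  if (any(df$ci_width <= 0)) abort("CI widths must be strictly positive.")
  df$w <- 1 / df$ci_width
  fit <- lm(estimate ~ level, data = df, weights = w)
  se <- sqrt(diag(vcov(fit)))
  tibble::tibble(
    intercept = unname(coef(fit)[1]),
    slope = unname(coef(fit)[2]),
    intercept_se = unname(se[1]),
    slope_se = unname(se[2])
  )
}
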