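#' Histogram of reaction times with a fitted ex-Gaussian curve
#'
#' @param x Numeric vector of reaction times (ms).
#' @param fit Optional `exgauss_fit`; fitted to `x` when omitted.
#' @param binwidth Histogram bin width (ms).
#' @return A ggplot object.
#' @export
plot_exgauss_fit <- function(x, fit = NULL, binwidth = 25) {
  if (is.null(fit)) fit <- fit_exgauss(x)
  grid <- seq(min(x) - 2 * binwidth, max(x) + 2 * binwidth, length.out = 400)
  curve_df <- tibble::tibble(
    rt = grid,
    density = dexgauss(grid, fit$mu, fit$sigma, fit$tau)
  )
  ggplot2::ggplot(tibble::tibble(rt = x), ggplot2::aes(x = .data$rt)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density)),
      binwidth = binwidth, fill = "grey80", colour = "grey40"
    ) +
    ggplot2::geom_line(
      data = curve_df, ggplot2::aes(y = .data$density),
      linewidth = 1
    ) +
    ggplot2::labs(x = "Reaction time (ms)", y = "Density")
}

#' Scatter plots of a recovery simulation
#'
#' One panel per model parameter; the dashed diagonal is the identity line
#' expected in the absence of noise effects, the solid line the OLS fit.
#' `x`/`y` select which pair of value columns to compare: clean vs noisy
#' estimates (the bias view, default) or veridical vs clean estimates (the
#' recovery-quality view).
#'
#' @param object A `recovery_records` tibble.
#' @param x,y Column names among `"true"`, `"clean"`, `"noisy"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_records <- function(object, x = "clean", y = "noisy", ...) {
  df <- dplyr::filter(object, .data$clean_converged & .data$noisy_converged)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
      linewidth = 0.7, colour = "grey30") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = paste(x, "estimate"), y = paste(y, "estimate"))
}

#' Coefficients of a noise-bound sweep with WLS trend lines
#'
#' Per-parameter, per-term (intercept/slope) panels of the bias-regression
#' coefficients against the upper bound of the noise distribution, with
#' their 95% CIs and the [meta_regression_wls()] trend line (weights
#' inversely proportional to the CI width).
#'
#' @param object A `noise_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.noise_sweep <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(object, .data$noise_high, .data$parameter,
      term = "intercept", estimate = .data$intercept,
      ci_low = .data$intercept_ci_low, ci_high = .data$intercept_ci_high
    ),
    dplyr::transmute(object, .data$noise_high, .data$parameter,
      term = "slope", estimate = .data$slope,
      ci_low = .data$slope_ci_low, ci_high = .data$slope_ci_high
    )
  ) |>
    dplyr::mutate(ci_width = .data$ci_high - .data$ci_low)
  trend <- long |>
    dplyr::group_by(.data$parameter, .data$term) |>
    dplyr::group_modify(
      ~ meta_regression_wls(.x, noise_high, estimate, ci_width)
    ) |>
    dplyr::ungroup()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$noise_high, y = .data$estimate)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      size = 0.3
    ) +
    ggplot2::geom_abline(
      data = trend,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope),
      colour = "red"
    ) +
    ggplot2::facet_wrap(parameter ~ term, scales = "free_y") +
    ggplot2::labs(x = "Noise upper bound (ms)", y = "Coefficient")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
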