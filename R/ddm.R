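#' Simulate trials from a two-boundary Wiener diffusion process
#'
#' Generates reaction times and choices from the Ratcliff diffusion model
#' restricted to its four main parameters: evidence starts at `z`, drifts at
#' rate `v` with within-trial noise `s`, and is absorbed at 0 (lower
#' boundary) or `a` (upper boundary); the observed RT is the first-passage
#' time plus the non-decision time `ter`. Across-trial variabilities
#' (eta, s_z, s_t) are fixed at zero throughout the package. Each trial is an
#' Euler-Maruyama walk with time step `dt` (implemented in C++, driven by R's
#' RNG); a walk not absorbed within `max_time` is discarded and resampled,
#' with the number of resampled walks reported as an attribute.
#'
#' @param n Number of trials.
#' @param a Boundary separation (evidence units).
#' @param v Drift rate (evidence units per second).
#' @param ter Non-decision time (seconds).
#' @param z Starting point; defaults to `a/2` (the unbiased constraint used
#'   in all package pipelines). Must satisfy `0 < z < a`.
#' @param s Within-trial diffusion coefficient; fixed scaling constant,
#'   conventionally 0.1.
#' @param dt Euler step (seconds). Steps coarser than 0.005 s trigger a
#'   warning: the first-passage discretisation bias grows with `sqrt(dt)`.
#' @param max_time Hard cap (seconds) on a single walk before resampling.
#'
#' @return A tibble of class `ddm_trials` with columns `rt` (seconds) and
#'   `response` (`"upper"` or `"lower"`); attribute `resampled` counts
#'   discarded walks, attribute `params` records the generating parameters.
#' @examples
#' set.seed(1)
#' simulate_ddm(5, a = 0.2, v = 0.2, ter = 0.2)
#' @export
simulate_ddm <- function(n, a, v, ter, z = a / 2, s = 0.1,
                         dt = 5e-4, max_time = 60) {
  check_ddm_params(a, v, ter, z, s)
  stopifnot(n >= 1, dt > 0)
  if (dt > 0.005) {
    warn("`dt` > 0.005 s: first-passage times will be visibly biased.")
  }
  sim <- simulate_ddm_cpp(as.integer(n), a, v, z, s, ter, dt, max_time)
  out <- tibble::tibble(
    rt = sim$rt,
    response = ifelse(sim$upper == 1L, "upper", "lower")
  )
  class(out) <- c("ddm_trials", class(out))
  attr(out, "resampled") <- sim$resampled
  attr(out, "params") <- list(a = a, v = v, ter = ter, z = z, s = s)
  out
}

check_ddm_params <- function(a, v, ter, z, s) {
  if (!all(is.finite(c(a, v, ter, z, s)))) {
    abort("Diffusion parameters must be finite.")
  }
  if (a <= 0 || s <= 0 || ter < 0 || z <= 0 || z >= a) {
    abort("Require a > 0, s > 0, ter >= 0 and 0 < z < a.")
  }
  invisible(TRUE)
}

#' Closed-form absorption probability at a boundary
#'
#' Probability that the diffusion started at `z` is absorbed at the stated
#' boundary (gambler's-ruin formula); `1/2` at the upper boundary when
#' `v = 0, z = a/2`.
#'
#' @inheritParams simulate_ddm
#' @param boundary `"upper"` or `"lower"`.
#' @return A probability.
#' @export
ddm_absorption_prob <- function(a, v, z = a / 2, s = 0.1,
                                boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  check_ddm_params(a, v, 0, z, s)
  p_up <- if (abs(v) < 1e-12) {
    z / a
  } else {
    (1 - exp(-2 * v * z / s^2)) / (1 - exp(-2 * v * a / s^2))
  }
  if (boundary == "upper") p_up else 1 - p_up
}

# Unit-diffusion first-passage density at the LOWER boundary for a process on
# (0, a') started at w * a', expressed in normalised time u = t / a'^2.
# Small-time and large-time series representations, each truncated by the
# standard error bound so the absolute truncation error is below `eps`;
# the cheaper representation is selected per evaluation point.
wfpt_f0 <- function(u, w, eps = 1e-10, representation = c("auto", "small", "large")) {
  representation <- match.arg(representation)
  stopifnot(all(u > 0), w > 0, w < 1)
  ks <- ifelse(2 * eps * sqrt(2 * pi * u) < 1,
    2 + sqrt(pmax(-2 * u * base::log(2 * eps * sqrt(2 * pi * u)), 0)),
    2
  )
  ks <- pmax(ks, sqrt(u) + 1)
  kl <- ifelse(pi * u * eps < 1,
    sqrt(pmax(-2 * base::log(pi * u * eps), 0) / (pi^2 * u)),
    1 / (pi * sqrt(u))
  )
  kl <- pmax(kl, 1 / (pi * sqrt(u)))
  use_small <- switch(representation,
    auto = ks < kl,
    small = rep(TRUE, length(u)),
    large = rep(FALSE, length(u))
  )
  out <- numeric(length(u))
  if (any(use_small)) {
    us <- u[use_small]
    K <- ceiling(max(ks[use_small]))
    k <- seq(-floor((K - 1) / 2), ceiling((K - 1) / 2))
    terms <- outer(us, k, function(uu, kk) {
      (w + 2 * kk) * exp(-(w + 2 * kk)^2 / (2 * uu))
    })
    out[use_small] <- rowSums(terms) / sqrt(2 * pi * us^3)
  }
  if (any(!use_small)) {
    ul <- u[!use_small]
    K <- ceiling(max(kl[!use_small]))
    k <- seq_len(K)
    terms <- outer(ul, k, function(uu, kk) {
      kk * exp(-kk^2 * pi^2 * uu / 2) * sin(kk * pi * w)
    })
    out[!use_small] <- pi * rowSums(terms)
  }
  pmax(out, 0)
}

#' Defective first-passage-time density of the Wiener diffusion
#'
#' Density of absorption at the stated boundary at decision time `t`
#' (seconds, excluding non-decision time). The two defective densities
#' jointly integrate to 1 over `t > 0`. Evaluation rescales to a
#' unit-diffusion process (`a/s`, `v/s`) and uses the small-time or
#' large-time series representation, whichever needs fewer terms at each
#' `t`, truncated so the absolute series error is below `eps`.
#'
#' @param t Decision times (seconds). Non-positive values return 0.
#' @inheritParams simulate_ddm
#' @inheritParams ddm_absorption_prob
#' @param eps Absolute truncation error bound for the series.
#' @param representation Force the `"small"`- or `"large"`-time series
#'   (mainly for numerical cross-checks); default `"auto"` selects per point.
#' @return Vector of defective densities (1/s).
#' @examples
#' ddm_fpt_density(0.5, a = 0.2, v = 0.2, boundary = "upper")
#' @export
ddm_fpt_density <- function(t, a, v, z = a / 2, s = 0.1,
                            boundary = c("upper", "lower"),
                            eps = 1e-10,
                            representation = c("auto", "small", "large")) {
  boundary <- match.arg(boundary)
  representation <- match.arg(representation)
  check_ddm_params(a, v, 0, z, s)
  out <- numeric(length(t))
  pos <- is.finite(t) & t > 0
  if (!any(pos)) {
    return(out)
  }
  tp <- t[pos]
  # rescale to unit diffusion; for the upper boundary reflect the process
  an <- a / s
  vn <- v / s
  w <- z / a
  if (boundary == "upper") {
    vn <- -vn
    w <- 1 - w
  }
  u <- tp / an^2
  f0 <- wfpt_f0(u, w, eps = eps, representation = representation)
  out[pos] <- f0 / an^2 * exp(-vn * an * w - vn^2 * tp / 2)
  out
}

#' Defective first-passage-time distribution function
#'
#' Probability that the process has been absorbed at the stated boundary by
#' decision time `t`. Obtained by integrating the large-time series of the
#' defective density term by term, which turns each mode into a closed-form
#' exponential tail; the series is truncated once the term bound falls below
#' `eps`, and times at which even the fastest-passage probability is below
#' machine noise return 0 outright. As `t` grows the value approaches
#' [ddm_absorption_prob()]; summed over both boundaries the limit is 1.
#'
#' @inheritParams ddm_fpt_density
#' @return Vector of defective cumulative probabilities.
#' @export
ddm_fpt_cdf <- function(t, a, v, z = a / 2, s = 0.1,
                        boundary = c("upper", "lower"), eps = 1e-10) {
  boundary <- match.arg(boundary)
  check_ddm_params(a, v, 0, z, s)
  an <- a / s
  vn <- v / s
  w <- z / a
  if (boundary == "upper") {
    vn <- -vn
    w <- 1 - w
  }
  p_all <- ddm_absorption_prob(a, v, z, s, boundary)
  out <- numeric(length(t))
  # below this time even reaching the nearer boundary has probability < 1e-12
  t_floor <- (an * min(w, 1 - w) / 7.1)^2
  pos <- is.finite(t) & t > t_floor
  if (!any(pos)) {
    return(out)
  }
  tp <- t[pos]
  u_min <- min(tp) / an^2
  K <- min(ceiling(sqrt(2 * -base::log(eps) / (pi^2 * u_min))) + 2, 500)
  k <- seq_len(K)
  lam <- (vn^2 + k^2 * pi^2 / an^2) / 2
  coefk <- pi * k * sin(k * pi * w) * exp(-vn * an * w) / an^2
  tails <- outer(tp, k, function(tt, kk) exp(-lam[kk] * tt)) %*% (coefk / lam)
  out[pos] <- pmin(pmax(p_all - drop(tails), 0), 1)
  out
}

#' Constrained fit of the diffusion model
#'
#' Fits boundary separation `a`, drift rate `v` and non-decision time `ter`
#' to reaction times and responses under the constraints `z = a/2` and zero
#' across-trial variabilities, using one of two objectives:
#'
#' * `method = "quantile"` (default): multinomial likelihood on RT
#'   quantiles, the approach of the standard diffusion-fitting toolboxes.
#'   For each boundary with at least 10 responses, the observed
#'   0.1/0.3/0.5/0.7/0.9 quantiles cut the time axis into six bins; the
#'   model-implied defective probabilities of those bins
#'   ([ddm_fpt_cdf()] differences) enter a multinomial log-likelihood with
#'   the observed bin counts. A boundary with fewer than 10 responses
#'   contributes only its total absorption probability.
#' * `method = "ml"`: continuous maximum likelihood, summing log defective
#'   densities ([ddm_fpt_density()]) evaluated at `rt - ter`. Trials with
#'   `rt <= ter` during the search contribute a smooth penalty
#'   `-1e6 * (ter - rt + 1e-4)` instead of `-Inf`, which repels the simplex
#'   from infeasible `ter` without cliffs.
#'
#' Both objectives are maximised by a Nelder-Mead simplex over
#' (`log a`, `v`, `log ter`). The start is data-dependent, computed by the
#' EZ-diffusion moment equations (accuracy and correct-RT mean/variance give
#' closed-form a, v, Ter), clamped to the feasible region, with the fallback
#' `a = 0.2`, `v = 0.2`, `ter = 0.9 * min(rt)` when the moment solution is
#' undefined; this is the initialization strategy of the standard
#' diffusion-fitting toolboxes. A non-converged optimisation is retried once
#' from a deterministically perturbed start and otherwise flagged. The
#' quantile objective and EZ starts are the defaults because the
#' noisy-versus-clean regression structure of the recovery pipelines is a
#' property of the fitter, and this toolbox-style fit — unlike trial-level
#' ML from a fixed start — reproduces the behaviour the standard toolboxes
#' show at the study's 100-trial scale (see the package vignette).
#'
#' @param data A data frame with columns `rt` (seconds) and `response`
#'   (`"upper"`/`"lower"`, or 1/0), e.g. from [simulate_ddm()].
#' @param s Diffusion coefficient (fixed scaling constant).
#' @param method Fitting objective, see Details.
#' @param probs Quantiles used by the `"quantile"` objective.
#' @param start Optional `c(a, v, ter)` start override (e.g. for refits).
#' @return An object of class `ddm_fit`: list with `a`, `v`, `ter`,
#'   `loglik`, `converged`, `restarts`, `n`, and `flags` (character vector
#'   noting fewer than 50 trials or single-boundary data).
#' @seealso [tidy.ddm_fit()], [glance.ddm_fit()]
#' @examples
#' set.seed(1)
#' trials <- simulate_ddm(300, a = 0.2, v = 0.2, ter = 0.2)
#' fit_ddm(trials)
#' @export
fit_ddm <- function(data, s = 0.1, method = c("quantile", "ml"),
                    probs = c(0.1, 0.3, 0.5, 0.7, 0.9), start = NULL) {
  method <- match.arg(method)
  rt <- data$rt
  response <- data$response
  if (is.numeric(response)) response <- ifelse(response == 1, "upper", "lower")
  if (length(rt) == 0 || any(!is.finite(rt)) || any(rt <= 0)) {
    abort("`rt` must be non-empty, finite and positive (seconds).")
  }
  if (!all(response %in% c("upper", "lower"))) {
    abort("`response` must be 'upper'/'lower' (or 1/0).")
  }
  up <- response == "upper"
  flags <- character()
  if (length(rt) < 50) flags <- c(flags, "fewer than 50 trials")
  if (all(up) || all(!up)) flags <- c(flags, "all responses at one boundary")

  negll_ml <- function(th) {
    a <- exp(th[1])
    v <- th[2]
    ter <- exp(th[3])
    dtm <- rt - ter
    ok <- dtm > 0
    ll <- numeric(length(rt))
    ll[!ok] <- -1e6 * (ter - rt[!ok] + 1e-4)
    if (any(ok & up)) {
      ll[ok & up] <- base::log(pmax(
        ddm_fpt_density(dtm[ok & up], a, v, a / 2, s, "upper"), 1e-300
      ))
    }
    if (any(ok & !up)) {
      ll[ok & !up] <- base::log(pmax(
        ddm_fpt_density(dtm[ok & !up], a, v, a / 2, s, "lower"), 1e-300
      ))
    }
    val <- -sum(ll)
    if (!is.finite(val)) 1e12 else val
  }

  qdat <- lapply(c(TRUE, FALSE), function(b) {
    rb <- rt[up == b]
    list(
      n = length(rb),
      boundary = if (b) "upper" else "lower",
      q = if (length(rb) >= 10) {
        stats::quantile(rb, probs, names = FALSE)
      },
      counts = length(rb) * diff(c(0, probs, 1))
    )
  })
  negll_q <- function(th) {
    a <- exp(th[1])
    v <- th[2]
    ter <- exp(th[3])
    ll <- 0
    for (side in qdat) {
      if (side$n == 0) next
      pb <- ddm_absorption_prob(a, v, a / 2, s, side$boundary)
      if (is.null(side$q)) {
        ll <- ll + side$n * base::log(max(pb, 1e-10))
      } else {
        fq <- ddm_fpt_cdf(side$q - ter, a, v, a / 2, s, side$boundary)
        pj <- diff(c(0, fq, pb))
        ll <- ll + sum(side$counts * base::log(pmax(pj, 1e-10)))
      }
    }
    if (!is.finite(ll)) 1e12 else -ll
  }
  negll <- if (method == "quantile") negll_q else negll_ml

  if (is.null(start)) {
    start <- ez_start(rt, up, s)
    if (!all(is.finite(start)) || start[1] <= 0 || start[3] <= 0) {
      start <- c(0.2, 0.2, 0.9 * min(rt))
    }
    start[1] <- min(max(start[1], 0.05), 1)
    start[3] <- max(min(start[3], 0.95 * min(rt)), 1e-3)
  }
  th0 <- c(base::log(start[1]), start[2], base::log(start[3]))
  opt <- optim(th0, negll,
    method = "Nelder-Mead",
    control = list(maxit = 2000, reltol = 1e-10)
  )
  restarts <- 0L
  if (opt$convergence != 0) {
    opt2 <- optim(opt$par * c(1.1, 0.9, 1.1), negll,
      method = "Nelder-Mead",
      control = list(maxit = 2000, reltol = 1e-10)
    )
    restarts <- 1L
    if (opt2$value <= opt$value) opt <- opt2
  }
  structure(
    list(
      a = exp(opt$par[1]),
      v = opt$par[2],
      ter = exp(opt$par[3]),
      loglik = -opt$value,
      converged = opt$convergence == 0,
      restarts = restarts,
      n = length(rt),
      method = method,
      flags = flags
    ),
    class = "ddm_fit"
  )
}

# EZ-diffusion closed-form moment estimates (accuracy, mean and variance of
# upper-boundary RTs), used as data-dependent starting values.
ez_start <- function(rt, up, s = 0.1) {
  n <- length(rt)
  p <- mean(up)
  p <- min(max(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  if (abs(p - 0.5) < 1 / (2 * n)) p <- 0.5 + 1 / (2 * n)
  L <- stats::qlogis(p)
  vrt <- if (sum(up) >= 2) var(rt[up]) else var(rt)
  if (!is.finite(vrt) || vrt <= 0) {
    return(c(NA_real_, NA_real_, NA_real_))
  }
  x <- L * (L * p^2 - L * p + p - 0.5) / vrt
  v <- sign(p - 0.5) * s * abs(x)^(1 / 4)
  a <- s^2 * L / v
  mdt <- (a / (2 * v)) * (1 - exp(-v * a / s^2)) / (1 + exp(-v * a / s^2))
  ter <- mean(if (sum(up) >= 1) rt[up] else rt) - mdt
  c(a, v, ter)
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("Diffusion-model ML fit (z = a/2, variabilities 0; n =", x$n, ")\n")
  cat(sprintf(
    "  a = %.4f  v = %.4f  Ter = %.4f\n  logLik = %.3f  converged = %s\n",
    x$a, x$v, x$ter, x$loglik, x$converged
  ))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Tidy a diffusion-model fit
#'
#' @param x A `ddm_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per free parameter (`term`, `estimate`).
#' @export
tidy.ddm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "v", "ter"),
    estimate = c(x$a, x$v, x$ter)
  )
}

#' One-row summary of a diffusion-model fit
#'
#' @param x A `ddm_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `logLik`, `converged`, `restarts`, `nobs`,
#'   `flagged`.
#' @export
glance.ddm_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    converged = x$converged,
    restarts = x$restarts,
    nobs = x$n,
    flagged = length(x$flags) > 0
  )
}
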