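#' Uniform parameter priors
#'
#' A prior is a named list of `c(low, high)` uniform bounds, one per model
#' parameter, in the parameter's native units. `exgauss_prior()` and
#' `ddm_prior()` return the study defaults: mu ~ U(450, 550) ms,
#' sigma ~ U(25, 75) ms, tau ~ U(50, 150) ms for the ex-Gaussian, and
#' a, v, ter each ~ U(0.15, 0.25) for the diffusion model (with the starting
#' point tied to `a/2` at draw time, never drawn).
#'
#' @param mu,sigma,tau,a,v,ter Length-2 numeric vectors `c(low, high)`.
#' @return A named list of bounds with class `prior_spec`.
#' @examples
#' exgauss_prior()
#' ddm_prior(v = c(0.1, 0.3))
#' @export
exgauss_prior <- function(mu = c(450, 550), sigma = c(25, 75),
                          tau = c(50, 150)) {
  new_prior(list(mu = mu, sigma = sigma, tau = tau))
}

#' @rdname exgauss_prior
#' @export
ddm_prior <- function(a = c(0.15, 0.25), v = c(0.15, 0.25),
                      ter = c(0.15, 0.25)) {
  new_prior(list(a = a, v = v, ter = ter))
}

new_prior <- function(bounds) {
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] > b[2]) {
      abort(paste0("Prior for `", nm, "` must be c(low, high) with low <= high."))
    }
  }
  structure(bounds, class = "prior_spec")
}

#' Additive technical-noise specification
#'
#' Bounds (ms) of the uniform distribution from which a per-trial recording
#' delay is drawn. The study default, U(10, 100) ms, models the latency
#' added between the true response and its recorded timestamp by input
#' devices, operating-system timers and browser timing functions.
#'
#' @param low,high Minimum and maximum added delay in ms; `0 <= low <= high`.
#' @return A list with elements `low` and `high`, class `noise_spec`.
#' @export
noise_spec <- function(low = 10, high = 100) {
  if (!all(is.finite(c(low, high))) || low < 0 || low > high) {
    abort("Require 0 <= low <= high.")
  }
  structure(list(low = low, high = high), class = "noise_spec")
}

#' Draw one parameter set from a uniform prior
#'
#' Each parameter is drawn independently and uniformly within its bounds
#' (degenerate bounds give that constant). For diffusion priors (those
#' containing `a`), the unbiased starting point `z = a/2` is appended
#' exactly, never drawn.
#'
#' @param prior A `prior_spec`, e.g. [exgauss_prior()] or [ddm_prior()].
#' @return A one-row tibble with one column per parameter.
#' @examples
#' set.seed(1)
#' sample_params(ddm_prior()) # z is exactly a/2
#' @export
sample_params <- function(prior) {
  stopifnot(inherits(prior, "prior_spec"))
  draws <- purrr::map(prior, function(b) runif(1, b[1], b[2]))
  out <- tibble::as_tibble(draws)
  if ("a" %in% names(out)) out$z <- out$a / 2
  out
}

#' Generate ex-Gaussian trials for one simulated condition
#'
#' Thin wrapper around [rexgauss()] taking a parameter row (as returned by
#' [sample_params()]) or a named list with `mu`, `sigma`, `tau`.
#'
#' @param params Named list / one-row data frame with `mu`, `sigma`, `tau`.
#' @param n Number of trials.
#' @return Numeric vector of `n` reaction times (ms).
#' @export
generate_exgauss_trials <- function(params, n) {
  stopifnot(n >= 1)
  rexgauss(n, params$mu, params$sigma, params$tau)
}

#' Add uniform technical noise to reaction times
#'
#' Adds an independent delay `u_i ~ U(low, high)` to every reaction time,
#' preserving trial order and length: the noisy data set is always the same
#' underlying clean draw plus delays, never an independent redraw. For
#' diffusion trial tables (seconds), the ms-scale delay is added as
#' `u_i / 1000` seconds and the response labels are untouched — a recording
#' delay shifts timestamps, not choices.
#'
#' @param x Numeric vector of RTs in ms, or a data frame with an `rt` column
#'   in seconds (e.g. from [simulate_ddm()]).
#' @param noise A [noise_spec()].
#' @return Same shape as `x`, with noise added.
#' @examples
#' set.seed(1)
#' add_noise(c(400, 500, 600), noise_spec(10, 100))
#' @export
add_noise <- function(x, noise = noise_spec()) {
  stopifnot(inherits(noise, "noise_spec"))
  UseMethod("add_noise")
}

#' @export
add_noise.numeric <- function(x, noise = noise_spec()) {
  x + runif(length(x), noise$low, noise$high)
}

#' @export
add_noise.data.frame <- function(x, noise = noise_spec()) {
  x$rt <- x$rt + runif(nrow(x), noise$low, noise$high) / 1000
  x
}

# Per-iteration substream seeds derived from one master seed, so that
# iterations are independent, reproducible, and parallelisable with results
# identical to serial execution.
derive_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(2147483646L, n)
}
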