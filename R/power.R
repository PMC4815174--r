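#' Paired t-test with Cohen's d for a within-subject comparison
#'
#' Classical paired-samples t-test of `x` against `y`, with the t value
#' converted to a Cohen's d effect size using the paired-design relation
#' d = t / sqrt(n).
#'
#' @param x,y Equal-length vectors of per-participant estimates
#'   (experimental and control condition).
#' @return A one-row tibble with `n`, `t`, `df`, `p_value`, `d`.
#' @examples
#' set.seed(1)
#' paired_t_and_d(rnorm(30, 0.5), rnorm(30))
#' @export
paired_t_and_d <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("`x` and `y` must have equal length >= 2.")
  }
  if (sd(x - y) == 0) {
    abort("Zero within-pair variance: t is undefined.")
  }
  tt <- t.test(x, y, paired = TRUE)
  n <- length(x)
  tibble::tibble(
    n = n,
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    d = unname(tt$statistic) / sqrt(n)
  )
}

#' Power of the two-tailed paired t-test
#'
#' Exact power via the noncentral t distribution: with `n` pairs, effect
#' size d, and two-tailed level `alpha`, the test statistic has df = n - 1
#' and noncentrality d * sqrt(n); power is the probability that it exceeds
#' the central-t critical value in either tail.
#'
#' @param n Number of pairs (>= 2).
#' @param d Cohen's d for the paired design.
#' @param alpha Two-tailed significance level.
#' @return Power (probability of rejection).
#' @export
paired_t_power <- function(n, d, alpha = 0.05) {
  stopifnot(all(n >= 2))
  tc <- qt(1 - alpha / 2, n - 1)
  ncp <- d * sqrt(n)
  pt(tc, n - 1, ncp = ncp, lower.tail = FALSE) + pt(-tc, n - 1, ncp = ncp)
}

#' Smallest sample size reaching a target power
#'
#' Smallest integer number of pairs n >= 2 such that the two-tailed paired
#' t-test at level `alpha` attains at least the target power for effect
#' size d ([paired_t_power()]); never rounded down.
#'
#' @param d Cohen's d (> 0).
#' @param power Target power in (0, 1).
#' @param alpha Two-tailed significance level in (0, 1).
#' @param n_max Search cap.
#' @return An integer sample size.
#' @examples
#' required_n(0.31) # 84 pairs for 80% power at alpha = .05
#' @export
required_n <- function(d, power = 0.80, alpha = 0.05, n_max = 1e6) {
  if (!is.finite(d) || d <= 0) abort("`d` must be > 0.")
  stopifnot(power > 0, power < 1, alpha > 0, alpha < 1)
  if (paired_t_power(2, d, alpha) >= power) {
    return(2L)
  }
  # geometric bracket then binary search (power is increasing in n)
  hi <- 4
  while (paired_t_power(hi, d, alpha) < power) {
    hi <- hi * 2
    if (hi > n_max) abort("No n <= n_max reaches the target power.")
  }
  lo <- hi %/% 2
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (paired_t_power(mid, d, alpha) >= power) hi <- mid else lo <- mid
  }
  as.integer(hi)
}

# NA rather than an error when a Monte-Carlo d comes out non-positive
safe_required_n <- function(d, power, alpha) {
  if (!is.finite(d) || d <= 0) {
    return(NA_integer_)
  }
  required_n(d, power, alpha)
}

#' Simulate one participant's two-condition data, clean and noisy
#'
#' Draws 80-trial (by default) control data at the participant's base
#' parameters and experimental data at the same parameters with `effect` ms
#' added to the `target` parameter, then constructs noisy copies of both by
#' adding per-trial uniform delays. All four data sets are ML-fitted.
#'
#' @param params Base ex-Gaussian parameters (named list / one-row data
#'   frame with `mu`, `sigma`, `tau`).
#' @param target `"mu"`, `"sigma"` or `"tau"` — the parameter carrying the
#'   experimental effect.
#' @param effect Effect size added to `target` (ms, >= 0).
#' @param n_trials Trials per condition.
#' @param noise A [noise_spec()].
#' @return A tibble with four rows (`condition` x `version`) and the fitted
#'   `mu`, `sigma`, `tau` plus `converged`.
#' @export
simulate_participant_pair <- function(params, target = c("mu", "sigma", "tau"),
                                      effect, n_trials = 80,
                                      noise = noise_spec(10, 100)) {
  target <- match.arg(target)
  stopifnot(effect >= 0)
  params_exp <- params
  params_exp[[target]] <- params[[target]] + effect
  control_clean <- generate_exgauss_trials(params, n_trials)
  exp_clean <- generate_exgauss_trials(params_exp, n_trials)
  control_noisy <- add_noise(control_clean, noise)
  exp_noisy <- add_noise(exp_clean, noise)
  fits <- list(
    control_clean = fit_exgauss(control_clean),
    experimental_clean = fit_exgauss(exp_clean),
    control_noisy = fit_exgauss(control_noisy),
    experimental_noisy = fit_exgauss(exp_noisy)
  )
  purrr::imap_dfr(fits, function(f, nm) {
    tibble::tibble(
      condition = sub("_(clean|noisy)$", "", nm),
      version = sub("^.*_", "", nm),
      mu = f$mu, sigma = f$sigma, tau = f$tau,
      converged = f$converged
    )
  })
}

#' Effect attenuation and power cost of technical noise
#'
#' For every combination of target parameter and injected effect size, the
#' function simulates a within-subject experiment: each participant gets
#' freshly drawn base parameters, a control and an experimental condition
#' (the latter with the effect added to the target parameter), and clean and
#' noisy versions of both ([simulate_participant_pair()]). Per cell it
#' reports the paired-t Cohen's d across participants for the clean and the
#' noisy data, and the sample size needed for the target power at each d.
#' Defaults reproduce the study conditions: 500 participants, 80 trials,
#' U(10, 100) ms noise, effects 10-50 ms on each of mu, sigma, tau.
#'
#' Participants whose relevant pair of fits (clean or noisy) did not both
#' converge are excluded from that version's t-test, with counts reported.
#'
#' @param targets Parameters to perturb.
#' @param effects Effect sizes (ms).
#' @param participants Simulated participants per cell.
#' @param n_trials Trials per condition.
#' @param noise A [noise_spec()].
#' @param prior Participant-level parameter prior.
#' @param seed Master seed.
#' @param power,alpha Passed to [required_n()].
#' @return A tibble of class `effect_power` with one row per
#'   target x effect cell: `d_clean`, `d_noisy`, `n80_clean`, `n80_noisy`,
#'   t statistics and usable-participant counts.
#' @export
run_simulation3 <- function(targets = c("mu", "sigma", "tau"),
                            effects = c(10, 20, 30, 40, 50),
                            participants = 500,
                            n_trials = 80,
                            noise = noise_spec(10, 100),
                            prior = exgauss_prior(),
                            seed = NULL,
                            power = 0.80, alpha = 0.05) {
  stopifnot(length(effects) >= 1, participants >= 2)
  cells <- tidyr::expand_grid(target = targets, effect = effects)
  cell_seeds <- derive_seeds(seed, nrow(cells))
  out <- purrr::pmap_dfr(
    list(cells$target, cells$effect, cell_seeds),
    function(tg, ef, cs) {
      part_seeds <- derive_seeds(cs, participants)
      fits <- purrr::map_dfr(seq_len(participants), function(p) {
        set.seed(part_seeds[p])
        base <- sample_params(prior)
        dplyr::mutate(
          simulate_participant_pair(base, tg, ef, n_trials, noise),
          participant = p
        )
      })
      wide <- fits |>
        dplyr::select(dplyr::all_of(c("participant", "condition", "version",
                                      tg, "converged"))) |>
        tidyr::pivot_wider(
          names_from = c("condition", "version"),
          values_from = dplyr::all_of(c(tg, "converged"))
        )
      v <- function(cond, ver) wide[[paste(tg, cond, ver, sep = "_")]]
      okc <- function(cond, ver) wide[[paste("converged", cond, ver, sep = "_")]]
      ok_clean <- okc("control", "clean") & okc("experimental", "clean")
      ok_noisy <- okc("control", "noisy") & okc("experimental", "noisy")
      t_clean <- paired_t_and_d(
        v("experimental", "clean")[ok_clean], v("control", "clean")[ok_clean]
      )
      t_noisy <- paired_t_and_d(
        v("experimental", "noisy")[ok_noisy], v("control", "noisy")[ok_noisy]
      )
      d_clean <- t_clean$d
      d_noisy <- t_noisy$d
      tibble::tibble(
        target = tg, effect = ef,
        participants = participants,
        used_clean = sum(ok_clean), used_noisy = sum(ok_noisy),
        t_clean = t_clean$t, d_clean = d_clean,
        n80_clean = safe_required_n(d_clean, power, alpha),
        t_noisy = t_noisy$t, d_noisy = d_noisy,
        n80_noisy = safe_required_n(d_noisy, power, alpha)
      )
    }
  )
  class(out) <- c("effect_power", class(out))
  attr(out, "seed") <- seed
  attr(out, "noise") <- noise
  out
}
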