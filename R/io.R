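#' Read reaction times from a plain-text file
#'
#' Accepts a single-column CSV (with or without a header line) or
#' whitespace-delimited text, one RT in ms per line.
#'
#' @param path File path.
#' @return Numeric vector of reaction times (ms).
#' @export
read_rt <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  tokens <- unlist(strsplit(lines, "[,;[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  vals <- suppressWarnings(as.numeric(tokens))
  if (length(vals) && is.na(vals[1]) && !is.na(suppressWarnings(
    as.numeric(tokens[length(tokens)])
  ))) {
    # leading header token(s): drop the first line's worth
    first_n <- length(strsplit(lines[1], "[,;[:space:]]+")[[1]])
    tokens <- tokens[-seq_len(first_n)]
    vals <- suppressWarnings(as.numeric(tokens))
  }
  if (any(is.na(vals))) abort("Non-numeric reaction-time values in file.")
  vals
}

#' Read and write diffusion trial tables
#'
#' Two-column CSV with `rt_seconds` and `response` coded 1 = upper
#' (correct), 0 = lower (error).
#'
#' @param path File path.
#' @param trials A data frame with `rt` (seconds) and `response`.
#' @return `read_ddm_trials()` a `ddm_trials` tibble; `write_ddm_trials()`
#'   the path, invisibly.
#' @export
read_ddm_trials <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    rt_seconds = readr::col_double(),
    response = readr::col_integer()
  ))
  if (!all(df$response %in% c(0L, 1L))) {
    abort("`response` must be 0 (lower) or 1 (upper).")
  }
  out <- tibble::tibble(
    rt = df$rt_seconds,
    response = ifelse(df$response == 1L, "upper", "lower")
  )
  class(out) <- c("ddm_trials", class(out))
  out
}

#' @rdname read_ddm_trials
#' @export
write_ddm_trials <- function(trials, path) {
  readr::write_csv(
    tibble::tibble(
      rt_seconds = trials$rt,
      response = as.integer(trials$response == "upper")
    ),
    path
  )
  invisible(path)
}

#' Write a fitted model as a one-row CSV
#'
#' `exgauss_fit` objects produce `{mu, sigma, tau, loglik, converged}`;
#' `ddm_fit` objects `{a, v, ter, loglik, converged}`.
#'
#' @param fit An `exgauss_fit` or `ddm_fit` object.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_fit <- function(fit, path) {
  row <- if (inherits(fit, "exgauss_fit")) {
    tibble::tibble(
      mu = fit$mu, sigma = fit$sigma, tau = fit$tau,
      loglik = fit$loglik, converged = fit$converged
    )
  } else if (inherits(fit, "ddm_fit")) {
    tibble::tibble(
      a = fit$a, v = fit$v, ter = fit$ter,
      loglik = fit$loglik, converged = fit$converged
    )
  } else {
    abort("`fit` must be an exgauss_fit or ddm_fit.")
  }
  readr::write_csv(row, path)
  invisible(path)
}

run_config_defaults <- function(simulation = 1) {
  model <- if (simulation == 4) "ddm" else "exgauss"
  list(
    simulation = simulation,
    model = model,
    prior = if (model == "exgauss") unclass(exgauss_prior()) else unclass(ddm_prior()),
    n_trials = if (model == "ddm") 100 else 80,
    noise = c(10, 100),
    iterations = if (simulation == 2) 1000 else 500,
    participants = 500,
    effects = c(10, 20, 30, 40, 50),
    targets = c("mu", "sigma", "tau"),
    upper_bounds = seq(50, 200, by = 10),
    seed = 1,
    out_dir = "results"
  )
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) experiment description and fills every omitted
#' field with the study defaults for the requested simulation (priors,
#' 80/100 trials, U(10, 100) ms noise, 500 iterations — 1000 for the noise
#' sweep). Unknown keys are rejected by name; counts must be positive.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file. An empty file yields
#'   the full Simulation-1 default configuration.
#' @return A named list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  if (!is.list(user)) abort("Config must be a mapping of keys to values.")
  sim <- if (!is.null(user$simulation)) user$simulation else 1
  if (!sim %in% 1:4) abort("`simulation` must be 1, 2, 3 or 4.")
  cfg <- run_config_defaults(sim)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(user)] <- user
  for (key in c("n_trials", "iterations", "participants")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] < 1) {
      abort(paste0("`", key, "` must be a count >= 1."))
    }
  }
  if (length(cfg$noise) != 2 || cfg$noise[1] < 0 || cfg$noise[1] > cfg$noise[2]) {
    abort("`noise` must be c(low, high) with 0 <= low <= high.")
  }
  structure(cfg, class = "run_config")
}

#' Write simulation results with a reproducibility summary
#'
#' Writes the result table as a long-format CSV with deterministic column
#' order, a coefficient summary CSV where applicable (recovery records get
#' their [bias_summary_table()]), and a JSON sidecar embedding the
#' configuration, master seed, package version, and fit-exclusion counts —
#' enough to regenerate the files exactly.
#'
#' @param x A `recovery_records`, `noise_sweep` or `effect_power` tibble
#'   (any data frame is accepted and written as-is).
#' @param dir Output directory (created if needed).
#' @param config Optional `run_config` (or plain list) to embed.
#' @param seed Master seed to record; defaults to `attr(x, "seed")`.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(x, dir, config = NULL, seed = attr(x, "seed")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  records_path <- file.path(dir, "records.csv")
  readr::write_csv(as.data.frame(x), records_path)
  paths <- c(paths, records_path)
  exclusions <- NULL
  if (inherits(x, "recovery_records")) {
    reg <- regress_noisy_on_clean(x)
    summary_path <- file.path(dir, "summary.csv")
    readr::write_csv(bias_summary_table(reg), summary_path)
    paths <- c(paths, summary_path)
    exclusions <- stats::setNames(as.list(reg$n_excluded), reg$parameter)
  }
  meta <- list(
    package = "rtnoise",
    version = as.character(utils::packageVersion("rtnoise")),
    seed = seed,
    config = if (!is.null(config)) unclass(config),
    exclusions = exclusions
  )
  json_path <- file.path(dir, "summary.json")
  jsonlite::write_json(meta, json_path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
  )
  paths <- c(paths, json_path)
  invisible(paths)
}
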