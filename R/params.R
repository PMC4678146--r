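# Model parameters, species presets and configuration files.

#' Model parameters for a repertoire simulation
#'
#' Collects all scalar rates and counts of the competition model. The time
#' unit is abstract: with \code{mu = 1}, one time unit is the mean lifetime
#' of a T cell in the absence of division stimulus (a year in a human, a
#' month in a mouse).
#'
#' @param mu per-cell death rate (1/time).
#' @param gamma mean per-pMHC stimulus rate (cell divisions per unit time).
#' @param sigma dispersion (sd/mean) of log-normal stimulus rates; 0 means a
#'   constant rate \code{gamma} for every subset.
#' @param M number of self-pMHC subsets.
#' @param p probability that a clonotype recognises a given pMHC subset.
#' @param theta thymic production rate of new clonotypes (clonotypes/time).
#' @param n_theta number of cells in a newly exported clonotype.
#' @param N0 initial number of clonotypes.
#' @param n0 initial number of cells per clonotype.
#' @param t_max simulation horizon (time).
#' @param record_dt recording interval for the trajectory (time).
#' @param seed integer used to derive the three named seeds when
#'   \code{seeds} is not given.
#' @param seeds named list with integer elements \code{network},
#'   \code{dynamics}, \code{thymus} — the three independent random number
#'   streams (so replicate runs can share a network while varying dynamics).
#' @return an object of class \code{model_params}.
#' @examples
#' model_params()          # the small-scale default configuration
#' @export
model_params <- function(mu = 1, gamma = 10, sigma = 0, M = 1000, p = 0.1,
                         theta = 0, n_theta = 4, N0 = 200, n0 = 25,
                         t_max = 100, record_dt = 1,
                         seed = 1, seeds = NULL) {
  if (is.null(seeds)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
        abs(seed) >= 2^31 - 2)
      stop("'seed' must be an integer below 2^31")
    seeds <- list(network = as.integer(seed),
                  dynamics = as.integer(seed) + 1L,
                  thymus = as.integer(seed) + 2L)
  }
  p_check_scalar(mu, "mu", lower = 0)
  p_check_scalar(gamma, "gamma", lower = 0)
  p_check_scalar(sigma, "sigma", lower = 0)
  p_check_count(M, "M", min = 1)
  check_probability(p)
  p_check_scalar(theta, "theta", lower = 0)
  p_check_count(n_theta, "n_theta", min = 1)
  p_check_count(N0, "N0", min = 0)
  if (N0 > 0) p_check_count(n0, "n0", min = 1)
  p_check_scalar(t_max, "t_max", lower = 0, strict = TRUE)
  p_check_scalar(record_dt, "record_dt", lower = 0, strict = TRUE)
  for (nm in c("network", "dynamics", "thymus")) {
    s <- seeds[[nm]]
    if (is.null(s) || !is.numeric(s) || is.na(s) || abs(s) >= 2^31)
      stop("seed '", nm, "' must be an integer below 2^31")
    seeds[[nm]] <- as.integer(s)
  }
  structure(list(mu = mu, gamma = gamma, sigma = sigma, M = M, p = p,
                 theta = theta, n_theta = as.integer(n_theta),
                 N0 = as.integer(N0), n0 = as.integer(n0),
                 t_max = t_max, record_dt = record_dt, seeds = seeds),
            class = "model_params")
}

p_check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok) stop("'", name, "' must be a number ",
                if (strict) "> " else ">= ", lower)
  invisible(x)
}

p_check_count <- function(x, name, min = 0) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min &&
    x == round(x)
  if (!ok) stop("'", name, "' must be an integer >= ", min)
  invisible(x)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Repertoire model parameters\n")
  cat(sprintf("  death rate mu: %g   stimulus rate gamma: %g (sigma = %g)\n",
              x$mu, x$gamma, x$sigma))
  cat(sprintf("  pMHC subsets M: %g   recognition probability p: %g (pM = %g)\n",
              x$M, x$p, x$p * x$M))
  cat(sprintf("  thymic output theta: %g   cells per emigrant n_theta: %d\n",
              x$theta, x$n_theta))
  cat(sprintf("  initial repertoire: N0 = %d clonotypes of n0 = %d cells\n",
              x$N0, x$n0))
  cat(sprintf("  horizon t_max: %g   recording interval: %g\n",
              x$t_max, x$record_dt))
  cat(sprintf("  seeds: network %d, dynamics %d, thymus %d\n",
              x$seeds$network, x$seeds$dynamics, x$seeds$thymus))
  invisible(x)
}

#' Physiological parameter presets
#'
#' Returns the estimated physiological parameter values for the naive CD4+
#' compartment of a human (rates per year) or a mouse (rates per month).
#' Presets are stored as data in
#' \code{system.file("extdata/species_presets.csv", package = "clonedyn")},
#' so further presets can be added without code changes.
#'
#' @param species \code{"human"} or \code{"mouse"} (or any species added to
#'   the preset table).
#' @param ... named overrides of individual preset values.
#' @return named list with \code{mu}, \code{gamma}, \code{theta}, \code{M},
#'   \code{p}, \code{n_theta} and \code{time_unit}.
#' @examples
#' species_params("human")
#' @export
species_params <- function(species, ...) {
  tab <- read.csv(system.file("extdata", "species_presets.csv",
                              package = "clonedyn"),
                  stringsAsFactors = FALSE)
  row <- tab[tab$species == species, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown species preset: '", species, "' (available: ",
         paste(tab$species, collapse = ", "), ")")
  out <- list(mu = row$mu, gamma = row$gamma, theta = row$theta, M = row$M,
              p = row$p, n_theta = row$n_theta, time_unit = row$time_unit)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(out))
    if (length(bad)) stop("unknown preset field: '", bad[1], "'")
    out[names(dots)] <- dots
  }
  out
}

config_keys <- c("mu", "gamma", "sigma", "M", "p", "theta", "n_theta",
                 "N0", "n0", "t_max", "record_dt", "seed", "species")

#' Load a simulation configuration file
#'
#' Reads a flat YAML file with the keys of \code{\link{model_params}}
#' (\code{mu}, \code{gamma}, \code{sigma}, \code{M}, \code{p}, \code{theta},
#' \code{n_theta}, \code{N0}, \code{n0}, \code{t_max}, \code{record_dt}) plus
#' \code{seed} (a scalar, or a mapping with \code{network}, \code{dynamics},
#' \code{thymus}) and an optional \code{species} preset which supplies
#' \code{mu}, \code{gamma}, \code{theta}, \code{M}, \code{p} and
#' \code{n_theta} before explicit keys are applied. Unknown keys are
#' rejected; out-of-range values raise an error naming the key.
#'
#' @param path path of the YAML configuration file.
#' @return a validated \code{model_params} object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration must be a YAML mapping")
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown))
    stop("unknown configuration key: '", unknown[1], "'")
  vals <- list()
  if (!is.null(cfg$species)) {
    preset <- species_params(cfg$species)
    vals[c("mu", "gamma", "theta", "M", "p", "n_theta")] <-
      preset[c("mu", "gamma", "theta", "M", "p", "n_theta")]
  } else {
    for (key in c("mu", "gamma", "M", "p"))
      if (is.null(cfg[[key]]))
        stop("missing required configuration key: '", key, "'")
  }
  for (key in setdiff(names(cfg), c("seed", "species")))
    vals[[key]] <- cfg[[key]]
  seed_args <- list()
  if (!is.null(cfg$seed)) {
    if (is.list(cfg$seed)) {
      bad <- setdiff(names(cfg$seed), c("network", "dynamics", "thymus"))
      if (length(bad)) stop("unknown configuration key: 'seed.", bad[1], "'")
      base <- list(network = 1L, dynamics = 2L, thymus = 3L)
      base[names(cfg$seed)] <- cfg$seed
      seed_args$seeds <- base
    } else seed_args$seed <- cfg$seed
  }
  do.call(model_params, c(vals, seed_args))
}
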