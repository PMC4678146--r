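# High-level simulation interface around the compiled Gillespie engine.

#' Run an exact Gillespie realisation of the competition model
#'
#' Simulates the coupled birth-death-immigration process to
#' \code{params$t_max} (or to total extinction when \code{theta = 0}). If no
#' network is supplied, one is generated from the parameters using the
#' \code{network} seed (including log-normal stimulus rates when
#' \code{sigma > 0}); the dynamics and thymus streams are seeded separately
#' so replicate designs can share a network while varying the dynamics.
#'
#' @param params a \code{\link{model_params}} object.
#' @param network optional \code{recognition_network} (its \code{M} and
#'   stimulus rates are used as given). The network describes the founding
#'   clonotypes; thymic emigrants draw their patterns inside the engine.
#' @return an object of class \code{repertoire_sim}: list with
#'   \describe{
#'     \item{trajectory}{data frame sampled every \code{record_dt}: \code{t},
#'       \code{n_total}, \code{N_surviving}, \code{phi_bar}, \code{C_bar},
#'       cumulative \code{deaths}, \code{divisions}, \code{thymic_arrivals}.}
#'     \item{fates}{data frame with one row per clonotype ever created:
#'       \code{clonotype_id}, \code{t_birth}, \code{t_extinction} (NA if
#'       censored at the horizon), \code{censored}, \code{phi},
#'       \code{max_size}.}
#'     \item{final}{live ids, counts, per-pMHC totals \code{c}, division
#'       rates \code{Lambda} and total rate \code{S} at the horizon.}
#'     \item{params, network, tallies}{inputs and event totals.}
#'   }
#' @examples
#' sim <- run_simulation(model_params(M = 100, p = 0.1, N0 = 30, n0 = 5,
#'                                    t_max = 5, seed = 1))
#' summary(sim)
#' @export
run_simulation <- function(params, network = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (params$M > .Machine$integer.max)
    stop("'M' is too large to simulate directly; use the theory layer for physiological scales")
  if (is.null(network)) {
    set.seed(params$seeds$network)
    rates <- assign_stimulus_rates(params$M, params$gamma, params$sigma)
    network <- generate_network(params$N0, params$M, params$p,
                                stimulus_rates = rates)
    network$seed <- params$seeds$network
  } else {
    stopifnot(inherits(network, "recognition_network"))
    if (network$M != params$M)
      stop("network M (", network$M, ") does not match params M (", params$M, ")")
  }
  n_founders <- length(network$patterns)
  counts0 <- rep(params$n0, n_founders)
  res <- cpp_gillespie_run(unname(network$patterns),
                           network$stimulus_rates,
                           params$mu, params$theta, params$n_theta, params$p,
                           as.integer(counts0),
                           params$t_max, params$record_dt,
                           params$seeds$dynamics, params$seeds$thymus,
                           check_caches = FALSE)
  assemble_sim(res, params, network)
}

assemble_sim <- function(res, params, network) {
  traj <- as.data.frame(res$trajectory)
  fates <- as.data.frame(res$fates)
  fates$censored <- is.na(fates$t_extinction)
  fates <- fates[, c("clonotype_id", "t_birth", "t_extinction", "censored",
                     "phi", "max_size")]
  structure(list(params = params, network = network, trajectory = traj,
                 fates = fates, final = res$final, tallies = res$tallies),
            class = "repertoire_sim")
}

#' @export
print.repertoire_sim <- function(x, ...) {
  tr <- x$trajectory
  last <- tr[nrow(tr), ]
  cat("Gillespie realisation of the multiclonal competition model\n")
  cat(sprintf("  horizon t = %g (%d recorded times)\n", max(tr$t), nrow(tr)))
  cat(sprintf("  clonotypes: %d initial, %d thymic, %d surviving at horizon\n",
              x$params$N0, as.integer(x$tallies[["thymic_arrivals"]]),
              as.integer(last$N_surviving)))
  cat(sprintf("  cells at horizon: %d   events: %d deaths, %d divisions\n",
              as.integer(last$n_total), as.integer(x$tallies[["deaths"]]),
              as.integer(x$tallies[["divisions"]])))
  invisible(x)
}

#' @export
summary.repertoire_sim <- function(object, ...) {
  tr <- object$trajectory
  tail_win <- tr$t >= 0.75 * max(tr$t)
  out <- list(
    params = object$params,
    t_max = max(tr$t),
    n_final = tr$n_total[nrow(tr)],
    N_final = tr$N_surviving[nrow(tr)],
    n_tail_mean = mean(tr$n_total[tail_win]),
    N_tail_mean = mean(tr$N_surviving[tail_win]),
    extinct_fraction = mean(!object$fates$censored),
    tallies = object$tallies)
  class(out) <- "summary.repertoire_sim"
  out
}

#' @export
print.summary.repertoire_sim <- function(x, ...) {
  cat("Repertoire simulation summary\n")
  cat(sprintf("  horizon: %g   final cells: %d   final clonotypes: %d\n",
              x$t_max, as.integer(x$n_final), as.integer(x$N_final)))
  cat(sprintf("  late-time means (final 25%% of horizon): n = %.1f, N = %.1f\n",
              x$n_tail_mean, x$N_tail_mean))
  cat(sprintf("  fraction of created clonotypes extinct: %.3f\n",
              x$extinct_fraction))
  cat(sprintf("  events: %d deaths, %d divisions, %d thymic arrivals\n",
              as.integer(x$tallies[["deaths"]]),
              as.integer(x$tallies[["divisions"]]),
              as.integer(x$tallies[["thymic_arrivals"]])))
  invisible(x)
}

#' @export
plot.repertoire_sim <- function(x, ...) {
  tr <- x$trajectory
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(tr$t, tr$n_total, type = "l", xlab = "time", ylab = "total cells n(t)",
       main = "cells", ...)
  tpos <- tr$t > 0
  plot(tr$t[tpos], tr$N_surviving[tpos], type = "l", log = "x",
       xlab = "time", ylab = "surviving clonotypes N(t)",
       main = "clonotypes", ...)
  invisible(x)
}

#' Replicate realisations on a fixed recognition network
#'
#' Re-runs the dynamics several times on the same connection matrix (the
#' same in-silico individual) with different dynamics seeds, recording which
#' clonotypes survive to the horizon in each realisation. Used to ask
#' whether the competition is selective (the same clonotypes survive in most
#' realisations) or purely stochastic. Thymic input must be switched off so
#' that the founding clonotypes are comparable across replicates.
#'
#' @param network a \code{recognition_network}.
#' @param params a \code{model_params} with \code{theta = 0}.
#' @param n_replicates number of realisations (>= 2).
#' @param dynamics_seeds optional integer vector of per-replicate dynamics
#'   seeds; defaults to \code{params$seeds$dynamics + 0:(n_replicates-1)}.
#' @return an object of class \code{replicate_run}: list with the logical
#'   \code{survival} matrix (replicate x clonotype), per-clonotype
#'   \code{frequency}, cross-reactivities \code{phi}, and the seeds used.
#' @export
run_replicates_fixed_network <- function(network, params, n_replicates,
                                         dynamics_seeds = NULL) {
  stopifnot(inherits(network, "recognition_network"),
            inherits(params, "model_params"))
  if (params$theta != 0)
    stop("replicate survival experiments require theta = 0")
  if (n_replicates < 2) stop("'n_replicates' must be >= 2")
  if (is.null(dynamics_seeds))
    dynamics_seeds <- params$seeds$dynamics + seq_len(n_replicates) - 1L
  if (length(dynamics_seeds) != n_replicates)
    stop("'dynamics_seeds' must have length n_replicates")
  ids <- as.integer(names(network$patterns))
  survival <- matrix(FALSE, n_replicates, length(ids),
                     dimnames = list(NULL, names(network$patterns)))
  for (r in seq_len(n_replicates)) {
    pr <- params
    pr$seeds$dynamics <- as.integer(dynamics_seeds[r])
    sim <- run_simulation(pr, network = network)
    survival[r, ] <- ids %in% sim$final$id
  }
  structure(list(survival = survival, frequency = colMeans(survival),
                 phi = lengths(network$patterns),
                 dynamics_seeds = as.integer(dynamics_seeds),
                 params = params),
            class = "replicate_run")
}

#' @export
print.replicate_run <- function(x, ...) {
  R <- nrow(x$survival)
  cat("Replicate realisations on a fixed recognition network\n")
  cat(sprintf("  %d replicates x %d clonotypes; mean survival fraction %.4f\n",
              R, ncol(x$survival), mean(x$survival)))
  cat(sprintf("  clonotypes surviving in >= %d/%d replicates: %d\n",
              ceiling(0.8 * R), R, sum(colSums(x$survival) >= ceiling(0.8 * R))))
  invisible(x)
}
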