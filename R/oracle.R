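# Brute-force Monte Carlo oracle for the diffusion-approximation lifetime:
# direct simulation of the single-clone birth-death chain with birth rate
# mu*n/(1+alpha) and death rate mu*n, independent of both the diffusion
# formula and the repertoire engine.

#' Monte Carlo mean extinction time of the single-clone chain
#'
#' Simulates the integer birth-death process with per-clone birth rate
#' \code{mu * n / (1 + alpha)} and death rate \code{mu * n} from
#' \code{n = n_theta} until absorption at 0, by direct Gillespie sampling,
#' and returns the Monte Carlo mean and standard error. Exploits that the
#' embedded jump chain is a simple random walk (up-step probability
#' \code{1/(2+alpha)} independent of \code{n}) with sojourn times
#' \code{Exponential(rate = (2+alpha)/(1+alpha) * mu * n)}; all replicates
#' are advanced in lockstep. Used as an independent validation oracle for
#' \code{\link{mean_extinction_time}}.
#'
#' @param alpha thymic-to-peripheral production ratio (> 0: the chain is
#'   subcritical and the mean is finite).
#' @param n_theta initial number of cells.
#' @param mu per-cell death rate.
#' @param n_replicates number of independent chains (>= 1000).
#' @param seed optional integer seed.
#' @param max_steps safety cap on jump-chain length per replicate.
#' @return list with \code{mean}, \code{se}, \code{n_replicates}.
#' @examples
#' birth_death_extinction_oracle(0.1, 4, 1, n_replicates = 2000, seed = 1)
#' @export
birth_death_extinction_oracle <- function(alpha, n_theta, mu,
                                          n_replicates = 1e4, seed = NULL,
                                          max_steps = 1e6) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be > 0 (alpha = 0 is critical: infinite mean)")
  p_check_count(n_theta, "n_theta", min = 1)
  p_check_scalar(mu, "mu", lower = 0, strict = TRUE)
  if (n_replicates < 1000) stop("'n_replicates' must be >= 1000")
  if (!is.null(seed)) set.seed(seed)
  lambda <- mu / (1 + alpha)          # per-cell birth rate
  rate_per_cell <- lambda + mu        # total jump rate per cell
  p_up <- lambda / rate_per_cell
  n <- rep.int(n_theta, n_replicates)
  tt <- numeric(n_replicates)
  active <- seq_len(n_replicates)
  steps <- 0L
  while (length(active)) {
    steps <- steps + 1L
    if (steps > max_steps)
      stop("chain exceeded max_steps before absorption; increase 'max_steps'")
    na <- n[active]
    tt[active] <- tt[active] + rexp(length(active), rate_per_cell * na)
    up <- runif(length(active)) < p_up
    na <- na + ifelse(up, 1L, -1L)
    n[active] <- na
    active <- active[na > 0L]
  }
  list(mean = mean(tt), se = sd(tt) / sqrt(n_replicates),
       n_replicates = n_replicates)
}
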