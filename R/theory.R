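# Closed-form layer: stationary means, the thymic-to-peripheral production
# ratio, diffusion-approximation clonal lifetimes and clonotype-number
# estimates.

#' Euler-Mascheroni constant
#' @export
euler_gamma <- 0.5772156649015329

# Ei(-z) for z > 0, via the E1 exponential integral. For large z the product
# e^z * E1(z) is computed from its asymptotic series to avoid overflow of
# exp(z).
ei_neg <- function(z) -vapply(z, pracma::expint_E1, numeric(1))

exp_ei_neg <- function(z) {
  # returns e^z * Ei(-z) for z > 0
  out <- numeric(length(z))
  small <- z <= 50
  if (any(small)) out[small] <- exp(z[small]) * ei_neg(z[small])
  if (any(!small)) {
    zz <- z[!small]
    out[!small] <- -(1 / zz) * (1 - 1 / zz + 2 / zz^2 - 6 / zz^3 + 24 / zz^4)
  }
  out
}

#' Stationary mean total number of cells
#'
#' While every pMHC subset is recognised by at least one cell, the total
#' peripheral division rate is the constant \code{Phi = sum_q gamma_q}, and
#' the mean total cell count relaxes (on the timescale \code{1/mu}) to
#' \code{x* = (Phi + theta * n_theta) / mu}. With a constant stimulus rate
#' \code{gamma}, \code{Phi = gamma * M}.
#'
#' @param gamma_total total stimulus rate \code{sum_q gamma_q} (for constant
#'   rates, \code{gamma * M}).
#' @param theta thymic clonotype production rate.
#' @param n_theta cells per new clonotype.
#' @param mu per-cell death rate (> 0).
#' @return stationary mean number of cells.
#' @examples
#' stationary_mean_cells(1e11, 1e9, 4, 0.5)  # adult human, cells/year rates
#' @export
stationary_mean_cells <- function(gamma_total, theta = 0, n_theta = 0, mu) {
  if (!is.numeric(mu) || any(mu <= 0)) stop("'mu' must be > 0")
  (gamma_total + theta * n_theta) / mu
}

#' Steady-state fraction of undivided thymic emigrants
#'
#' \code{r = theta * n_theta / (gamma_total + theta * n_theta)}: the fraction
#' of cells that came from the thymus and have not divided in the periphery.
#'
#' @inheritParams stationary_mean_cells
#' @return a probability.
#' @export
thymic_fraction <- function(theta, n_theta, gamma_total) {
  denom <- gamma_total + theta * n_theta
  if (any(denom <= 0))
    stop("at least one of 'gamma_total' and 'theta * n_theta' must be positive")
  theta * n_theta / denom
}

#' Thymic-to-peripheral production ratio
#'
#' \code{alpha = n_theta * theta / gamma_total}: the ratio of the rate at
#' which the thymus creates cells to the rate of peripheral division.
#' \code{alpha << 1} is the human regime; \code{alpha >> 1} the murine one.
#'
#' @inheritParams stationary_mean_cells
#' @return dimensionless ratio.
#' @examples
#' alpha_ratio(1e9, 4, 1e11)  # adult human: 0.04
#' @export
alpha_ratio <- function(theta, n_theta, gamma_total) {
  if (any(gamma_total <= 0)) stop("'gamma_total' must be > 0")
  n_theta * theta / gamma_total
}

#' Clonotype number in the weak-peripheral-division (murine) limit
#'
#' With negligible peripheral division, clonotypes decay independently from
#' their initial \code{n_theta} cells and the mean number of cells per
#' clonotype, averaged over its lifetime, is \code{n_theta / 2}; hence
#' \code{N* = 2 x / n_theta} where \code{x} is the mean total naive T cell
#' count. Because a surviving clonotype always has at least one cell, the
#' mean clone size is floored at 1: for \code{n_theta < 2} (nearly every
#' clonotype has a single cell) the function returns \code{N* = x} with a
#' regime warning.
#'
#' @param n_theta cells per thymic emigrant clonotype (>= 1).
#' @param x mean total number of naive T cells.
#' @return estimated number of clonotypes.
#' @examples
#' murine_clonotype_number(4, 1e7)  # about 5e6 clonotypes in a mouse
#' @export
murine_clonotype_number <- function(n_theta, x) {
  p_check_count(n_theta, "n_theta", min = 1)
  if (n_theta < 2)
    warning("n_theta < 2: nearly every clonotype has one cell; reporting the N* <= x bound")
  x / max(n_theta / 2, 1)
}

#' Mean clonal lifetime from the diffusion approximation
#'
#' The size of one clonotype embedded in a homeostatic repertoire is
#' approximated by a diffusion with drift \code{-mu * alpha/(1+alpha) * x}
#' and squared noise \code{(2+alpha)/(1+alpha) * mu * x}. For small
#' \code{alpha} the mean first-passage time to 0 from \code{b} cells is
#' \deqn{T(\alpha, b) = \frac{1}{\alpha\mu}\left(\gamma_E -
#'   e^{\alpha b}\,\mathrm{Ei}(-\alpha b) + \log(\alpha b)\right),}
#' with Ei the exponential integral. For \code{alpha * b < 1e-8} the
#' asymptotic form \code{(b/mu) * (1 - gamma_E - log(alpha * b))} is used to
#' avoid catastrophic cancellation; at \code{alpha = 0} the process is
#' critical and the mean lifetime diverges (\code{Inf} is returned).
#'
#' @param alpha thymic-to-peripheral production ratio (>= 0).
#' @param b initial clone size (cells, > 0); for a thymic emigrant,
#'   \code{n_theta}.
#' @param mu per-cell death rate (> 0).
#' @return mean time to extinction (units \code{1/mu}); \code{Inf} where
#'   \code{alpha = 0}.
#' @examples
#' mean_extinction_time(0.04, 4, 0.5)  # human-regime clonal lifetime, years
#' @export
mean_extinction_time <- function(alpha, b, mu) {
  if (!is.numeric(mu) || any(mu <= 0)) stop("'mu' must be > 0")
  if (any(b <= 0)) stop("'b' must be > 0")
  if (any(alpha < 0)) stop("'alpha' must be >= 0")
  n <- max(length(alpha), length(b), length(mu))
  alpha <- rep_len(alpha, n); b <- rep_len(b, n); mu <- rep_len(mu, n)
  out <- numeric(n)
  ab <- alpha * b
  crit <- alpha == 0
  out[crit] <- Inf
  tiny <- !crit & ab < 1e-8
  out[tiny] <- (b[tiny] / mu[tiny]) * (1 - euler_gamma - log(ab[tiny]))
  rest <- !crit & !tiny
  out[rest] <- (euler_gamma - exp_ei_neg(ab[rest]) + log(ab[rest])) /
    (alpha[rest] * mu[rest])
  out
}

#' Stationary number of clonotypes
#'
#' The stationary clonotype number is the thymic production rate times the
#' mean clonal lifetime: \code{N* = theta * T(alpha, n_theta)}. In
#' asymptotic mode the small-\code{alpha * n_theta} expansion
#' \code{N* = (theta * n_theta / mu) * (1 - gamma_E - log(n_theta * alpha))}
#' is returned instead.
#'
#' @param theta thymic clonotype production rate.
#' @param alpha thymic-to-peripheral production ratio.
#' @param n_theta cells per new clonotype.
#' @param mu per-cell death rate.
#' @param mode \code{"exact"} (via \code{\link{mean_extinction_time}}) or
#'   \code{"asymptotic"}.
#' @return stationary mean number of clonotypes.
#' @examples
#' clonotype_number(1e9, 0.04, 4, 0.5, mode = "asymptotic")  # about 1.8e10
#' @export
clonotype_number <- function(theta, alpha, n_theta, mu,
                             mode = c("exact", "asymptotic")) {
  mode <- match.arg(mode)
  if (theta == 0) return(0)
  if (mode == "exact") {
    theta * mean_extinction_time(alpha, n_theta, mu)
  } else {
    (theta * n_theta / mu) * (1 - euler_gamma - log(n_theta * alpha))
  }
}

#' Clonal extinction probability of the critical diffusion
#'
#' At \code{alpha = 0} the clone-size diffusion is critical and the
#' probability that a clone starting from \code{b} cells is extinct by time
#' \code{t} is \code{exp(-b / (mu * t))}. At the repertoire level, with
#' \code{N0} founding clonotypes sharing \code{gamma_total / mu} cells, the
#' appropriate initial condition is \code{b = gamma_total / (mu * N0)}.
#'
#' @param b initial clone size (cells, > 0).
#' @param mu per-cell death rate.
#' @param t time (> 0); vectorised.
#' @return probability of extinction by time \code{t}.
#' @export
extinction_probability <- function(b, mu, t) {
  if (any(b <= 0)) stop("'b' must be > 0")
  if (any(mu <= 0)) stop("'mu' must be > 0")
  if (any(t <= 0)) stop("'t' must be > 0")
  exp(-b / (mu * t))
}

#' Mean-field division rate of one clonotype
#'
#' Replacing the per-pMHC competitor totals by their homeostatic means gives
#' \code{Lambda = mu * n / (1 + alpha)}: in the absence of thymic input the
#' division rate balances the death rate \code{mu * n} exactly; thymic
#' dilution (\code{alpha > 0}) tips the balance towards contraction.
#'
#' @param n clone size (cells).
#' @param alpha thymic-to-peripheral production ratio.
#' @param mu per-cell death rate.
#' @return division rate.
#' @export
meanfield_division_rate <- function(n, alpha, mu) {
  if (any(n < 0)) stop("'n' must be >= 0")
  mu * n / (1 + alpha)
}

#' Drift and squared-noise coefficients of the clone-size diffusion
#'
#' The diffusion approximation of the single-clone process has increment
#' mean \code{-mu * alpha/(1+alpha) * x * dt} and increment mean square
#' \code{(2+alpha)/(1+alpha) * mu * x * dt}.
#'
#' @param x clone size (>= 0).
#' @param alpha thymic-to-peripheral production ratio.
#' @param mu per-cell death rate.
#' @return list with \code{drift} and \code{noise_sq}.
#' @export
sde_coefficients <- function(x, alpha, mu) {
  if (any(x < 0)) stop("'x' must be >= 0")
  list(drift = -mu * alpha / (1 + alpha) * x,
       noise_sq = (2 + alpha) / (1 + alpha) * mu * x)
}

#' Theory report for one parameter set
#'
#' Evaluates the whole closed-form layer for a physiological parameter set:
#' stationary cells, thymic fraction, production ratio, mean clonal lifetime
#' and the clonotype number in exact and asymptotic form.
#'
#' @param mu,gamma,theta,M,p,n_theta model parameters (see
#'   \code{\link{model_params}}); \code{p} is carried for the report only.
#' @return named list \code{x_star}, \code{r}, \code{alpha},
#'   \code{mean_lifetime}, \code{N_star_exact}, \code{N_star_asymptotic},
#'   \code{regime}.
#' @examples
#' do.call(theory_report, species_params("human")[c("mu","gamma","theta","M","p","n_theta")])
#' @export
theory_report <- function(mu, gamma, theta, M, p, n_theta) {
  gM <- gamma * M
  a <- alpha_ratio(theta, n_theta, gM)
  list(x_star = stationary_mean_cells(gM, theta, n_theta, mu),
       r = thymic_fraction(theta, n_theta, gM),
       alpha = a,
       mean_lifetime = mean_extinction_time(a, n_theta, mu),
       N_star_exact = clonotype_number(theta, a, n_theta, mu, "exact"),
       N_star_asymptotic = if (a > 0 && n_theta * a < 1)
         clonotype_number(theta, a, n_theta, mu, "asymptotic") else NA_real_,
       regime = if (a > 1) "thymic-dominated (murine-like)"
                else "peripheral-division-dominated (human-like)")
}

#' Steady-state clonotype number as a function of thymic strength
#'
#' Regenerates the theory curve family \code{N*(alpha)} on a logarithmic
#' \code{alpha} grid for several emigrant sizes \code{n_theta}, at fixed
#' total peripheral division \code{gamma_total / mu}. For each point,
#' \code{theta = alpha * gamma_total / n_theta} and
#' \code{N* = theta * T(alpha, n_theta)} (exact), alongside the
#' weak-thymus asymptotic form.
#'
#' @param alpha numeric grid of production ratios (> 0).
#' @param n_theta integer vector of emigrant sizes.
#' @param gamma_total_over_mu total cells produced per mean cell lifetime
#'   (default \code{1e11}, the human naive CD4+ compartment).
#' @param mu death rate (sets the time unit; default 1).
#' @return data frame with \code{alpha}, \code{n_theta}, \code{theta},
#'   \code{N_exact}, \code{N_asymptotic}.
#' @export
theory_curves <- function(alpha = 10^seq(-4, 0, length.out = 41),
                          n_theta = c(1, 4, 16),
                          gamma_total_over_mu = 1e11, mu = 1) {
  if (any(alpha <= 0)) stop("'alpha' grid must be positive")
  grid <- expand.grid(alpha = alpha, n_theta = n_theta)
  gM <- gamma_total_over_mu * mu
  grid$theta <- grid$alpha * gM / grid$n_theta
  grid$N_exact <- grid$theta *
    mean_extinction_time(grid$alpha, grid$n_theta, mu)
  grid$N_asymptotic <- (grid$theta * grid$n_theta / mu) *
    (1 - euler_gamma - log(grid$n_theta * grid$alpha))
  grid
}
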