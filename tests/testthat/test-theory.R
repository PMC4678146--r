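# Closed-form layer: stationary means, production ratio, diffusion lifetime
# and clonotype-number estimates.

test_that("stationary mean cells and thymic fraction", {
  expect_equal(stationary_mean_cells(10 * 1000, 0, 0, 1), 1e4)
  expect_equal(stationary_mean_cells(1e11, 1e9, 4, 0.5), 2.08e11)
  expect_equal(stationary_mean_cells(5000, 0, 0, 2), 5000 / 2)
  expect_error(stationary_mean_cells(1, 0, 0, 0), "'mu'")

  expect_equal(thymic_fraction(1, 4, 4), 1 / 2)
  expect_equal(thymic_fraction(1e9, 4, 1e11), 4e9 / 1.04e11)
  # murine limit: nearly all cells are undivided emigrants
  expect_gt(thymic_fraction(2.5e6, 4, 1e6), 0.9)
  expect_error(thymic_fraction(0, 0, 0), "positive")
})

test_that("thymic-to-peripheral production ratio", {
  expect_equal(alpha_ratio(1e9, 4, 1e11), 0.04)
  expect_equal(alpha_ratio(0, 4, 10), 0)
  expect_equal(alpha_ratio(3, 8, 10), 2 * alpha_ratio(3, 4, 10))
  expect_error(alpha_ratio(1, 4, 0), "'gamma_total'")
})

test_that("murine clonotype estimate with the single-cell floor", {
  expect_equal(murine_clonotype_number(4, 1e7), 5e6)
  expect_equal(murine_clonotype_number(2, 123), 123)
  expect_warning(n1 <- murine_clonotype_number(1, 1e7), "one cell")
  expect_equal(n1, 1e7)  # N* <= x bound when every clone has one cell
})

test_that("mean clonal lifetime matches special-function values", {
  # gamma_E - e * Ei(-1), Ei(-1) = -0.2193839...
  expect_equal(mean_extinction_time(1, 1, 1), 1.173563, tolerance = 1e-6)
  expect_equal(mean_extinction_time(0.1, 4, 1), 7.08753, tolerance = 1e-5)
  expect_identical(mean_extinction_time(0, 4, 1), Inf)  # critical: no mean
  expect_error(mean_extinction_time(0.1, -1, 1), "'b'")
})

test_that("asymptotic branch agrees with the exact form near the switch", {
  # 1% agreement when alpha*b = 1e-3
  exact <- mean_extinction_time(1e-3, 1, 1)
  asym <- (1 / 1) * (1 - euler_gamma - log(1e-3))
  expect_lt(abs(exact - asym) / exact, 0.01)
  # continuity across the 1e-8 switch threshold (limited by cancellation in
  # the exact branch, whose bracket is O(alpha*b) there)
  lo <- mean_extinction_time(0.9999e-8, 1, 1)
  hi <- mean_extinction_time(1.0001e-8, 1, 1)
  expect_lt(abs(lo - hi) / hi, 1e-4)
  # overflow-safe branch for large alpha*b stays finite and positive
  big <- mean_extinction_time(c(10, 200, 1000), 4, 1)
  expect_true(all(is.finite(big) & big > 0))
  # large-argument expansion: -e^x Ei(-x) ~ 1/x - 1/x^2 + ...
  expect_equal(mean_extinction_time(200, 4, 1),
               (euler_gamma + log(800) + 1 / 800) / 200, tolerance = 1e-5)
})

test_that("lifetime satisfies mu*b*T'' - alpha*mu*b*T' = -1", {
  h <- 1e-3
  for (alpha in c(0.05, 0.2, 1)) {
    for (b in c(1, 2, 4, 8)) {
      Tm <- mean_extinction_time(alpha, b - h, 1)
      T0 <- mean_extinction_time(alpha, b, 1)
      Tp <- mean_extinction_time(alpha, b + h, 1)
      d1 <- (Tp - Tm) / (2 * h)
      d2 <- (Tp - 2 * T0 + Tm) / h^2
      residual <- b * d2 - alpha * b * d1 + 1
      expect_lt(abs(residual), 1e-6)
    }
  }
})

test_that("lifetime is monotone in alpha and b, and scales as 1/mu", {
  a_grid <- c(0.01, 0.05, 0.2, 1, 5)
  Ts <- mean_extinction_time(a_grid, 4, 1)
  expect_true(all(diff(Ts) < 0))
  b_grid <- c(1, 2, 4, 8, 16)
  Tb <- mean_extinction_time(0.1, b_grid, 1)
  expect_true(all(diff(Tb) > 0))
  expect_equal(mean_extinction_time(0.1, 4, 3),
               mean_extinction_time(0.1, 4, 1) / 3)
})

test_that("clonotype number: definitional identity and human regime", {
  expect_equal(clonotype_number(7, 0.1, 4, 1, "exact"),
               7 * mean_extinction_time(0.1, 4, 1))
  expect_equal(clonotype_number(0, 0.1, 4, 1), 0)
  Nh <- clonotype_number(1e9, 0.04, 4, 0.5, "asymptotic")
  expect_equal(Nh, 8e9 * (1 - euler_gamma - log(0.16)))
  # exact and asymptotic modes agree within 15% at alpha*n_theta = 0.16
  Ne <- clonotype_number(1e9, 0.04, 4, 0.5, "exact")
  expect_lt(abs(Ne - Nh) / Ne, 0.15)
  # ... and within 1% deep in the weak-thymus regime
  a <- 1e-3 / 4
  expect_lt(abs(clonotype_number(1, a, 4, 1, "exact") -
                clonotype_number(1, a, 4, 1, "asymptotic")) /
            clonotype_number(1, a, 4, 1, "exact"), 0.01)
})

test_that("critical extinction law and its discrete-chain oracle", {
  expect_equal(extinction_probability(5, 2, 5 / 2), exp(-1))
  expect_lt(extinction_probability(50, 1, 1e-3), 1e-10)  # t -> 0+: 0
  expect_gt(extinction_probability(50, 1, 1e6), 0.9999)  # t -> inf: 1
  # exact linear critical birth-death chain: P[extinct by t] = (mt/(1+mt))^b
  b <- 50; mt <- 50
  chain <- (mt / (1 + mt))^b
  diffusion <- extinction_probability(b, 1, mt)
  expect_lt(abs(chain - diffusion) / diffusion, 0.01)
})

test_that("mean-field division rate and diffusion coefficients", {
  expect_equal(meanfield_division_rate(10, 0, 2), 20)  # balance at alpha = 0
  expect_equal(meanfield_division_rate(10, 0.04, 0.5), 5 / 1.04)
  expect_lt(meanfield_division_rate(10, 0.3, 1), 10)

  co <- sde_coefficients(7, 0, 1)
  expect_equal(co$drift, 0)
  expect_equal(co$noise_sq, 14)
  co0 <- sde_coefficients(0, 0.5, 1)
  expect_equal(unlist(co0), c(drift = 0, noise_sq = 0))
  # drift / (-mu x) -> alpha as alpha -> 0
  a <- 1e-4
  expect_equal(sde_coefficients(3, a, 2)$drift / (-2 * 3), a,
               tolerance = 1e-3)
})

test_that("theory report and curve family are coherent", {
  hp <- species_params("human")
  rep <- theory_report(hp$mu, hp$gamma, hp$theta, hp$M, hp$p, hp$n_theta)
  expect_equal(rep$x_star, 2.08e11)
  expect_equal(rep$alpha, 0.04)
  expect_equal(rep$N_star_exact, hp$theta * rep$mean_lifetime)
  expect_match(rep$regime, "human")
  mp <- species_params("mouse")
  repm <- theory_report(mp$mu, mp$gamma, mp$theta, mp$M, mp$p, mp$n_theta)
  expect_match(repm$regime, "murine")
  expect_equal(repm$alpha, 10)

  cv <- theory_curves(alpha = 10^seq(-4, -1, length.out = 13), n_theta = 4)
  expect_true(all(diff(cv$N_exact) > 0))  # more thymus, more clonotypes
  at <- theory_curves(alpha = 1e-3, n_theta = 1)
  expect_lt(abs(at$N_exact - at$N_asymptotic) / at$N_exact, 0.01)
})
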