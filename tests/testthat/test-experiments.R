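# Scripted experiment drivers: degree drift, selectivity, scaling with
# system size, thymic input and log-normal stimulus rates.

test_that("extinction driver outputs the comparison table and mean recovery", {
  ex <- extinction_experiment(n_replicates = 2, t_max = 10, seed = 5,
                              M = 100, N0 = 50, n0 = 5)
  expect_named(ex$comparison, c("t", "extinct_fraction", "predicted"))
  expect_equal(ex$manifest$b, 10 * 100 / (1 * 50))
  expect_equal(ex$x_star, 1000)
  expect_lt(abs(ex$late_n_mean - 1000) / 1000, 0.2)
  expect_true(all(diff(ex$comparison$predicted) >= 0))
})

test_that("extinction raises phi_bar and lowers C_bar at fixed identity", {
  dd <- degree_drift_experiment(seed = 19, t_max = 60)
  s <- dd$series
  expect_lt(abs(s$phi_bar[1] - 100), 3 * sqrt(2000 * 0.05 * 0.95 / 1000))
  expect_gt(s$phi_bar[nrow(s)], s$phi_bar[1])
  expect_lt(s$C_bar[nrow(s)], s$C_bar[1])
  expect_identity_holds(dd$sim$trajectory, 2000)
  # substantial extinction, but far from total
  frac_surv <- s$N_surviving[nrow(s)] / 1000
  expect_gt(frac_surv, 0.05)
  expect_lt(frac_surv, 0.45)
  # histogram bookkeeping: end summaries are over the survivors only
  expect_equal(dd$end$N, s$N_surviving[nrow(s)])
  expect_identical(sum(dd$end$Cq_counts), dd$end$total_connections)
  # the survivors' cross-reactivities sit higher than the founding pool's
  expect_gt(mean(dd$end$phi), mean(dd$start$phi))
})

test_that("competition is selective, not chance-only", {
  sel <- selectivity_fixture()
  # positive rank association between cross-reactivity and survival
  expect_gt(sel$rank_association$rho, 0)
  expect_lt(sel$rank_association$p_value, 0.01)
  # a subset of clonotypes survives in most realisations: far more
  # high-frequency survivors than the chance-only binomial null allows
  expect_gt(sel$null_comparison$observed,
            max(1, 3 * sel$null_comparison$expected_under_chance))
  # most clonotypes go extinct in every realisation
  expect_lt(sel$survival_fraction, 0.3)
  expect_gt(mean(colSums(sel$replicates$survival) == 0), 0.5)
})

test_that("replicates with identical dynamics seeds are identical", {
  set.seed(61)
  net <- generate_network(30, 50, 0.2, stimulus_rates = rep(4, 50))
  params <- model_params(M = 50, p = 0.2, N0 = 30, n0 = 4, theta = 0,
                         t_max = 4, seed = 3)
  reps <- run_replicates_fixed_network(net, params, 3,
                                       dynamics_seeds = c(5L, 5L, 8L))
  expect_identical(reps$survival[1, ], reps$survival[2, ])
  expect_error(run_replicates_fixed_network(
    net, model_params(M = 50, p = 0.2, theta = 1, N0 = 30, n0 = 4), 2),
    "theta")
})

test_that("p*N(t) is invariant under system growth at fixed pM", {
  sc <- scaling_experiment(M_grid = c(1600, 3200), t_max = 15,
                           n_replicates = 3, seed = 23)
  expect_equal(sc$curves[["1600"]]$pN_mean[1], 25)  # p * N0 = pM/4
  expect_equal(sc$curves[["3200"]]$pN_mean[1], 25)
  bs <- sc$band_stats[[1]]
  expect_gte(bs$frac_within_3se, 0.9)
})

test_that("thymic input sets the clonotype plateau, not the cell count", {
  # horizons must cover the slow extinction of the giant clones founded in
  # the initially empty periphery, which sets the equilibration timescale
  th <- thymus_experiment(theta_grid = c(10, 25), M = 100, pM = 100,
                          t_max = 120, seed = 29, detail_theta = 25,
                          n_replicates = 1)
  s <- th$summary
  expect_true(all(diff(s$N_plateau) > 0))  # more thymus, more clonotypes
  expect_lt(abs(s$n_plateau[1] - s$x_star[1]) / s$x_star[1], 0.1)
  expect_lt(abs(s$n_plateau[2] - s$x_star[2]) / s$x_star[2], 0.1)
  # plateau tracks theta * T(alpha, n_theta) within 20%
  expect_true(all(abs(s$N_plateau - s$N_theory) / s$N_theory < 0.2))
  expect_true(all(th$detail$survival_times > 0))
  expect_true(all(th$detail$surviving_sizes >= 1))
})

test_that("log-normal stimulus rates barely move the repertoire dynamics", {
  ln <- lognormal_experiment(sigma_grid = c(0, 1), M = 500, pM = 100,
                             theta = 50, t_max = 40, n_replicates = 2,
                             seed = 31)
  s <- ln$summary
  dN <- abs(s$N_plateau[1] - s$N_plateau[2])
  seN <- sqrt(s$N_plateau_se[1]^2 + s$N_plateau_se[2]^2)
  expect_lt(dN / s$N_plateau[1], 0.15)
  expect_lt(dN, 4 * seN + 0.1 * s$N_plateau[1])
  dn <- abs(s$n_plateau[1] - s$n_plateau[2])
  expect_lt(dn / s$n_plateau[1], 0.05)
})
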