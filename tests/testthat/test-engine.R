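# Compiled Gillespie engine: incremental caches versus scratch
# recomputation, determinism, conservation laws and degenerate regimes.

engine_run <- function(net, n0, mu = 1, theta = 0, n_theta = 4, p = 0.1,
                       t_max = 10, record_dt = 1, sd = 1, st = 2,
                       check = FALSE) {
  clonedyn:::cpp_gillespie_run(unname(net$patterns), net$stimulus_rates,
                               mu, theta, n_theta, p,
                               rep(as.integer(n0), length(net$patterns)),
                               t_max, record_dt, sd, st, check)
}

test_that("incremental caches agree with scratch recomputation after 1e4+ events", {
  set.seed(51)
  net <- generate_network(30, 40, 0.1, stimulus_rates = rep(5, 40))
  res <- engine_run(net, 5, theta = 2, t_max = 50, check = TRUE)
  expect_gt(sum(res$tallies), 1e4)
  chk <- res$cache_check
  expect_identical(chk$max_c_diff, 0)
  expect_identical(chk$sum_phi_diff, 0)
  expect_identical(chk$ntot_diff, 0)
  expect_lt(chk$max_lambda_rel_diff, 1e-9)
})

test_that("runs are reproducible from seeds and diverge across streams", {
  params <- model_params(M = 100, p = 0.1, N0 = 20, n0 = 5, theta = 2,
                         t_max = 5, seed = 7)
  a <- run_simulation(params)
  b <- run_simulation(params)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$fates, b$fates)
  params2 <- params
  params2$seeds$dynamics <- params$seeds$dynamics + 17L
  c <- run_simulation(params2)
  expect_false(identical(a$trajectory, c$trajectory))
})

test_that("counting identity and rate conservation hold along a run", {
  sim <- run_simulation(model_params(M = 120, p = 0.1, N0 = 40, n0 = 6,
                                     theta = 3, t_max = 20, seed = 9))
  expect_identity_holds(sim$trajectory, 120)
  # Sum of division rates equals total stimulus over recognised subsets
  gam <- sim$network$stimulus_rates
  expect_equal(sum(sim$final$Lambda), sum(gam[sim$final$c > 0]),
               tolerance = 1e-9)
  # S = mu * n + sum Lambda + theta at the horizon
  expect_equal(sim$final$S,
               1 * sum(sim$final$n) + sum(sim$final$Lambda) + 3,
               tolerance = 1e-9)
})

test_that("fates are consistent: irreversibility, censoring, fresh ids", {
  sim <- run_simulation(model_params(M = 80, p = 0.15, N0 = 25, n0 = 3,
                                     theta = 4, t_max = 15, seed = 13))
  f <- sim$fates
  expect_false(any(duplicated(f$clonotype_id)))
  expect_equal(nrow(f), 25 + sim$tallies[["thymic_arrivals"]],
               ignore_attr = TRUE)
  ext <- f[!f$censored, ]
  expect_true(all(ext$t_extinction > ext$t_birth))
  expect_true(all(is.na(f$t_extinction[f$censored])))
  # survivors at the horizon are exactly the censored clonotypes
  expect_setequal(sim$final$id, f$clonotype_id[f$censored])
  # thymic emigrants are born strictly after t = 0
  expect_true(all(f$t_birth[f$clonotype_id > 25] > 0))
  expect_true(all(f$max_size >= 1))
})

test_that("pure-death regime: every cell dies, no divisions", {
  set.seed(55)
  net <- generate_network(10, 12, 0.3, stimulus_rates = rep(1e-12, 12))
  res <- engine_run(net, 4, mu = 1, theta = 0, t_max = 50)
  expect_equal(res$tallies[["deaths"]], 40)
  expect_equal(res$tallies[["divisions"]], 0)
  expect_equal(res$trajectory$n_total[51], 0)
  expect_equal(res$trajectory$N_surviving[51], 0)
  # absorbing state: the trajectory is padded to the horizon
  expect_length(res$trajectory$t, 51)
})

test_that("no deaths: cell count non-decreasing; empty start builds up", {
  set.seed(56)
  net <- generate_network(6, 10, 0.4, stimulus_rates = rep(1, 10))
  res <- engine_run(net, 2, mu = 0, theta = 0, t_max = 3)
  expect_true(all(diff(res$trajectory$n_total) >= 0))
  expect_equal(res$tallies[["deaths"]], 0)

  sim0 <- run_simulation(model_params(M = 50, p = 0.2, N0 = 0, n0 = 1,
                                      theta = 5, n_theta = 4, t_max = 10,
                                      seed = 21))
  expect_equal(sim0$trajectory$n_total[1], 0)
  expect_gt(sim0$tallies[["thymic_arrivals"]], 0)
  expect_true(all(sim0$fates$t_birth > 0))
  expect_true(all(sim0$fates$phi >= 1))
})

test_that("sigma = 0 runs reduce exactly to the constant-rate engine", {
  p1 <- model_params(M = 60, p = 0.2, N0 = 15, n0 = 4, sigma = 0,
                     gamma = 7, t_max = 5, seed = 17)
  a <- run_simulation(p1)
  set.seed(p1$seeds$network)
  net <- generate_network(15, 60, 0.2, stimulus_rates = rep(7, 60))
  b <- run_simulation(p1, network = net)
  expect_identical(a$trajectory, b$trajectory)
})
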