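# Pure-R reference dynamics: division rates, event selection, incremental
# cache updates.

test_that("division rates share each subset's stimulus equally", {
  # sole recogniser absorbs the full stimulus, independent of its size
  net <- clonedyn:::new_recognition_network(
    M = 1L, p = 1, patterns = list(`1` = 1L), stimulus_rates = 10,
    next_id = 2L)
  st <- repertoire_state(net, c(`1` = 7L))
  expect_equal(unname(division_rates(st)), 10)

  # two equal clones sharing exactly one subset split it evenly
  net2 <- clonedyn:::new_recognition_network(
    M = 1L, p = 1, patterns = list(`1` = 1L, `2` = 1L), stimulus_rates = 6,
    next_id = 3L)
  st2 <- repertoire_state(net2, c(`1` = 5L, `2` = 5L))
  expect_equal(unname(division_rates(st2)), c(3, 3))

  # hand-computed three-clonotype fixture
  st3 <- hand_state()
  expect_equal(unname(st3$Lambda), c(1.8, 4.2, 4))
  expect_equal(unname(division_rates(st3)), c(1.8, 4.2, 4))
})

test_that("total division rate conserves the recognised stimulus", {
  set.seed(21)
  for (rep in 1:5) {
    net <- generate_network(20, 30, 0.2,
                            stimulus_rates = runif(30, 0.5, 2))
    st <- repertoire_state(net, sample(1:6, 20, replace = TRUE) |>
                             setNames(names(net$patterns)))
    expect_equal(sum(st$Lambda),
                 sum(net$stimulus_rates[st$c > 0]))
  }
})

test_that("total event rate sums deaths, divisions and thymic input", {
  net <- clonedyn:::new_recognition_network(
    M = 1L, p = 1, patterns = list(`1` = 1L), stimulus_rates = 10,
    next_id = 2L)
  st <- repertoire_state(net, c(`1` = 1L))
  expect_equal(total_event_rate(st, model_params(mu = 1, theta = 0,
                                                 M = 1, p = 1, N0 = 1)), 11)
  # empty repertoire: only thymic arrivals are possible
  net0 <- generate_network(0, 5, 0.5, seed = 1)
  st0 <- repertoire_state(net0, integer(0))
  expect_equal(total_event_rate(st0, model_params(theta = 5, M = 5, p = 0.5,
                                                  N0 = 0)), 5)
  # hand fixture: S = 0.5 * 9 + 10 + 2
  st3 <- hand_state()
  expect_equal(total_event_rate(st3, model_params(mu = 0.5, theta = 2,
                                                  M = 4, p = 0.5, N0 = 3)),
               16.5)
})

test_that("event selection frequencies are proportional to the rates", {
  st <- hand_state()
  params <- model_params(mu = 0.5, theta = 2, M = 4, p = 0.5, N0 = 3)
  S <- total_event_rate(st, params)
  prob <- c(thymic = 2,
            d1 = 0.5 * 2, d2 = 0.5 * 3, d3 = 0.5 * 4,
            b1 = 1.8, b2 = 4.2, b3 = 4) / S
  set.seed(31)
  n <- 4e4
  draws <- character(n)
  for (i in seq_len(n)) {
    ev <- select_event(st, params)
    draws[i] <- if (ev$type == "thymic") "thymic"
                else paste0(if (ev$type == "death") "d" else "b", ev$id)
  }
  counts <- table(factor(draws, levels = names(prob)))
  gof <- stats::chisq.test(counts, p = prob)
  expect_gt(gof$p.value, 1e-3)
  freq <- as.numeric(counts) / n
  expect_lt(max(abs(freq - prob)), 0.01)
})

test_that("with no stimulus and no thymus the repertoire dies out", {
  set.seed(41)
  net <- generate_network(5, 6, 0.5, stimulus_rates = rep(1e-12, 6))
  st <- repertoire_state(net, 3)
  params <- model_params(mu = 1, theta = 0, M = 6, p = 0.5, N0 = 5, n0 = 3)
  types <- character(0)
  repeat {
    out <- gillespie_step(st, params)
    if (out$event$type == "absorbed") break
    types <- c(types, out$event$type)
    st <- out$state
  }
  expect_length(st$counts, 0)
  expect_true(all(types == "death"))
  expect_length(types, 15)  # every founding cell died exactly once
})

test_that("with no deaths the total cell count is non-decreasing", {
  set.seed(42)
  net <- generate_network(4, 8, 0.5, stimulus_rates = rep(2, 8))
  st <- repertoire_state(net, 2)
  params <- model_params(mu = 0, theta = 0, M = 8, p = 0.5, N0 = 4, n0 = 2)
  tot <- sum(st$counts)
  for (i in 1:200) {
    st <- gillespie_step(st, params)$state
    expect_gte(sum(st$counts), tot)
    tot <- sum(st$counts)
  }
})

test_that("incremental caches match scratch recomputation along a run", {
  set.seed(43)
  net <- generate_network(15, 20, 0.25, stimulus_rates = runif(20, 1, 3))
  st <- repertoire_state(net, 4)
  params <- model_params(mu = 1, theta = 1.5, M = 20, p = 0.25,
                         N0 = 15, n0 = 4)
  for (i in 1:300) {
    out <- gillespie_step(st, params)
    if (out$event$type == "absorbed") break
    st <- out$state
    if (i %% 50 == 0) {
      ref <- recompute_state(st)
      expect_identical(st$c, ref$c)
      expect_equal(st$Lambda[order(names(st$Lambda))],
                   ref$Lambda[order(names(ref$Lambda))], tolerance = 1e-12)
      # conservation after every mutation of the state
      expect_equal(sum(st$Lambda),
                   sum(st$network$stimulus_rates[st$c > 0]),
                   tolerance = 1e-12)
    }
  }
  # thymic arrivals extended the id space monotonically
  expect_gte(st$network$next_id, 16L)
})
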