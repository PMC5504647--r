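# Metropolis acceptance, exchange rule, MC chain, REMC loop.

test_that("Boltzmann acceptance probability clamps its exponent", {
  expect_equal(boltz_acceptance_prob(5, 5, 2), 1)
  expect_equal(boltz_acceptance_prob(0, 200, 2), exp(-40))
  expect_equal(boltz_acceptance_prob(200, 0, 2), exp(40))
  expect_error(boltz_acceptance_prob(0, 1, 0), "temperature")
})

test_that("Metropolis decision matches hand values on both paths", {
  # downhill: accepted for any u
  for (u in c(0, 0.5, 1)) {
    expect_true(metropolis_accept(1, 0, 2, u))
    expect_true(metropolis_accept(1, 0, 2, u, method = "exponential"))
  }
  # boltz factor -1: exp(-1) ~ 0.368 < 0.5 -> rejected
  expect_false(metropolis_accept(0, 2, 2, 0.5))
  expect_true(metropolis_accept(0, 2, 2, 0.3))
  expect_error(metropolis_accept(0, 1, 1, 1.5), "u must")
})

test_that("fast path and exponential path agree exactly", {
  set.seed(13)
  n <- 1e4
  last <- rnorm(n, 0, 30); sc <- rnorm(n, 0, 30)
  tt <- runif(n, 0.1, 10); u <- runif(n)
  expect_identical(metropolis_accept(last, sc, tt, u, method = "fast"),
                   metropolis_accept(last, sc, tt, u, method = "exponential"))
})

test_that("exchange Delta follows the two-replica formula", {
  expect_equal(exchange_delta(3, 3, 2, 4), 0)
  expect_equal(exchange_delta(-2, 7, 3, 3), 0)
  expect_equal(exchange_delta(-10, -5, 2, 4), 1.25)
  # algebraic identity: swapping both argument pairs preserves Delta
  set.seed(2)
  for (i in 1:100) {
    E <- rnorm(2, 0, 10); Tt <- runif(2, 0.5, 5)
    expect_equal(exchange_delta(E[1], E[2], Tt[1], Tt[2]),
                 exchange_delta(E[2], E[1], Tt[2], Tt[1]))
  }
  expect_error(exchange_delta(0, 0, -1, 2), "must be > 0")
})

test_that("attempt_exchange: certain, impossible and stochastic regimes", {
  mk <- function(E_i, E_j, T_i = 2, T_j = 4)
    list(i = replica_state(1, NULL, E_i, 1L, T_i),
         j = replica_state(2, NULL, E_j, 2L, T_j))
  r <- mk(-5, -10)                      # Delta = (1/4-1/2)(5) = -1.25
  expect_true(attempt_exchange(r$i, r$j, u = 0.999)$accepted)
  big <- mk(-400, 0)                    # Delta = 100 > 75
  expect_false(attempt_exchange(big$i, big$j, u = 0)$accepted)
  # accepted swap exchanges rungs, labels travel with states
  out <- attempt_exchange(r$i, r$j, u = 0.5)
  expect_equal(out$rep_i$temp_index, 2L)
  expect_equal(out$rep_j$temp_index, 1L)
  expect_equal(out$rep_i$label, 1)
  # applying the same accepted exchange again restores the assignment
  back <- attempt_exchange(out$rep_j, out$rep_i, u = 0.5)
  expect_equal(back$rep_j$temp_index, 2L)
  expect_equal(back$rep_i$temp_index, 1L)
  far <- list(i = replica_state(1, NULL, 0, 1L, 2),
              j = replica_state(2, NULL, 0, 3L, 4))
  expect_error(attempt_exchange(far$i, far$j, 0.5), "neighbouring")
})

test_that("flat landscape accepts every move", {
  flat <- energy_model(function(s) 0)
  res <- mc_boltzmann(0, 2, 500, flat, function(s, k) s + rnorm(1), seed = 1)
  expect_equal(res$acceptance_rate, 1)
  expect_true(all(res$archive$accepted))
})

test_that("MC occupancy approaches the closed-form Boltzmann weights", {
  sys <- make_discrete_system(c(0, 1, 2))
  res <- mc_boltzmann(1L, 2, 1e5, sys$model, sys$proposer, seed = 5)
  occ <- tabulate(unlist(archive_states(res$archive)), 3) / 1e5
  expect_lt(0.5 * sum(abs(occ - sys$boltzmann(2))), 0.03)
})

test_that("rejected steps archive a duplicate of the previous sample", {
  sys <- make_discrete_system(c(0, 5))
  res <- mc_boltzmann(1L, 0.5, 200, sys$model, sys$proposer, seed = 2)
  st <- unlist(archive_states(res$archive))
  rej <- which(!res$archive$accepted)
  rej <- rej[rej > 1]
  expect_true(length(rej) > 0)
  expect_true(all(st[rej] == st[rej - 1]))
  expect_equal(res$archive$tscore[1:res$archive$n], sys$energies[st])
})

test_that("identical seeds give bit-identical archives", {
  dw <- make_double_well(3)
  cfg <- sampler_config(numR = 4, numC = 6, seed = 7, n_cycles = 5,
                        selector = "hmo")
  a <- remc_run(0.5, dw$model, dw$proposer, cfg)
  b <- remc_run(0.5, dw$model, dw$proposer, cfg)
  expect_identical(archive_table(a$archive), archive_table(b$archive))
  expect_identical(archive_states(a$archive), archive_states(b$archive))
  expect_identical(a$occupancy, b$occupancy)
})

test_that("REMC with one replica degenerates to plain MC", {
  dw <- make_double_well(4, asymmetry = 1)
  cfg <- sampler_config(numR = 1, numC = 5, maxT = 2, seed = 31,
                        n_cycles = 8, selector = "last")
  rem <- remc_run(-1, dw$model, dw$proposer, cfg)
  mc <- mc_boltzmann(-1, 2, 40, dw$model, dw$proposer,
                     stream = rng_stream(derive_stream_seed(31, 1L)))
  expect_identical(rem$archive$tscore[1:40], mc$archive$tscore[1:40])
  expect_identical(archive_states(rem$archive), archive_states(mc$archive))
  expect_identical(rem$archive$accepted[1:40], mc$archive$accepted[1:40])
})

test_that("REMC bookkeeping invariants hold", {
  dw <- make_double_well(3)
  cfg <- sampler_config(numR = 6, numC = 4, seed = 3, n_cycles = 10)
  res <- remc_run(0, dw$model, dw$proposer, cfg)
  # archive length and strictly increasing steps
  expect_equal(archive_length(res$archive), 6 * 4 * 10)
  expect_true(all(diff(res$archive$step[1:res$archive$n]) == 1))
  # temperature multiset invariant: every occupancy row is a permutation
  for (cy in seq_len(nrow(res$occupancy)))
    expect_setequal(res$occupancy[cy, ], 1:6)
  # even-pair scheme: only odd low rungs are ever attempted
  expect_true(all(res$exchanges$rung_low %in% c(1, 3, 5)))
  # final replica energies are consistent with the model
  for (r in res$replicas)
    expect_equal(r$energy, dw$model$score(r$state))
})

test_that("constant-energy model accepts every exchange", {
  flat <- energy_model(function(s) 1)
  cfg <- sampler_config(numR = 4, numC = 3, seed = 9, n_cycles = 6)
  res <- remc_run(0, flat, function(s, k) s + rnorm(1), cfg)
  expect_true(all(res$exchanges$accepted))
  expect_true(all(res$exchanges$delta == 0))
})

test_that("configuration preconditions are enforced", {
  expect_error(sampler_config(numR = 4, minT = 2, maxT = 2), "minT < maxT")
  expect_error(sampler_config(numR = 0), "numR")
  expect_error(temperature_ladder(0, 2, 4), "minT")
  ld <- temperature_ladder(2, 4, 16)
  expect_equal(ld[1], 2)
  expect_equal(ld[16], 4)
  expect_true(all(diff(ld) > 0))
  # geometric spacing: constant ratio
  expect_equal(var(diff(log(ld))), 0, tolerance = 1e-20)
})

test_that("method dispatch and the mc warning behave as documented", {
  dw <- make_double_well(3)
  cfg <- sampler_config(numR = 2, numC = 4, seed = 1, n_cycles = 3)
  expect_warning(run_sampler("mc", 0, dw$model, dw$proposer, cfg),
                 "ignored")
  res <- run_sampler("mo-remc", 0, dw$model, dw$proposer, cfg)
  expect_s3_class(res, "remc_result")
  expect_equal(res$config$selector, "mo")
})

test_that("early stop fires at the first qualifying state", {
  dw <- make_double_well(0.5)
  visit <- stop_when_state(function(x) x > 0.9)
  cfg <- sampler_config(numR = 2, numC = 5, seed = 12, n_cycles = 200)
  res <- remc_run(-1, dw$model, dw$proposer, cfg, stop_fn = visit)
  expect_false(is.na(res$stopped_at))
  st <- unlist(archive_states(res$archive))
  first <- min(which(st > 0.9))
  expect_equal(res$stopped_at, res$archive$step[first])
})
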