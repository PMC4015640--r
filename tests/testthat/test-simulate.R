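# stochastic update schemes and their estimators

test_that("per-step probabilities and time steps follow each scheme", {
  toy <- toy_model()
  # varying-step random sequential from [0 1]: entry 0.6, exit 0.4, dt 1
  sp <- step_probabilities(c(0, 1), toy, "rs_varying")
  expect_equal(sp$events$select_prob[sp$events$label == "alpha"], 0.6)
  expect_equal(sp$events$select_prob[sp$events$label == "beta"], 0.4)
  expect_equal(sp$dt, 1)
  # a single allowed event is chosen with probability 1, dt = 1/gamma
  sp1 <- step_probabilities(c(1, 1, 0),
                            translation_model(3, 2, alpha = 1, beta = 1,
                                              gamma = 0.5), "rs_varying")
  expect_equal(sp1$events$select_prob[sp1$events$type == "hop"], 1)
  expect_equal(sp1$dt, 2)
  # conventional: entry fires from [0 0] with (1/3) * 0.6 = 0.2, dt = 1/3
  sc <- step_probabilities(c(0, 0), toy, "conventional")
  expect_equal(sc$events$fire_prob[sc$events$label == "alpha"], 0.2)
  expect_equal(sc$dt, 1 / 3)
  # alternative: the hop is selected with probability gamma/(n-r+2) = 1/3
  sa <- step_probabilities(c(1, 0), toy, "alternative")
  expect_equal(sa$events$select_prob[sa$events$label == "gamma_1"], 1 / 3)
  # efficient fixed: selection (0.3, 0.5, 0.2), dt = 1/2
  se <- step_probabilities(c(0, 0), toy, "efficient_fixed")
  expect_equal(se$events$select_prob, c(0.3, 0.5, 0.2))
  expect_equal(se$dt, 0.5)
  # parallel with equal rates: every allowed event fires with probability 1
  mu <- translation_model(6, 2, alpha = 1, beta = 1, gamma = 1)
  spp <- step_probabilities(c(1, 1, 0, 1, 1, 0), mu, "parallel")
  expect_true(all(spp$events$fire_prob[spp$events$allowed] == 1))
})

test_that("stationary skip probability of the fixed-step scheme matches the exact law", {
  # 1 - sum_i p_i psi_bar_i evaluated with the exact stationary density
  toy <- toy_model()
  ss <- pbn_steady_state(toy)
  fl <- event_fluxes(ss)
  p <- event_table(toy)$rate / sum(event_table(toy)$rate)
  expect_equal(1 - sum(p * fl$psi_bar), 0.64, tolerance = 1e-12)
  sim <- simulate(toy, nsim = 60000, seed = 21, algorithm = "efficient_fixed")
  expect_equal(sim$skip_fraction, 0.64, tolerance = 0.02)
})

test_that("identical seed and configuration reproduce the run exactly", {
  m <- translation_model(8, 2, alpha = 0.8, beta = 0.6, gamma = 1)
  for (alg in c("rs_varying", "conventional", "alternative",
                "efficient_fixed", "parallel")) {
    a <- simulate(m, nsim = 3000, seed = 99, algorithm = alg,
                  record_states = TRUE, record_events = TRUE)
    b <- simulate(m, nsim = 3000, seed = 99, algorithm = alg,
                  record_states = TRUE, record_events = TRUE)
    expect_identical(a$events_log, b$events_log)
    expect_identical(a$rho, b$rho)
    expect_identical(a$state_freq, b$state_freq)
    d <- simulate(m, nsim = 3000, seed = 100, algorithm = alg)
    expect_false(identical(a$c, d$c))
  }
})

test_that("estimators are time-weighted and internally consistent", {
  m <- translation_model(6, 2, alpha = 1, beta = 0.4, gamma = c(1, 2, 0.5, 1))
  sim <- simulate(m, nsim = 30000, seed = 5, record_states = TRUE)
  expect_equal(sum(sim$state_freq), 1, tolerance = 1e-12)
  expect_true(all(sim$rho >= 0 & sim$rho <= 1))
  expect_equal(sim$mean_occupancy, sum(sim$rho) / 2, tolerance = 1e-12)
  # rho from the state histogram equals the accumulated rho
  st <- enumerate_states(m)
  keys <- names(sim$state_freq)
  occ <- vapply(seq_len(m$n), function(i)
    sum(sim$state_freq * vapply(keys, function(k)
      as.integer(substr(k, i, i)), integer(1))), numeric(1))
  expect_equal(occ, sim$rho, tolerance = 1e-10)
  # varying-step scheme never skips
  expect_identical(sim$skip_fraction, 0)
  expect_error(simulate(m, nsim = 100, burn_in = 100), "burn_in")
})

test_that("all random-sequential variants agree with the exact solution", {
  toy <- toy_model()
  exact <- pbn_steady_state(toy)
  for (alg in c("rs_varying", "conventional", "alternative",
                "efficient_fixed")) {
    sim <- simulate(toy, nsim = 60000, seed = 31, algorithm = alg)
    expect_lt(abs(sim$c - exact$c), 0.008)
    expect_lt(max(abs(sim$rho - exact$rho)), 0.012)
  }
  # a footprint-2 lattice with non-uniform rates, against the master equation
  m <- translation_model(4, 2, alpha = 1, beta = 1, gamma = c(1, 0.5))
  ex <- pbn_steady_state(m)
  for (alg in c("rs_varying", "efficient_fixed")) {
    sim <- simulate(m, nsim = 60000, seed = 32, algorithm = alg)
    expect_lt(abs(sim$c - ex$c), 0.01)
    expect_lt(max(abs(sim$rho - ex$rho)), 0.015)
  }
})

test_that("rates above one are rescaled in the probability-interpretation schemes", {
  m <- translation_model(5, 1, alpha = 2.5, beta = 3, gamma = 4)
  ex <- pbn_steady_state(m)
  for (alg in c("conventional", "alternative")) {
    sim <- simulate(m, nsim = 80000, seed = 41, algorithm = alg)
    expect_lt(abs(sim$c - ex$c) / ex$c, 0.05)
  }
})

test_that("state frequencies converge to the exact stationary density", {
  toy <- toy_model()
  ss <- pbn_steady_state(toy)
  sim <- simulate(toy, nsim = 80000, seed = 8, record_states = TRUE)
  expect_lt(max(abs(sim$state_freq[names(ss$pi)] - ss$pi)), 0.01)
})

test_that("the parallel rule speeds translation and empties the first codon", {
  m <- reduced_fig3(1)
  rs <- simulate(m, nsim = 30000, seed = 3)
  par <- simulate(m, nsim = 30000, seed = 3, algorithm = "parallel")
  expect_gt(par$c, rs$c)
  # first-codon depletion under the parallel rule, at the full lattice
  # geometry (the effect is footprint-dependent)
  m50 <- translation_model(50, 12, alpha = 1, beta = 0.5, gamma = 1)
  rs50 <- simulate(m50, nsim = 25000, seed = 3)
  par50 <- simulate(m50, nsim = 25000, seed = 3, algorithm = "parallel")
  expect_gt(par50$c, rs50$c)
  expect_lt(par50$rho[1], rs50$rho[1])
})

test_that("an empty event set is an absorbing state, handled gracefully", {
  m <- translation_model(4, 2, alpha = 0, beta = 1, gamma = 1)
  sim <- simulate(m, nsim = 1000, seed = 1)
  expect_true(sim$degenerate)
  expect_identical(sim$c, 0)
  simp <- simulate(m, nsim = 1000, seed = 1, algorithm = "parallel")
  expect_true(simp$degenerate)
})
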