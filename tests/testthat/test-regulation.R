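# slow codons, premature stop codons, initiation feedback

test_that("slow-codon profiles replace only the requested rates", {
  m <- translation_model(50, 12, alpha = 1, beta = 1, gamma = 1)
  s1 <- with_slow_codons(m, 25, 0.2)
  expect_equal(unname(s1$gamma[as.character(25)]), 0.2)
  expect_equal(sum(s1$gamma != 1), 1L)
  s2 <- with_slow_codons(m, c(25, 26), 0.2)
  expect_equal(unname(s2$gamma[as.character(c(25, 26))]), c(0.2, 0.2))
  expect_error(with_slow_codons(m, 5, 0.2), "hop range")
  expect_error(with_slow_codons(m, 50, 0.2), "hop range")
  # replacing with the base rate leaves the model unchanged
  expect_equal(with_slow_codons(m, 25, 1)$events, m$events)
})

test_that("consecutive slow codons are slower than a single one, except in the Petri net", {
  c_single <- pbn_steady_state(reduced_fig4(0.1))$c
  c_double <- pbn_steady_state(reduced_fig4(0.1, double = TRUE))$c
  expect_lt(c_double, c_single)
  s_single <- simulate(reduced_fig4(0.1), 60000, seed = 11)$c
  s_double <- simulate(reduced_fig4(0.1, TRUE), 60000, seed = 12)$c
  expect_lt(s_double, s_single)
  expect_identical(petri_translation_rate(reduced_fig4(0.1)),
                   petri_translation_rate(reduced_fig4(0.1, TRUE)))
})

test_that("full readthrough is the baseline and zero readthrough blocks the lattice", {
  base <- translation_model(8, 2, alpha = 1, beta = 0.5, gamma = 1)
  full <- translation_model(8, 2, alpha = 1, beta = 0.5, gamma = 1,
                            premature_stop = list(position = 4, mu = 1))
  expect_equal(unname(pbn_steady_state(full)$pi[names(pbn_steady_state(base)$pi)]),
               unname(pbn_steady_state(base)$pi), tolerance = 1e-12)
  none <- translation_model(8, 2, alpha = 1, beta = 0.5, gamma = 1,
                            premature_stop = list(position = 4, mu = 0))
  ssn <- pbn_steady_state(none)
  expect_equal(ssn$rho[8], 0)
  expect_equal(ssn$c, 0)
})

test_that("the dissociation event clears the footprint and matches the master equation", {
  m <- translation_model(6, 2, alpha = 1, beta = 0.5, gamma = 1,
                         premature_stop = list(position = 3, mu = 0.4))
  # event table: hop at 3 carries mu*gamma, dissociation (1-mu)*gamma
  ev <- event_table(m)
  expect_equal(ev$rate[ev$label == "gamma_3"], 0.4)
  expect_equal(ev$rate[ev$label == "dissoc_3"], 0.6)
  expect_identical(apply_event(c(0, 1, 1, 0, 0, 0), "dissoc_3", m),
                   c(0L, 0L, 0L, 0L, 0L, 0L))
  # disallowed (codon 4 occupied): identity
  expect_identical(apply_event(c(1, 1, 1, 1, 0, 0), "dissoc_3", m),
                   c(1L, 1L, 1L, 1L, 0L, 0L))
  expect_equal(unname(pbn_steady_state(m)$pi),
               unname(ctmc_stationary(m)[names(pbn_steady_state(m)$pi)]),
               tolerance = 1e-10)
})

test_that("translation rate grows with readthrough and the branch fluxes balance", {
  mus <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  cs <- vapply(mus, function(mu)
    pbn_steady_state(reduced_fig5(mu))$c, numeric(1))
  expect_equal(cs[1], 0)
  expect_true(all(diff(cs) > 0))
  # two-branch balance at the stop codon: upstream flux splits into
  # readthrough + dissociation; downstream flux equals the readthrough flux
  ss <- pbn_steady_state(reduced_fig5(0.5))
  fl <- event_fluxes(ss)
  up <- fl$flux[fl$type %in% c("entry", "hop") & fl$pos < 10]
  down <- fl$flux[fl$pos > 10 & fl$type %in% c("hop", "exit")]
  through <- fl$flux[fl$label == "gamma_10"]
  dis <- fl$flux[fl$label == "dissoc_10"]
  expect_lt(diff(range(up)), 1e-10)
  expect_lt(diff(range(down)), 1e-10)
  expect_equal(unname(up[1]), through + dis, tolerance = 1e-10)
  expect_equal(unname(down[1]), through, tolerance = 1e-10)
  expect_equal(ss$c, unname(through), tolerance = 1e-10)
})

test_that("simulation and exact solver agree with a premature stop, parallel is faster", {
  m <- reduced_fig5(0.5)
  ex <- pbn_steady_state(m)$c
  rs <- simulate(m, nsim = 50000, seed = 7)
  expect_lt(abs(rs$c - ex) / ex, 0.08)
  par <- simulate(m, nsim = 50000, seed = 7, algorithm = "parallel")
  expect_gt(par$c, rs$c)
})

test_that("feedback fixed point reduces to the open loop at k_I = 0", {
  m <- translation_model(10, 2, beta = 1, gamma = 1,
                         feedback = list(alpha_I = 1, k_I = 0, d_I = 1,
                                         rho_m = 1))
  fp <- feedback_fixed_point(m)
  expect_equal(fp$alpha, 1)
  open <- pbn_steady_state(translation_model(10, 2, alpha = 1, beta = 1,
                                             gamma = 1))$c
  expect_equal(fp$c, open, tolerance = 1e-9)
  expect_equal(fp$rho_I, fp$c, tolerance = 1e-8)
  expect_error(feedback_fixed_point(translation_model(2, 1, alpha = 1,
                                                      beta = 1, gamma = 1)),
               "feedback")
})

test_that("stronger autoregulation and slower degradation depress translation", {
  mk <- function(k_I, d_I) translation_model(10, 2, beta = 1, gamma = 1,
    feedback = list(alpha_I = 1, k_I = k_I, d_I = d_I, rho_m = 1))
  cs <- vapply(c(0, 0.5, 1, 2, 4), function(k)
    feedback_fixed_point(mk(k, 1))$c, numeric(1))
  expect_true(all(diff(cs) < 0))
  fps <- lapply(c(0.25, 0.5, 1, 2), function(d) feedback_fixed_point(mk(2, d)))
  c_d <- vapply(fps, `[[`, numeric(1), "c")
  rho_d <- vapply(fps, `[[`, numeric(1), "rho_I")
  a_d <- vapply(fps, `[[`, numeric(1), "alpha")
  expect_true(all(diff(c_d) > 0))     # faster degradation -> faster translation
  expect_true(all(diff(rho_d) < 0))   # ... and less protein
  expect_true(all(diff(a_d) > 0))
  # c* and rho_I* proportional with factor rho_m / d_I
  for (i in seq_along(fps))
    expect_equal(fps[[i]]$rho_I, fps[[i]]$c * 1 / c(0.25, 0.5, 1, 2)[i],
                 tolerance = 1e-8)
})

test_that("stochastic and fixed-point feedback couplings agree", {
  m <- translation_model(10, 2, beta = 1, gamma = 1,
                         feedback = list(alpha_I = 1, k_I = 1, d_I = 1,
                                         rho_m = 1))
  fp <- feedback_fixed_point(m)
  sim <- simulate(m, nsim = 120000, seed = 5)
  expect_lt(abs(sim$c - fp$c) / fp$c, 0.1)
  expect_lt(abs(sim$rho_I_mean - fp$rho_I) / fp$rho_I, 0.1)
  # pathwise ergodic identity: time-averaged rho_I = c_hat * rho_m / d_I
  expect_lt(abs(sim$rho_I_mean - sim$c * 1 / 1), 5 / sim$total_time)
  # the alternative Euler coupling lands in the same place
  sim2 <- simulate(m, nsim = 120000, seed = 6, feedback_scheme = "euler")
  expect_lt(abs(sim2$c - fp$c) / fp$c, 0.1)
  # k_I = 0 matches a feedback-free run with the same seed
  m0 <- translation_model(10, 2, beta = 1, gamma = 1,
                          feedback = list(alpha_I = 1, k_I = 0, d_I = 1,
                                          rho_m = 1))
  s0 <- simulate(m0, nsim = 40000, seed = 9)
  plain <- simulate(translation_model(10, 2, alpha = 1, beta = 1, gamma = 1),
                    nsim = 40000, seed = 9)
  expect_equal(s0$c, plain$c, tolerance = 1e-12)
})

test_that("protein decays exponentially and production is event-driven", {
  # alpha_I = 0, one ribosome ready to exit: the single step is fully
  # deterministic -- exact decay over dt = 1/beta, then +rho_m at exit
  m <- translation_model(6, 2, beta = 0.5, gamma = 1,
                         feedback = list(alpha_I = 0, k_I = 1, d_I = 0.5,
                                         rho_m = 1))
  sim <- simulate(m, nsim = 10, burn_in = 0, seed = 3, rho_I0 = 4,
                  init = c(0, 0, 0, 0, 1, 1))
  expect_identical(sim$steps_run, 2L)   # exit, then absorbing empty lattice
  expect_true(sim$degenerate)
  expect_equal(sim$rho_I[1], 4 * exp(-0.5 * 2) + 1, tolerance = 1e-12)
  # with alpha_I = 0 from the empty lattice nothing can happen at all
  s0 <- simulate(m, nsim = 10, burn_in = 0, seed = 3)
  expect_true(s0$degenerate)
})
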