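# exact stationary solver: transition matrices, state density, profiles

test_that("toy model reproduces the printed transition matrix and solution", {
  toy <- toy_model()
  tm <- build_transition_matrix(toy)
  expect_identical(tm$states$key, c("11", "10", "01", "00"))
  expect_equal(as.matrix(tm$M), toy_ME_expected, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.matrix(tm$M)[1, 1], 0.8, tolerance = 1e-12)
  ss <- pbn_steady_state(toy)
  expect_equal(unname(ss$pi), unname(toy_pi_expected), tolerance = 1e-12)
  expect_equal(ss$rho, c(0.6, 0.6), tolerance = 1e-12)
  expect_equal(ss$c, 0.24, tolerance = 1e-12)
})

test_that("per-event matrices are 0/1 column-stochastic and assemble M_E", {
  for (m in list(toy_model(),
                 translation_model(6, 2, alpha = 0.7, beta = 0.3,
                                   gamma = c(1, 0.5, 2, 0.8)),
                 translation_model(6, 2, alpha = 1, beta = 0.5, gamma = 1,
                                   premature_stop = list(position = 3,
                                                         mu = 0.4)))) {
    st <- enumerate_states(m)
    ev <- event_table(m)
    Ms <- lapply(seq_len(nrow(ev)), function(k)
      build_event_matrix(ev[k, , drop = FALSE], m, st))
    for (Mi in Ms) {
      expect_true(all(Matrix::colSums(Mi) == 1))
      expect_true(all(Mi@x == 1))
    }
    p <- ev$rate / sum(ev$rate)
    ME_rule <- Reduce(`+`, Map(function(Mi, pk) pk * Mi, Ms, p))
    tm <- build_transition_matrix(m)
    expect_equal(as.matrix(ME_rule), as.matrix(tm$M), tolerance = 1e-12)
    expect_equal(unname(Matrix::colSums(tm$M)), rep(1, nrow(tm$M)),
                 tolerance = 1e-12)
  }
  # toy: entry matrix maps [0 1] -> [1 1]; exit maps [1 1] -> [1 0]
  toy <- toy_model()
  st <- enumerate_states(toy)
  Ment <- as.matrix(build_event_matrix("alpha", toy, st))
  expect_identical(Ment[, 3], c(1, 0, 0, 0))   # column [0 1]
  Mexit <- as.matrix(build_event_matrix("beta", toy, st))
  expect_identical(Mexit[, 1], c(0, 1, 0, 0))  # exit: [1 1] -> [1 0]
  expect_identical(Mexit[, 2], c(0, 1, 0, 0))  # identity on [1 0]
  # single-state restricted space: M_E is the 1x1 identity
  m1 <- translation_model(1, 1, alpha = 0, beta = 1)
  expect_equal(as.matrix(build_transition_matrix(m1)$M),
               matrix(1, 1, 1), ignore_attr = TRUE)
})

test_that("Boolean event rules equal the predicate-plus-apply semantics", {
  for (nr in list(c(6L, 2L), c(8L, 3L), c(6L, 1L))) {
    m <- translation_model(nr[1], nr[2], alpha = 1, beta = 1, gamma = 1,
                           premature_stop = if (nr[2] > 1)
                             list(position = nr[2] + 1L, mu = 0.5) else NULL)
    st <- enumerate_states(m)
    ev <- event_table(m)
    for (k in seq_len(nrow(ev))) {
      rule <- boolean_event_rule(ev[k, , drop = FALSE], m)
      for (j in seq_along(st$key)) {
        x <- st$x[j, ]
        via_rule <- rule(x)
        via_pred <- if (ev$label[k] %in% allowed_events(x, m)$label)
          apply_event(x, ev[k, , drop = FALSE], m) else x
        expect_identical(via_rule, via_pred,
                         info = paste(nr[1], nr[2], ev$label[k], st$key[j]))
      }
    }
  }
})

test_that("stationary law matches the continuous-time master equation", {
  set.seed(404)
  cases <- list(c(4L, 2L), c(5L, 2L), c(6L, 3L), c(6L, 1L), c(5L, 1L),
                c(6L, 2L))
  for (nr in cases) {
    n <- nr[1]; r <- nr[2]
    m <- translation_model(n, r, alpha = runif(1, 0.2, 2),
                           beta = runif(1, 0.2, 2),
                           gamma = runif(n - r, 0.2, 2))
    ss <- pbn_steady_state(m)
    po <- ctmc_stationary(m)
    expect_equal(unname(ss$pi), unname(po[names(ss$pi)]), tolerance = 1e-9)
    # power iteration agrees with the linear solve
    pp <- pbn_steady_state(m, method = "power")
    expect_equal(unname(pp$pi), unname(ss$pi), tolerance = 1e-8)
  }
})

test_that("stationary fluxes are balanced and bounded", {
  set.seed(11)
  for (i in 1:4) {
    n <- sample(4:8, 1); r <- sample(1:min(3, n - 1), 1)
    m <- translation_model(n, r, alpha = runif(1, 0.1, 2),
                           beta = runif(1, 0.1, 2),
                           gamma = runif(n - r, 0.1, 2))
    ss <- pbn_steady_state(m)
    fl <- event_fluxes(ss)
    expect_lt(diff(range(fl$flux)), 1e-10)
    expect_equal(fl$flux[1], ss$c, tolerance = 1e-10)
    expect_gte(ss$c, 0)
    expect_lte(ss$c, min(event_table(m)$rate) + 1e-12)
  }
})

test_that("state ranking finds the most and least likely configurations", {
  ss <- pbn_steady_state(toy_model())
  rk <- rank_states(ss, k = 1)
  expect_identical(rk$top$state, "11")
  expect_equal(rk$top$density, 0.36, tolerance = 1e-12)
  expect_identical(rk$bottom$state, "00")
  expect_equal(rk$bottom$density, 0.16, tolerance = 1e-12)
  # k larger than the state count is clipped
  expect_identical(nrow(rank_states(ss, k = 99)$top), 4L)
  # ties break by canonical order
  m1 <- translation_model(1, 1, alpha = 1, beta = 1)
  rk1 <- rank_states(pbn_steady_state(m1), k = 2)
  expect_identical(rk1$top$state, c("1", "0"))
})

test_that("figure-scale state space solves exactly and sums to one", {
  m <- translation_model(50, 12, alpha = 1, beta = 0.1, gamma = 1,
                         premature_stop = list(position = 25, mu = 0.5))
  ss <- pbn_steady_state(m)
  expect_identical(length(ss$pi), 1113L)
  expect_equal(sum(ss$pi), 1, tolerance = 1e-12)
  expect_true(all(ss$pi >= 0))
  M <- ss$transition_matrix
  expect_lt(max(abs(as.numeric(M %*% ss$pi) - ss$pi)), 1e-12)
})

test_that("exact rate sensitivities match an independent stencil", {
  toy <- toy_model()
  s_beta <- rate_sensitivity(toy, "beta", target = "c", delta = 1e-5)
  # independent 5-point refit at shrinking delta
  cb <- function(b) pbn_steady_state(
    translation_model(2, 1, alpha = 0.6, beta = b, gamma = 1))$c
  d <- 1e-3
  stencil <- (cb(0.4 - 2 * d) - 8 * cb(0.4 - d) + 8 * cb(0.4 + d) -
                cb(0.4 + 2 * d)) / (12 * d)
  expect_equal(s_beta, stencil, tolerance = 1e-6)
  expect_gte(rate_sensitivity(toy, "alpha", target = "c"), 0)
  # normalization: the sensitivity of sum(pi) to any rate is 0
  s_pi <- vapply(c("11", "10", "01", "00"), function(k)
    rate_sensitivity(toy, "alpha", target = "pi", index = k), numeric(1))
  expect_equal(sum(s_pi), 0, tolerance = 1e-9)
  expect_error(rate_sensitivity(toy, "beta", delta = 0.5), "non-positive")
})

test_that("degenerate rates collapse to the absorbing restriction", {
  m <- translation_model(4, 2, alpha = 0, beta = 1, gamma = 1)
  ss <- pbn_steady_state(m)
  expect_identical(names(ss$pi), "0000")
  expect_equal(ss$c, 0)
  expect_error(build_transition_matrix(
    translation_model(2, 1, alpha = 0, beta = 1, gamma = 0)), NA)
})
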