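# Independent oracles used across the suite.  These deliberately avoid
# the package's internals: enumeration by filtering all 2^n occupancy
# vectors, full-window occurrence conditions, and a continuous-time
# master-equation solve built directly from the rates.

toy_model <- function() {
  translation_model(2, 1, alpha = 0.6, beta = 0.4, gamma = 1)
}

# a state is valid iff every maximal run of 1s has length divisible by r
brute_states <- function(n, r) {
  grid <- as.matrix(expand.grid(rep(list(c(1L, 0L)), n)))
  colnames(grid) <- NULL
  ok <- apply(grid, 1L, function(x) {
    rl <- rle(x)
    all(rl$lengths[rl$values == 1L] %% r == 0L)
  })
  grid[ok, , drop = FALSE]
}

# head positions of the ribosomes in a state (ends of each footprint)
brute_heads <- function(x, r) {
  rl <- rle(x)
  ends <- cumsum(rl$lengths)
  heads <- integer(0)
  for (b in which(rl$values == 1L)) {
    run_end <- ends[b]
    run_len <- rl$lengths[b]
    heads <- c(heads, seq(run_end - run_len + r, run_end, by = r))
  }
  heads
}

# stationary law of the continuous-time chain with generator built from
# the raw rates (master equation dp/dt = Q p), solved densely; returns
# a vector named by state key
ctmc_stationary <- function(model) {
  n <- model$n; r <- model$r
  S <- brute_states(n, r)
  key <- apply(S, 1L, paste0, collapse = "")
  m <- nrow(S)
  Q <- matrix(0, m, m)
  ps <- model$premature_stop
  add <- function(from, to_x, rate) {
    j <- match(paste0(to_x, collapse = ""), key)
    Q[j, from] <<- Q[j, from] + rate
  }
  for (s in seq_len(m)) {
    x <- S[s, ]
    if (all(x[1:r] == 0L)) {
      y <- x; y[1:r] <- 1L
      add(s, y, model$alpha)
    }
    for (h in brute_heads(x, r)) {
      if (h == n) {
        y <- x; y[(n - r + 1L):n] <- 0L
        add(s, y, model$beta)
      } else if (x[h + 1L] == 0L) {
        g <- unname(model$gamma[as.character(h)])
        if (!is.null(ps) && ps$position == h) {
          y <- x; y[h - r + 1L] <- 0L; y[h + 1L] <- 1L
          add(s, y, ps$mu * g)
          y2 <- x; y2[(h - r + 1L):h] <- 0L
          add(s, y2, (1 - ps$mu) * g)
        } else {
          y <- x; y[h - r + 1L] <- 0L; y[h + 1L] <- 1L
          add(s, y, g)
        }
      }
    }
  }
  diag(Q) <- -colSums(Q)
  A <- rbind(Q[-m, , drop = FALSE], rep(1, m))
  pi <- solve(A, c(rep(0, m - 1L), 1))
  names(pi) <- key
  pi
}

# the printed toy-model solution, frozen
toy_pi_expected <- c("11" = 0.36, "10" = 0.24, "01" = 0.24, "00" = 0.16)
toy_ME_expected <- matrix(c(0.8, 0.2, 0.0, 0.0,
                            0.0, 0.5, 0.5, 0.0,
                            0.3, 0.0, 0.5, 0.2,
                            0.0, 0.3, 0.0, 0.7), nrow = 4)

# reduced bottleneck scenarios standing in for the figure-scale sweeps
reduced_fig3 <- function(alpha) {
  translation_model(20, 4, alpha = alpha, beta = 0.5, gamma = 1)
}
reduced_fig4 <- function(slow_rate, double = FALSE) {
  translation_model(20, 4, alpha = 1, beta = 1, gamma = 1,
                    slow_codons = list(positions = if (double) c(10L, 11L) else 10L,
                                       rate = slow_rate))
}
reduced_fig5 <- function(mu) {
  translation_model(20, 4, alpha = 1, beta = 0.1, gamma = 1,
                    premature_stop = list(position = 10L, mu = mu))
}
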