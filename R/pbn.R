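#' Boolean event rule as a total state-to-state function
#'
#' Each event of the codon-based model corresponds to a Boolean update
#' function on the occupancy vector: it performs the event's state
#' transformation when the occurrence condition holds and acts as the
#' identity otherwise.  The entry rule tests codon `r` (empty), the
#' exit rule tests codon `n` (occupied), and the hop rule at head `j`
#' tests codon `j` occupied and codon `j+1` empty; these reduced tests
#' are equivalent to the full window conditions on the reachable state
#' set.  A premature-dissociation rule clears the footprint
#' `j-r+1..j` under the same test as the hop at `j`.
#'
#' @inheritParams apply_event
#' @return A function mapping an occupancy vector to an occupancy
#'   vector.
#' @export
boolean_event_rule <- function(event, model) {
  stopifnot(inherits(model, "translation_model"))
  ev <- resolve_event(event, model)
  n <- model$n; r <- model$r
  type <- ev$type; pos <- ev$pos
  function(x) {
    x <- as_state(x, n)
    if (!event_allowed_vec(x, ev, n, r)[1L]) return(x)
    apply_event_x(x, type, pos, n, r)
  }
}

#' Per-event transition matrix over the reachable states
#'
#' Column `j` holds the indicator of the image of state `chi_j` under
#' the event's Boolean rule (identity column where the event is
#' disallowed), giving a column-stochastic 0/1 matrix with exactly one
#' entry per column.  Stored sparsely.
#'
#' @inheritParams apply_event
#' @param states a `lattice_states` enumeration in canonical order
#'   (defaults to `enumerate_states(model)`).
#' @return A sparse `m x m` `Matrix` with states ordered as in
#'   `states`.
#' @export
build_event_matrix <- function(event, model, states = enumerate_states(model)) {
  ev <- resolve_event(event, model)
  m <- length(states$key)
  target <- event_images(ev, model, states)
  Matrix::sparseMatrix(i = target, j = seq_len(m), x = 1, dims = c(m, m))
}

# vectorized image indices for one event over all states (reduced
# predicates; the per-state rule path below is the cross-checked
# reference used by build_event_matrix)
event_images_fast <- function(type, pos, states) {
  X <- states$x; key <- states$key
  n <- states$n; r <- states$r
  m <- nrow(X)
  allowed <- switch(type,
    entry = X[, r] == 0L,
    hop = ,
    dissoc = X[, pos] == 1L & X[, pos + 1L] == 0L,
    exit = X[, n] == 1L)
  tgt <- seq_len(m)
  if (any(allowed)) {
    Y <- X[allowed, , drop = FALSE]
    if (type == "entry") {
      Y[, 1:r] <- 1L
    } else if (type == "hop") {
      Y[, pos - r + 1L] <- 0L; Y[, pos + 1L] <- 1L
    } else if (type == "dissoc") {
      Y[, (pos - r + 1L):pos] <- 0L
    } else {
      Y[, (n - r + 1L):n] <- 0L
    }
    keys <- apply(Y, 1L, paste0, collapse = "")
    hit <- match(keys, key)
    if (anyNA(hit))
      stop("event image left the enumerated state set (internal error)")
    tgt[allowed] <- hit
  }
  tgt
}

# m x length(rows) matrix of image indices, one column per selected
# event row (zero-rate events can map outside a rate-restricted state
# set and must be excluded by the caller)
all_event_images <- function(model, states, rows = seq_len(nrow(model$events))) {
  ev <- model$events
  vapply(rows, function(k)
    event_images_fast(ev$type[k], ev$pos[k], states),
    integer(length(states$key)))
}

# indices of the image states of each canonical state under one event
event_images <- function(ev, model, states) {
  n <- model$n; r <- model$r
  m <- length(states$key)
  target <- integer(m)
  for (j in seq_len(m)) {
    x <- states$x[j, ]
    if (event_allowed_vec(x, ev, n, r)[1L]) {
      y <- apply_event_x(x, ev$type, ev$pos, n, r)
      tk <- match(paste0(y, collapse = ""), states$key)
      if (is.na(tk))
        stop("event image left the enumerated state set (internal error)")
      target[j] <- tk
    } else target[j] <- j
  }
  target
}

#' Averaged transition matrix of the translation Markov chain
#'
#' Builds the discrete-time transition matrix
#' `M_E = sum_i p_i M_i` over the reachable occupancy states, where
#' `M_i` is the per-event transition matrix and
#' `p_i = gamma_i / sum(gamma)` is the event-selection probability of
#' the efficient fixed-time-step construction (the uniformized chain of
#' the underlying continuous-time dynamics: `M_E = I + Q / sum(gamma)`).
#' Orientation is column-stochastic: `x(t+1) = M_E x(t)` in
#' distribution over state indicators.
#'
#' The state space is restricted to the states reachable from the empty
#' lattice under events with strictly positive rate, which keeps the
#' chain on a closed communicating set even for degenerate rate
#' profiles (e.g. a premature stop with readthrough probability 0, or
#' `alpha = 0`).
#'
#' @param model a [translation_model()].
#' @return An object of class `"transition_matrix"`: list with `M`
#'   (sparse column-stochastic matrix), `p` (event probabilities),
#'   `events`, `states` (the possibly restricted `lattice_states`),
#'   and `model`.
#' @examples
#' toy <- translation_model(2, 1, alpha = 0.6, beta = 0.4, gamma = 1)
#' as.matrix(build_transition_matrix(toy)$M)
#' @export
build_transition_matrix <- function(model) {
  stopifnot(inherits(model, "translation_model"))
  ev <- model$events
  total <- sum(ev$rate)
  if (total <= 0) stop("total event rate is zero", call. = FALSE)
  states <- reachable_from_empty(model)
  m <- length(states$key)
  p <- ev$rate / total
  keep <- which(p > 0)
  images <- all_event_images(model, states, rows = keep)
  M <- Matrix::sparseMatrix(i = as.vector(images),
                            j = rep(seq_len(m), times = length(keep)),
                            x = rep(p[keep], each = m),
                            dims = c(m, m))
  structure(list(M = M, p = p, events = ev, states = states, model = model),
            class = "transition_matrix")
}

# restrict the canonical enumeration to states reachable from the empty
# lattice under positive-rate events (a closed set, preserving order)
reachable_from_empty <- function(model) {
  states <- enumerate_states(model)
  ev <- model$events
  m <- length(states$key)
  empty <- match(paste(rep("0", model$n), collapse = ""), states$key)
  seen <- logical(m); seen[empty] <- TRUE
  frontier <- empty
  images <- all_event_images(model, states, rows = which(ev$rate > 0))
  while (length(frontier)) {
    nxt <- unique(as.vector(images[frontier, ]))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  if (all(seen)) return(states)
  keep <- which(seen)
  structure(list(x = states$x[keep, , drop = FALSE], key = states$key[keep],
                 heads = states$heads[keep], n = states$n, r = states$r),
            class = "lattice_states")
}

#' Stationary distribution of the translation chain
#'
#' Solves `M_E pi = pi`, `sum(pi) = 1`, `pi >= 0`.  The default is a
#' direct sparse linear solve of the rank-deficient system with the
#' normalization replacing one equation; power iteration (the
#' `lim M_E^t` form) is available as an independent cross-check.
#'
#' @param M a `"transition_matrix"` (from [build_transition_matrix()])
#'   or a plain column-stochastic matrix.
#' @param method `"linear"` (default) or `"power"`.
#' @param tol convergence tolerance for power iteration, and residual
#'   tolerance for the verification `max|M pi - pi|`.
#' @param max_iter iteration cap for power iteration.
#' @return Numeric vector `pi` over the states (columns) of `M`.
#' @export
stationary_distribution <- function(M, method = c("linear", "power"),
                                    tol = 1e-12, max_iter = 100000L) {
  method <- match.arg(method)
  A <- if (inherits(M, "transition_matrix")) M$M else M
  m <- nrow(A)
  if (m == 1L) return(1)
  csum <- Matrix::colSums(A)
  if (max(abs(csum - 1)) > 1e-9)
    stop("matrix is not column-stochastic", call. = FALSE)
  if (method == "linear") {
    B <- A - Matrix::Diagonal(m)
    B[m, ] <- 1
    b <- c(rep(0, m - 1L), 1)
    pi <- tryCatch(as.numeric(Matrix::solve(B, b)),
                   error = function(e)
                     stop("stationary solve failed (chain may be reducible beyond the reachable restriction): ",
                          conditionMessage(e), call. = FALSE))
  } else {
    pi <- rep(1 / m, m)
    for (it in seq_len(max_iter)) {
      nxt <- as.numeric(A %*% pi)
      if (max(abs(nxt - pi)) <= tol * max(1, max(abs(pi)))) { pi <- nxt; break }
      pi <- nxt
      if (it == max_iter)
        stop("power iteration did not converge in ", max_iter, " steps",
             call. = FALSE)
    }
  }
  if (min(pi) < -1e-8)
    stop("stationary solve produced substantially negative mass; ",
         "the chain appears reducible", call. = FALSE)
  pi[pi < 0] <- 0
  pi <- pi / sum(pi)
  res <- max(abs(as.numeric(A %*% pi) - pi))
  if (res > 1e-8)
    warning(sprintf("stationary residual %.3g exceeds 1e-8", res))
  pi
}

#' Exact steady state of the codon-based model
#'
#' Builds the averaged transition matrix over the reachable states,
#' solves for the stationary state density `pi`, and derives the codon
#' densities `rho_i = sum_j pi_j chi_j[i]` and the translation rate
#' `c = beta * rho_n` (completed proteins per unit time).
#'
#' @param model a [translation_model()].
#' @param method passed to [stationary_distribution()].
#' @return An object of class `"pbn_steady_state"`: list with `pi`
#'   (named by state key), `rho`, `c`, `mean_occupancy` (mean ribosome
#'   count), `states`, `events`, `p`, and `model`.
#' @examples
#' toy <- translation_model(2, 1, alpha = 0.6, beta = 0.4, gamma = 1)
#' ss <- pbn_steady_state(toy)
#' ss$pi   # 0.36 0.24 0.24 0.16
#' ss$c    # 0.24
#' @export
pbn_steady_state <- function(model, method = c("linear", "power")) {
  tm <- build_transition_matrix(model)
  pi <- stationary_distribution(tm, method = match.arg(method))
  out <- steady_state_profiles(pi, tm$states, model)
  out$p <- tm$p
  out$events <- tm$events
  out$transition_matrix <- tm$M
  out
}

#' Codon densities and translation rate from a state density
#'
#' `rho = sum_i pi_i chi_i` componentwise over the occupancy vectors,
#' and `c = beta * rho_n`.
#'
#' @param pi state density over `states` (canonical order).
#' @param states a `lattice_states` object.
#' @param model the [translation_model()] providing `beta`.
#' @return A `"pbn_steady_state"` object (without matrix fields).
#' @export
steady_state_profiles <- function(pi, states, model) {
  stopifnot(length(pi) == length(states$key))
  rho <- as.numeric(crossprod(states$x, pi))
  names(pi) <- states$key
  structure(list(pi = pi, rho = rho, c = model$beta * rho[model$n],
                 mean_occupancy = sum(rho) / model$r,
                 states = states, model = model),
            class = "pbn_steady_state")
}

#' @export
print.pbn_steady_state <- function(x, ...) {
  cat(sprintf("Exact steady state (PBN/Markov solver): %d reachable states\n",
              length(x$pi)))
  cat(sprintf("  translation rate c = %.6f\n", x$c))
  cat(sprintf("  mean ribosome count = %.4f\n", x$mean_occupancy))
  cat("  codon densities rho:",
      paste(sprintf("%.4f", utils::head(x$rho, 8L)), collapse = " "),
      if (length(x$rho) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Mean event occurrence probabilities and fluxes at stationarity
#'
#' For each event, `psi_bar_i = sum_x pi(x) psi_i(x)` and the flux
#' `psi_bar_i * gamma_i`.  Without regulation the fluxes are balanced:
#' they are equal across all events and equal the translation rate.
#' With a premature stop codon the flux into the stop position splits
#' into the readthrough and dissociation branches.
#'
#' @param ss a `"pbn_steady_state"` from [pbn_steady_state()].
#' @return A data frame with columns `label`, `type`, `pos`, `rate`,
#'   `psi_bar`, `flux`.
#' @export
event_fluxes <- function(ss) {
  stopifnot(inherits(ss, "pbn_steady_state"))
  model <- ss$model
  ev <- model$events
  X <- ss$states$x
  psi <- vapply(seq_len(nrow(ev)), function(k) {
    allowed <- switch(ev$type[k],
      entry = X[, model$r] == 0L,
      hop = ,
      dissoc = X[, ev$pos[k]] == 1L & X[, ev$pos[k] + 1L] == 0L,
      exit = X[, model$n] == 1L)
    sum(ss$pi[allowed])
  }, numeric(1))
  data.frame(label = ev$label, type = ev$type, pos = ev$pos, rate = ev$rate,
             psi_bar = psi, flux = psi * ev$rate, stringsAsFactors = FALSE)
}

#' Most and least probable mRNA states
#'
#' Ranks the stationary state density: the `k` most and `k` least often
#' seen occupancy states.  Ties are broken by canonical state order.
#'
#' @param ss a `"pbn_steady_state"`.
#' @param k how many states per end (clipped to the state count).
#' @return List with data frames `top` and `bottom` (columns `state`,
#'   `density`).
#' @export
rank_states <- function(ss, k = 5L) {
  stopifnot(inherits(ss, "pbn_steady_state"))
  m <- length(ss$pi)
  k <- min(as.integer(k), m)
  ord <- order(-ss$pi, seq_len(m))  # ties: canonical order
  top <- ord[seq_len(k)]
  ordb <- order(ss$pi, seq_len(m))
  bottom <- ordb[seq_len(k)]
  list(top = data.frame(state = names(ss$pi)[top],
                        density = unname(ss$pi[top])),
       bottom = data.frame(state = names(ss$pi)[bottom],
                           density = unname(ss$pi[bottom])))
}

#' Exact sensitivity of a steady-state quantity to an event rate
#'
#' Central finite difference of a steady-state target with respect to
#' one event rate, using two exact solves (no Monte-Carlo noise).
#'
#' @param model a [translation_model()].
#' @param event event selector as in [apply_event()]: `"alpha"`,
#'   `"beta"`, a hop head position, or a label.
#' @param target `"c"` (translation rate), `"rho"` (a codon density;
#'   give the codon in `index`), or `"pi"` (a state density; give the
#'   canonical state index or key in `index`).
#' @param index codon index or state index/key when `target` is
#'   `"rho"`/`"pi"`.
#' @param delta finite-difference step; must keep the perturbed rate
#'   positive.
#' @return The sensitivity `d target / d rate` (a number).
#' @export
rate_sensitivity <- function(model, event, target = c("c", "rho", "pi"),
                             index = NULL, delta = 1e-4) {
  stopifnot(inherits(model, "translation_model"))
  target <- match.arg(target)
  ev <- resolve_event(event, model)
  base <- ev$rate
  if (ev$type %in% c("hop", "dissoc") && !is.null(model$premature_stop) &&
      ev$pos == model$premature_stop$position)
    stop("perturb the underlying hop rate via a model without the stop split",
         call. = FALSE)
  if (base - delta <= 0)
    stop("delta would make the perturbed rate non-positive", call. = FALSE)
  value <- function(rate) {
    m2 <- set_event_rate(model, ev, rate)
    ss <- pbn_steady_state(m2)
    switch(target,
      c = ss$c,
      rho = ss$rho[as.integer(index)],
      pi = {
        i <- if (is.character(index)) match(index, names(ss$pi))
             else as.integer(index)
        unname(ss$pi[i])
      })
  }
  (value(base + delta) - value(base - delta)) / (2 * delta)
}

# rebuild a model with one base rate changed
set_event_rate <- function(model, ev, rate) {
  alpha <- model$alpha; beta <- model$beta; gamma <- model$gamma
  if (ev$type == "entry") alpha <- rate
  else if (ev$type == "exit") beta <- rate
  else gamma[as.character(ev$pos)] <- rate
  translation_model(model$n, model$r, alpha, beta,
                    gamma = if (length(gamma)) unname(gamma) else NULL,
                    premature_stop = model$premature_stop,
                    feedback = model$feedback)
}
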