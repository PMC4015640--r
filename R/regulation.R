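#' Slow-codon variants of a model
#'
#' Returns a copy of the model with the hop rates at the given head
#' positions replaced (rare-tRNA bottleneck codons); everything else is
#' unchanged.
#'
#' @param model a [translation_model()].
#' @param positions head positions in `r..n-1`.
#' @param rate replacement elongation rate(s), recycled over
#'   `positions`.
#' @return A new `translation_model`.
#' @examples
#' m <- translation_model(50, 12, alpha = 1, beta = 1, gamma = 1)
#' slow1 <- with_slow_codons(m, 25, 0.1)
#' slow2 <- with_slow_codons(m, c(25, 26), 0.1)
#' @export
with_slow_codons <- function(model, positions, rate) {
  stopifnot(inherits(model, "translation_model"))
  translation_model(model$n, model$r, model$alpha, model$beta,
                    gamma = unname(model$gamma),
                    slow_codons = list(positions = positions, rate = rate),
                    premature_stop = model$premature_stop,
                    feedback = model$feedback)
}

# copy of a model with a different static initiation rate
with_alpha <- function(model, alpha) {
  translation_model(model$n, model$r, alpha, model$beta,
                    gamma = if (length(model$gamma)) unname(model$gamma) else NULL,
                    premature_stop = model$premature_stop,
                    feedback = model$feedback)
}

#' Self-consistent steady state under initiation autoregulation
#'
#' Solves the negative-feedback fixed point: the initiation rate
#' `alpha = alpha_I / (1 + k_I * rho_I)` depresses the translation rate
#' `c(alpha)`, which in turn sets the steady protein concentration
#' `rho_I = c * rho_m / d_I` (the steady state of
#' `d rho_I/dt = c rho_m - d_I rho_I`).  The iteration
#' `rho_I <- (1 - damping) rho_I + damping * c(alpha) rho_m / d_I`,
#' `alpha <- alpha_I / (1 + k_I rho_I)` is damped to guard against
#' oscillation and stops when successive `rho_I` differ by at most
#' `tol`.
#'
#' @param model a [translation_model()] carrying a `feedback` block.
#' @param backend steady-state solver used for `c(alpha)`: the exact
#'   solver (`"pbn"`, default and recommended), the mean-field solver
#'   (`"meanfield"`), the Petri-net closed form (`"petri"`), or a
#'   stochastic run (`"simulation"`, with `sim_args`).
#' @param damping damping factor in (0, 1].
#' @param tol convergence tolerance on `rho_I`.
#' @param max_iter iteration cap; non-convergence is an error carrying
#'   the iteration trace.
#' @param sim_args list of arguments for
#'   [simulate.translation_model()] when `backend = "simulation"`.
#' @return An object of class `"feedback_fixed_point"`: list with
#'   `alpha`, `c`, `rho_I`, `iterations`, `trace` (data frame of the
#'   iterates), `backend`, and `model`.
#' @examples
#' m <- translation_model(6, 2, beta = 1, gamma = 1,
#'   feedback = list(alpha_I = 1, k_I = 2, d_I = 1, rho_m = 1))
#' feedback_fixed_point(m)
#' @export
feedback_fixed_point <- function(model,
                                 backend = c("pbn", "meanfield", "petri",
                                             "simulation"),
                                 damping = 0.5, tol = 1e-10, max_iter = 500L,
                                 sim_args = list()) {
  stopifnot(inherits(model, "translation_model"))
  backend <- match.arg(backend)
  fb <- model$feedback
  if (is.null(fb))
    stop("model has no feedback block", call. = FALSE)
  if (backend == "simulation" && tol < 1e-4)
    tol <- 1e-4  # Monte-Carlo noise floor
  c_of <- function(alpha) {
    m2 <- with_alpha(model, alpha)
    m2$feedback <- NULL
    switch(backend,
      pbn = pbn_steady_state(m2)$c,
      meanfield = mf_steady_state(m2, rho_m = fb$rho_m)$c,
      petri = petri_translation_rate(m2),
      simulation = do.call(stats::simulate,
                           c(list(object = m2), sim_args))$c)
  }
  rho_I <- 0
  alpha <- fb$alpha_I
  trace <- data.frame(iter = integer(0), alpha = numeric(0),
                      c = numeric(0), rho_I = numeric(0))
  for (it in seq_len(max_iter)) {
    cc <- c_of(alpha)
    rho_new <- cc * fb$rho_m / fb$d_I
    delta <- rho_new - rho_I
    rho_I <- rho_I + damping * delta
    alpha <- fb$alpha_I / (1 + fb$k_I * rho_I)
    trace <- rbind(trace, data.frame(iter = it, alpha = alpha, c = cc,
                                     rho_I = rho_I))
    if (abs(delta) <= tol) {
      return(structure(list(alpha = alpha, c = cc, rho_I = rho_I,
                            iterations = it, trace = trace,
                            backend = backend, model = model),
                       class = "feedback_fixed_point"))
    }
  }
  err <- simpleError(sprintf(
    "feedback fixed point did not converge in %d iterations (last delta %.3g)",
    max_iter, abs(delta)))
  err$trace <- trace
  stop(err)
}

#' @export
print.feedback_fixed_point <- function(x, ...) {
  cat(sprintf("Initiation-feedback fixed point (%s backend, %d iterations)\n",
              x$backend, x$iterations))
  cat(sprintf("  alpha* = %.6f, c* = %.6f, rho_I* = %.6f\n",
              x$alpha, x$c, x$rho_I))
  invisible(x)
}

#' Run several solvers on one model and tabulate translation rates
#'
#' Side-by-side comparison of the steady-state translation rate from
#' the exact solver, random-sequential and parallel simulations, the
#' mean-field solver, and the Petri-net closed form.
#'
#' @param model a [translation_model()].
#' @param backends subset of
#'   `c("pbn", "rs", "parallel", "heinrich", "petri")`.
#' @param nsim,seed,burn_in simulation settings for the stochastic
#'   backends.
#' @return A one-row data frame with a `c_<backend>` column per
#'   backend.
#' @export
compare_backends <- function(model,
                             backends = c("pbn", "rs", "parallel",
                                          "heinrich", "petri"),
                             nsim = 20000L, seed = 1L, burn_in = NULL) {
  stopifnot(inherits(model, "translation_model"))
  backends <- match.arg(backends, several.ok = TRUE)
  out <- list()
  for (b in backends) {
    val <- switch(b,
      pbn = pbn_steady_state(model)$c,
      rs = simulate(model, nsim = nsim, seed = seed, burn_in = burn_in,
                    algorithm = "rs_varying")$c,
      parallel = simulate(model, nsim = nsim, seed = seed, burn_in = burn_in,
                          algorithm = "parallel")$c,
      heinrich = if (is.null(model$premature_stop))
        mf_steady_state(model)$c else NA_real_,
      petri = petri_translation_rate(model))
    out[[paste0("c_", b)]] <- val
  }
  as.data.frame(out)
}
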