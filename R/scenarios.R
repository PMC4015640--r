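#' Named scenario presets
#'
#' Ready-to-run parameter sets mirroring the worked examples of the
#' modelling study the package implements:
#' \describe{
#'   \item{`toy-pbn`}{`n = 2, r = 1, alpha = 0.6, beta = 0.4,
#'     gamma = 1`; exact solver.  The printed stationary density is
#'     `(0.36, 0.24, 0.24, 0.16)` over `11, 10, 01, 00`, with
#'     `rho = (0.6, 0.6)` and `c = 0.24`.}
#'   \item{`fig2`}{`n = 50, r = 12, beta = gamma = 0.5`, initiation
#'     sweep; random-sequential simulation vs mean-field vs Petri
#'     net.}
#'   \item{`fig3`}{`n = 50, r = 12, beta = 0.5, gamma = 1`, initiation
#'     sweep; random-sequential vs parallel update.}
#'   \item{`fig4`}{`n = 50, r = 12, alpha = beta = 1, gamma = 1`
#'     except one slow codon at 25 (`variant = "single"`) or equal-rate
#'     slow codons at 25 and 26 (`variant = "double"`); slow-rate
#'     sweep across backends.}
#'   \item{`fig5`}{`n = 50, r = 12, alpha = 1, beta = 0.1, gamma = 1`,
#'     premature stop at codon 25, readthrough sweep.}
#'   \item{`fig6`}{`n = 50, r = 12, beta = 1, gamma = 1, rho_m = 1`,
#'     initiation feedback; `k_I` sweep at fixed `d_I` and `d_I` sweep
#'     at fixed `k_I`.  The source study does not print its maximum
#'     initiation rate; `alpha_I` defaults to 1 here.}
#' }
#' All presets default to reduced step counts suitable for test runs;
#' pass `full = TRUE` to [run_scenario()] for figure-scale runs.
#'
#' @param name one of [scenario_names()].
#' @param ... preset-specific overrides: `alpha_sweep`, `slow_rates`,
#'   `mu_sweep`, `k_I_sweep`, `d_I_sweep`, `variant`, `alpha_I`,
#'   `d_I`, `k_I`.
#' @return An object of class `"scenario"`: list with `name`, `note`,
#'   the base `model` (or model factory), the sweep values, and a
#'   fixed default `seed`.
#' @export
scenario <- function(name, ...) {
  name <- match.arg(name, scenario_names())
  dots <- list(...)
  take <- function(key, default) if (!is.null(dots[[key]])) dots[[key]] else default
  sc <- switch(name,
    "toy-pbn" = list(
      note = "two-codon toy lattice solved exactly",
      model = translation_model(2, 1, alpha = 0.6, beta = 0.4, gamma = 1)),
    "fig2" = list(
      note = "initiation sweep: random-sequential TASEP vs mean-field vs Petri net",
      make = function(alpha) translation_model(50, 12, alpha = alpha,
                                               beta = 0.5, gamma = 0.5),
      alpha_sweep = take("alpha_sweep", c(0.02, 0.05, 0.1, 0.2, 0.35, 0.5)),
      backends = c("rs", "heinrich", "petri")),
    "fig3" = list(
      note = "initiation sweep: random-sequential vs parallel update",
      make = function(alpha) translation_model(50, 12, alpha = alpha,
                                               beta = 0.5, gamma = 1),
      alpha_sweep = take("alpha_sweep", c(0.05, 0.1, 0.25, 0.5, 1)),
      backends = c("rs", "parallel")),
    "fig4" = list(
      note = "slow codon(s) at 25 (and 26): rate sweep across backends",
      variant = take("variant", "single"),
      make = function(slow_rate, variant = "single") {
        pos <- if (variant == "double") c(25L, 26L) else 25L
        translation_model(50, 12, alpha = 1, beta = 1, gamma = 1,
                          slow_codons = list(positions = pos,
                                             rate = slow_rate))
      },
      slow_rates = take("slow_rates", c(0.05, 0.1, 0.25, 0.5, 1)),
      backends = c("pbn", "rs", "parallel", "petri")),
    "fig5" = list(
      note = "premature stop at codon 25: readthrough sweep",
      make = function(mu) translation_model(50, 12, alpha = 1, beta = 0.1,
                                            gamma = 1,
                                            premature_stop = list(position = 25L,
                                                                  mu = mu)),
      mu_sweep = take("mu_sweep", c(0, 0.25, 0.5, 0.75, 1)),
      backends = c("pbn", "rs", "parallel")),
    "fig6" = list(
      note = "initiation autoregulation: k_I and d_I sweeps (alpha_I is a required choice; default 1)",
      alpha_I = take("alpha_I", 1),
      d_I = take("d_I", 1),
      k_I = take("k_I", 1),
      make = function(k_I, d_I, alpha_I = 1) {
        translation_model(50, 12, beta = 1, gamma = 1,
                          feedback = list(alpha_I = alpha_I, k_I = k_I,
                                          d_I = d_I, rho_m = 1))
      },
      k_I_sweep = take("k_I_sweep", c(0, 0.5, 1, 2, 4)),
      d_I_sweep = take("d_I_sweep", c(0.25, 0.5, 1, 2, 4))))
  structure(c(list(name = name, seed = 20140227L), sc), class = "scenario")
}

#' @rdname scenario
#' @export
scenario_names <- function() c("toy-pbn", "fig2", "fig3", "fig4", "fig5", "fig6")

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': %s\n", x$name, x$note))
  invisible(x)
}

#' Run a scenario preset
#'
#' Executes the preset end to end and returns a tidy results table.
#' Defaults are desk-scale (reduced step counts); `full = TRUE`
#' switches to figure-scale run lengths.
#'
#' @param sc a [scenario()] or a scenario name.
#' @param nsim steps for stochastic backends (default 4000, or 200000
#'   when `full`).
#' @param seed RNG seed (default: the preset's fixed seed).
#' @param full figure-scale run lengths.
#' @param fp_tol convergence tolerance forwarded to
#'   [feedback_fixed_point()] for the feedback preset.
#' @param ... passed to [scenario()] when `sc` is a name.
#' @return A data frame; columns depend on the preset (the sweep
#'   variable plus one translation-rate column per backend, or the
#'   exact toy solution).
#' @export
run_scenario <- function(sc, nsim = NULL, seed = NULL, full = FALSE,
                         fp_tol = 1e-10, ...) {
  if (is.character(sc)) sc <- scenario(sc, ...)
  stopifnot(inherits(sc, "scenario"))
  if (is.null(nsim)) nsim <- if (full) 200000L else 4000L
  if (is.null(seed)) seed <- sc$seed
  if (sc$name == "toy-pbn") {
    ss <- pbn_steady_state(sc$model)
    return(data.frame(state = names(ss$pi), pi = unname(ss$pi),
                      rho = c(ss$rho, rep(NA, length(ss$pi) - length(ss$rho))),
                      c = ss$c))
  }
  if (sc$name == "fig6") {
    rows <- lapply(sc$k_I_sweep, function(k) {
      fp <- feedback_fixed_point(sc$make(k, sc$d_I, sc$alpha_I), tol = fp_tol)
      data.frame(sweep = "k_I", value = k, alpha = fp$alpha, c = fp$c,
                 rho_I = fp$rho_I)
    })
    rows2 <- lapply(sc$d_I_sweep, function(d) {
      fp <- feedback_fixed_point(sc$make(sc$k_I, d, sc$alpha_I), tol = fp_tol)
      data.frame(sweep = "d_I", value = d, alpha = fp$alpha, c = fp$c,
                 rho_I = fp$rho_I)
    })
    return(do.call(rbind, c(rows, rows2)))
  }
  sweep <- switch(sc$name,
    fig2 = , fig3 = sc$alpha_sweep,
    fig4 = sc$slow_rates,
    fig5 = sc$mu_sweep)
  sweep_name <- switch(sc$name, fig2 = , fig3 = "alpha", fig4 = "slow_rate",
                       fig5 = "mu")
  rows <- lapply(sweep, function(v) {
    model <- if (sc$name == "fig4") sc$make(v, sc$variant) else sc$make(v)
    res <- compare_backends(model, backends = sc$backends, nsim = nsim,
                            seed = seed)
    cbind(stats::setNames(data.frame(v), sweep_name), res)
  })
  do.call(rbind, rows)
}
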