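#' Mean-field fluxes of the Heinrich-Rapoport model
#'
#' Given head-occupancy probabilities `h_i` (the probability that codon
#' `i` carries the head of a ribosome, `i = r..n`), computes the
#' conditional vacancy probabilities
#' \deqn{W_0 = 1 - \sum_{s=r}^{\min(2r-1,n)} h_s, \quad
#'       W_i = \frac{1 - \sum_{s=1}^{r} h_{i+s}}
#'                  {1 - \sum_{s=1}^{r-1} h_{i+s}} \ (r \le i \le n-r),
#'       \quad W_i = 1 \ (i > n-r)}
#' (with `h_s = 0` for `s > n`) and the fluxes
#' `c_0 = alpha * rho_m * rho_r * W_0`,
#' `c_i = gamma_i * rho_m * h_i * W_i` for hops, and
#' `c_n = beta * rho_m * h_n`.
#'
#' @param h numeric vector of head occupancies for codons `r..n`
#'   (length `n - r + 1`).
#' @param model a [translation_model()].
#' @param rho_m total mRNA concentration (default 1).
#' @param rho_r free-ribosome concentration (default 1; held constant,
#'   no pool depletion).
#' @return List with `W` (named, for event positions `0, r..n`),
#'   `flux` (named by event position, including entry `c_0` and exit
#'   `c_n`).
#' @export
mf_fluxes <- function(h, model, rho_m = 1, rho_r = 1) {
  stopifnot(inherits(model, "translation_model"))
  n <- model$n; r <- model$r
  if (length(h) != n - r + 1L)
    stop(sprintf("'h' must have length n - r + 1 = %d", n - r + 1L),
         call. = FALSE)
  hfull <- numeric(n)            # h indexed by codon, 0 below r
  hfull[r:n] <- h
  hpad <- c(hfull, numeric(r))   # h_s = 0 for s > n
  g <- gamma_full(model)
  W <- numeric(n - r + 2L)       # entry, hops r..n-1, exit
  names(W) <- c("0", if (n > r) as.character(r:(n - 1L)) else NULL, as.character(n))
  W["0"] <- 1 - sum(hpad[r:min(2L * r - 1L, n)])
  if (n > r) {
    for (i in r:(n - 1L)) {
      if (i <= n - r) {
        den <- if (r == 1L) 1 else 1 - sum(hpad[(i + 1L):(i + r - 1L)])
        num <- 1 - sum(hpad[(i + 1L):(i + r)])
        if (den <= 0)
          stop("invalid mean-field state: vacancy denominator <= 0 at i = ", i,
               call. = FALSE)
        W[as.character(i)] <- num / den
      } else W[as.character(i)] <- 1
    }
  }
  W[as.character(n)] <- 1
  flux <- numeric(length(W))
  names(flux) <- names(W)
  flux["0"] <- model$alpha * rho_m * rho_r * W["0"]
  if (n > r)
    for (i in r:(n - 1L))
      flux[as.character(i)] <- g[as.character(i)] * rho_m * hfull[i] * W[as.character(i)]
  flux[as.character(n)] <- model$beta * rho_m * hfull[n]
  list(W = W, flux = flux)
}

# full event-rate vector indexed by head position as character:
# "0" = alpha, hops, "n" = beta
gamma_full <- function(model) {
  g <- c(model$alpha, unname(model$gamma), model$beta)
  names(g) <- c("0", names(model$gamma), as.character(model$n))
  g
}

#' Transient integration of the mean-field model
#'
#' Integrates `rho_m * dh_i/dt = c_{i-1} - c_i` (with `c_{r-1}` meaning
#' the entry flux `c_0`) from `h0` to `t_end` with `deSolve::ode`
#' (lsoda).
#'
#' @inheritParams mf_fluxes
#' @param t_end integration horizon.
#' @param h0 initial head occupancies (default: empty mRNA, all 0).
#' @param times output times (default: 200 points to `t_end`).
#' @return A list with `trajectory` (deSolve matrix: time plus
#'   `h_r..h_n`) and `h_end` (terminal state).
#' @export
mf_integrate <- function(model, t_end, h0 = NULL, rho_m = 1, rho_r = 1,
                         times = NULL) {
  stopifnot(inherits(model, "translation_model"))
  n <- model$n; r <- model$r
  nh <- n - r + 1L
  if (is.null(h0)) h0 <- numeric(nh)
  if (is.null(times)) times <- seq(0, t_end, length.out = 201L)
  derivs <- function(t, h, parms) {
    fl <- mf_fluxes(h, model, rho_m = rho_m, rho_r = rho_r)$flux
    # inflow into head position i is the flux of the event that puts a
    # head there: entry for i = r, the hop from i-1 otherwise
    inflow <- c(fl["0"], fl[as.character(if (n > r) r:(n - 1L) else integer(0))])
    outflow <- fl[c(if (n > r) as.character(r:(n - 1L)) else NULL,
                    as.character(n))]
    list(as.numeric(inflow - outflow) / rho_m)
  }
  sol <- deSolve::ode(y = stats::setNames(h0, paste0("h", r:n)),
                      times = times, func = derivs, parms = NULL)
  if (attr(sol, "istate")[1] < 0)
    stop("mean-field integration failed (lsoda diagnostics above)",
         call. = FALSE)
  list(trajectory = sol, h_end = as.numeric(sol[nrow(sol), -1L]))
}

#' Steady state of the mean-field model
#'
#' Solves the closed steady-state relations
#' `gamma_0 W_0 = gamma_i h_i W_i = gamma_n h_n = c`:
#' `h_i = c / gamma_i` for `i = n-r+1..n`, the backward recursion
#' \deqn{h_i = \frac{c\,(1 - \sum_{s=1}^{r-1} h_{i+s})}
#'                  {\gamma_i\,(1 - \sum_{s=1}^{r} h_{i+s})}}
#' for `i = n-r, ..., r`, and the closing relation
#' `alpha = c / (1 - sum_{s=r}^{min(2r-1,n)} h_s)`.  The scalar
#' unknown is `c`: for a trial `c` the recursion yields all `h_i` and
#' an implied initiation rate; bisection solves
#' `implied_alpha(c) = alpha` on the physical branch
#' `c` in `(0, min gamma)`, on which the implied rate is monotone
#' increasing (trial values producing `h` outside `[0, 1]` or a
#' non-positive denominator are rejected as too large).  The smallest
#' physical root is returned.
#'
#' @inheritParams mf_fluxes
#' @param tol relative bisection tolerance on `c`.
#' @return An object of class `"heinrich_steady_state"`: list with `c`,
#'   `h` (head occupancies `r..n`), `rho` (codon densities: codon `k`
#'   is covered when a head sits at `k..k+r-1`), `W`, `flux`,
#'   `implied_alpha`, and `model`.
#' @examples
#' m <- translation_model(12, 3, alpha = 0.05, beta = 0.5, gamma = 0.5)
#' mf_steady_state(m)$c
#' @export
mf_steady_state <- function(model, rho_m = 1, rho_r = 1, tol = 1e-13) {
  stopifnot(inherits(model, "translation_model"))
  if (!is.null(model$premature_stop))
    stop("the mean-field solver does not model premature stop codons",
         call. = FALSE)
  n <- model$n; r <- model$r
  g <- gamma_full(model)
  alpha_eff <- model$alpha * rho_r
  if (alpha_eff == 0) {
    h <- numeric(n - r + 1L)
    fl <- mf_fluxes(h, model, rho_m, rho_r)
    return(structure(list(c = 0, h = h, rho = numeric(n), W = fl$W,
                          flux = fl$flux, implied_alpha = 0, model = model),
                     class = "heinrich_steady_state"))
  }
  cmax <- min(g[-1L]) * (1 - 1e-12)  # c is bounded by the slowest non-entry rate

  implied_alpha <- function(cc) {
    h <- mf_recursion(cc, model)
    if (is.null(h)) return(Inf)
    hpad <- c(numeric(r - 1L), h, numeric(r))  # codon-indexed from 1, padded
    w0 <- 1 - sum(hpad[r:min(2L * r - 1L, n)])
    if (w0 <= 0) return(Inf)
    cc / w0
  }
  f <- function(cc) implied_alpha(cc) - alpha_eff
  lo <- 0; hi <- cmax
  if (f(hi) < 0) {
    # even the fastest physical c implies a smaller initiation rate:
    # initiation is not rate-limiting, c sits at the elongation bound
    warning("initiation rate exceeds the mean-field capacity; returning the bounding c")
    cc <- hi
  } else {
    while ((hi - lo) > tol * max(hi, 1)) {
      mid <- (lo + hi) / 2
      if (f(mid) >= 0) hi <- mid else lo <- mid
    }
    cc <- (lo + hi) / 2
    if (is.infinite(implied_alpha(cc))) cc <- lo
  }
  h <- mf_recursion(cc, model)
  if (is.null(h))
    stop("no physical mean-field root in (0, min gamma); bracket (",
         format(lo), ", ", format(hi), ")", call. = FALSE)
  fl <- mf_fluxes(h, model, rho_m, rho_r)
  # codon k is covered when a ribosome head is at k..k+r-1
  hfull <- numeric(n + r); hfull[r:n] <- h
  rho <- vapply(seq_len(n), function(k) sum(hfull[k:(k + r - 1L)]), numeric(1))
  structure(list(c = cc, h = h, rho = rho, W = fl$W, flux = fl$flux,
                 implied_alpha = implied_alpha(cc), model = model),
            class = "heinrich_steady_state")
}

# backward recursion for the head profile at a trial translation rate;
# NULL if unphysical (h outside [0,1] or non-positive denominator)
mf_recursion <- function(cc, model) {
  n <- model$n; r <- model$r
  g <- gamma_full(model)
  hfull <- numeric(n + r)  # codon-indexed, zero-padded beyond n
  for (i in n:max(n - r + 1L, r)) {
    hi <- cc / g[as.character(i)]
    if (!is.finite(hi) || hi < 0 || hi > 1) return(NULL)
    hfull[i] <- hi
  }
  if (n - r >= r) {
    for (i in (n - r):r) {
      s1 <- if (r > 1L) sum(hfull[(i + 1L):(i + r - 1L)]) else 0
      s2 <- sum(hfull[(i + 1L):(i + r)])
      den <- g[as.character(i)] * (1 - s2)
      if (1 - s1 <= 0 || den <= 0) return(NULL)
      hi <- cc * (1 - s1) / den
      if (!is.finite(hi) || hi < 0 || hi > 1) return(NULL)
      hfull[i] <- hi
    }
  }
  if (sum(hfull) > n) return(NULL)
  hfull[r:n]
}

#' @export
print.heinrich_steady_state <- function(x, ...) {
  cat(sprintf("Mean-field (Heinrich) steady state: n = %d, r = %d\n",
              x$model$n, x$model$r))
  cat(sprintf("  translation rate c = %.6f (implied alpha = %.6f)\n",
              x$c, x$implied_alpha))
  cat("  head occupancies h:",
      paste(sprintf("%.4f", utils::head(x$h, 8L)), collapse = " "),
      if (length(x$h) > 8L) "..." else "", "\n")
  invisible(x)
}
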