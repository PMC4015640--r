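#' Construct a codon-based translation model
#'
#' Defines the codon lattice and event-rate profile of a codon-resolved
#' model of mRNA translation.  The mRNA is a one-dimensional lattice of
#' `n` codons; a ribosome covers `r` consecutive codons (its footprint).
#' Three event types drive the dynamics: entry (initiation) at rate
#' `alpha`, requiring the first `r` codons to be empty; hops
#' (elongation) of a ribosome whose head is at codon `i` (for
#' `i = r, ..., n-1`) at rate `gamma[i]`, requiring codon `i+1` to be
#' empty; and exit (termination) at rate `beta` once the head reaches
#' codon `n`.  Events are indexed by the head position at which they
#' occur: 0 for entry, `n` for exit, `r..n-1` for hops.
#'
#' Optional regulation blocks extend the event set:
#' \describe{
#'   \item{slow_codons}{a list `list(positions =, rate =)` replacing the
#'     hop rate at the given head positions (bottleneck codons with rare
#'     tRNAs).  `rate` is recycled to the length of `positions`.}
#'   \item{premature_stop}{a list `list(position = j, mu =)`: a
#'     premature stop codon at head position `j` (`r <= j < n`).  The
#'     hop at `j` splits into readthrough (rate `mu * gamma[j]`, a
#'     normal hop) and premature dissociation (rate `(1-mu) * gamma[j]`,
#'     clearing codons `j-r+1..j`), so the total attempt rate at `j`
#'     stays `gamma[j]` and a moving ribosome reads through with
#'     probability `mu`.}
#'   \item{feedback}{a list `list(alpha_I =, k_I =, d_I =, rho_m = 1)`:
#'     negative autoregulation of initiation,
#'     `alpha = alpha_I / (1 + k_I * rho_I)`, where the protein
#'     concentration follows `d rho_I/dt = c * rho_m - d_I * rho_I`.
#'     When a feedback block is present `alpha` may be omitted; the
#'     static rate used by non-feedback solvers is `alpha_I` (the
#'     `rho_I = 0` limit).}
#' }
#'
#' @param n number of codons (integer >= 1).
#' @param r ribosome footprint in codons (integer, `1 <= r <= n`).
#' @param alpha initiation (entry) rate, >= 0.
#' @param beta termination (exit) rate, > 0.
#' @param gamma hop rates for head positions `r..n-1`: a scalar
#'   (uniform) or a vector of length `n - r`.  Ignored (may be missing)
#'   when `n == r`.
#' @param slow_codons,premature_stop,feedback optional regulation
#'   blocks, see Details.
#' @return An object of class `"translation_model"`: a list with the
#'   validated parameters and the derived event table (`$events`, one
#'   row per event with columns `type`, `pos`, `rate`, `label`).
#' @examples
#' toy <- translation_model(n = 2, r = 1, alpha = 0.6, beta = 0.4, gamma = 1)
#' toy
#' pbn_steady_state(toy)
#' @export
translation_model <- function(n, r = 1, alpha, beta, gamma = NULL,
                              slow_codons = NULL, premature_stop = NULL,
                              feedback = NULL) {
  n <- as.integer(n); r <- as.integer(r)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("'n' must be a single integer >= 1", call. = FALSE)
  if (length(r) != 1L || is.na(r) || r < 1L || r > n)
    stop("'r' must be a single integer with 1 <= r <= n", call. = FALSE)

  fb <- NULL
  if (!is.null(feedback)) {
    fb <- validate_block(feedback, c("alpha_I", "k_I", "d_I", "rho_m"),
                         required = c("alpha_I", "k_I", "d_I"), "feedback")
    if (is.null(fb$rho_m)) fb$rho_m <- 1
    if (fb$alpha_I < 0 || fb$k_I < 0 || fb$d_I <= 0 || fb$rho_m <= 0)
      stop("feedback requires alpha_I >= 0, k_I >= 0, d_I > 0, rho_m > 0",
           call. = FALSE)
    if (missing(alpha)) alpha <- fb$alpha_I
  }
  check_rate <- function(x, nm, positive = FALSE) {
    if (length(x) != 1L || !is.finite(x) || x < 0 || (positive && x == 0))
      stop(sprintf("'%s' must be a finite %s rate", nm,
                   if (positive) "positive" else "non-negative"),
           call. = FALSE)
    as.numeric(x)
  }
  alpha <- check_rate(alpha, "alpha")
  beta  <- check_rate(beta,  "beta", positive = TRUE)

  n_hops <- n - r
  if (n_hops == 0L) {
    gamma <- numeric(0)
  } else {
    if (is.null(gamma))
      stop("'gamma' is required when n > r", call. = FALSE)
    if (length(gamma) == 1L) gamma <- rep(as.numeric(gamma), n_hops)
    if (length(gamma) != n_hops)
      stop(sprintf("'gamma' must be a scalar or a vector of length n - r = %d",
                   n_hops), call. = FALSE)
    if (any(!is.finite(gamma)) || any(gamma < 0))
      stop("'gamma' rates must be finite and >= 0", call. = FALSE)
    gamma <- as.numeric(gamma)
  }
  names(gamma) <- if (n_hops > 0L) as.character(r:(n - 1L)) else character(0)

  if (!is.null(slow_codons)) {
    sc <- validate_block(slow_codons, c("positions", "rate"),
                         required = c("positions", "rate"), "slow_codons")
    pos <- as.integer(sc$positions)
    if (any(pos < r) || any(pos > n - 1L))
      stop(sprintf("slow codon positions must lie in the hop range %d..%d",
                   r, n - 1L), call. = FALSE)
    rate <- rep_len(as.numeric(sc$rate), length(pos))
    if (any(!is.finite(rate)) || any(rate < 0))
      stop("slow codon rates must be finite and >= 0", call. = FALSE)
    gamma[as.character(pos)] <- rate
  }

  ps <- NULL
  if (!is.null(premature_stop)) {
    ps <- validate_block(premature_stop, c("position", "mu"),
                         required = c("position", "mu"), "premature_stop")
    ps$position <- as.integer(ps$position)
    if (ps$position < r || ps$position >= n)
      stop(sprintf("premature stop position must satisfy r <= j < n (%d..%d)",
                   r, n - 1L), call. = FALSE)
    if (!is.finite(ps$mu) || ps$mu < 0 || ps$mu > 1)
      stop("readthrough probability 'mu' must lie in [0, 1]", call. = FALSE)
  }

  model <- structure(
    list(n = n, r = r, alpha = alpha, beta = beta, gamma = gamma,
         premature_stop = ps, feedback = fb),
    class = "translation_model")
  model$events <- build_event_table(model)
  model
}

# check a named-list regulation block for unknown/missing keys
validate_block <- function(x, allowed, required, what) {
  if (!is.list(x) || is.null(names(x)) || any(names(x) == ""))
    stop(sprintf("'%s' must be a named list", what), call. = FALSE)
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop(sprintf("unknown %s key(s): %s", what,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop(sprintf("%s requires key(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  x
}

# Event table: one row per event in left-to-right sweep order.
# pos is the head position at which the event occurs (0 = entry,
# n = exit); a premature-dissociation event shares the hop's position.
build_event_table <- function(model) {
  n <- model$n; r <- model$r
  type <- "entry"; pos <- 0L; rate <- model$alpha; label <- "alpha"
  if (n > r) {
    hp <- r:(n - 1L)
    hr <- unname(model$gamma)
    type <- c(type, rep("hop", length(hp)))
    pos <- c(pos, hp)
    rate <- c(rate, hr)
    label <- c(label, paste0("gamma_", hp))
  }
  type <- c(type, "exit"); pos <- c(pos, n)
  rate <- c(rate, model$beta); label <- c(label, "beta")
  ev <- data.frame(type = type, pos = as.integer(pos), rate = rate,
                   label = label, stringsAsFactors = FALSE)
  ps <- model$premature_stop
  if (!is.null(ps)) {
    j <- ps$position
    k <- which(ev$type == "hop" & ev$pos == j)
    base <- ev$rate[k]
    ev$rate[k] <- ps$mu * base
    dis <- data.frame(type = "dissoc", pos = j, rate = (1 - ps$mu) * base,
                      label = paste0("dissoc_", j), stringsAsFactors = FALSE)
    # keep sweep (position) order: dissociation right after its hop
    ev <- rbind(ev[seq_len(k), ], dis, ev[-seq_len(k), ])
    rownames(ev) <- NULL
  }
  ev
}

#' The event set of a translation model
#'
#' Returns the model's events as a data frame, one row per event, in
#' left-to-right sweep order: columns `type`
#' (`entry`/`hop`/`dissoc`/`exit`), `pos` (head position; 0 for entry,
#' `n` for exit), `rate` and `label`.  For a model without a premature
#' stop codon the index set is `{0, r, r+1, ..., n}` with
#' `n - r + 2` members.
#'
#' @param model a [translation_model()].
#' @return A data frame of events.
#' @export
event_table <- function(model) {
  stopifnot(inherits(model, "translation_model"))
  model$events
}

#' @export
print.translation_model <- function(x, ...) {
  cat(sprintf("Codon-based translation model: n = %d codons, footprint r = %d\n",
              x$n, x$r))
  cat(sprintf("  entry rate alpha = %g, exit rate beta = %g\n",
              x$alpha, x$beta))
  if (length(x$gamma)) {
    g <- unique(x$gamma)
    if (length(g) == 1L) {
      cat(sprintf("  hop rates gamma = %g (uniform over heads %d..%d)\n",
                  g, x$r, x$n - 1L))
    } else {
      cat(sprintf("  hop rates gamma: non-uniform over heads %d..%d (range %g..%g)\n",
                  x$r, x$n - 1L, min(x$gamma), max(x$gamma)))
    }
  }
  if (!is.null(x$premature_stop))
    cat(sprintf("  premature stop codon at %d, readthrough mu = %g\n",
                x$premature_stop$position, x$premature_stop$mu))
  if (!is.null(x$feedback))
    cat(sprintf("  initiation feedback: alpha_I = %g, k_I = %g, d_I = %g, rho_m = %g\n",
                x$feedback$alpha_I, x$feedback$k_I, x$feedback$d_I,
                x$feedback$rho_m))
  cat(sprintf("  events: %d (%s)\n", nrow(x$events),
              paste(unique(x$events$type), collapse = ", ")))
  invisible(x)
}

# rate profile indexed by event row, refreshed for a given alpha
# (used by the feedback-coupled simulator)
event_rates_with_alpha <- function(events, alpha) {
  events$rate[events$type == "entry"] <- alpha
  events$rate
}
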