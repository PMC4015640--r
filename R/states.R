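#' Enumerate the reachable occupancy states of the lattice
#'
#' A reachable mRNA state is an occupancy vector over the `n` codons in
#' which every ribosome covers exactly `r` consecutive codons: the
#' occupied codons decompose uniquely into disjoint runs of `r`
#' consecutive ones whose head positions are at least `r` apart.  For
#' `r = 1` all `2^n` occupancy vectors are reachable.  The number of
#' reachable states is `sum_k choose(n - k*r + k, k)` over feasible
#' ribosome counts `k`.
#'
#' Canonical order: states are sorted by ribosome count, descending,
#' and within a count lexicographically by the ascending tuple of head
#' positions.  For `n = 2, r = 1` this gives `[1 1], [1 0], [0 1],
#' [0 0]`.  The order is a package convention (it makes small transition
#' matrices directly readable); no ordering is canonical in the field.
#'
#' @param model a [translation_model()], or an integer `n` when `r` is
#'   given.
#' @param r footprint, used only when `model` is given as an integer.
#' @return An object of class `"lattice_states"`: a list with `x` (an
#'   `m x n` 0/1 integer matrix, one row per state in canonical order),
#'   `key` (states serialized as strings of 0/1 characters, codon 1
#'   leftmost), `heads` (list of head-position vectors), and `n`, `r`.
#' @examples
#' enumerate_states(3, 2)$key   # "110" "011" "000"
#' @export
enumerate_states <- function(model, r = NULL) {
  if (inherits(model, "translation_model")) {
    n <- model$n; r <- model$r
  } else {
    n <- as.integer(model); r <- as.integer(r)
    if (length(n) != 1L || length(r) != 1L || is.na(n) || is.na(r) ||
        n < 1L || r < 1L || r > n)
      stop("need 1 <= r <= n", call. = FALSE)
  }
  kmax <- n %/% r
  heads <- vector("list", 0L)
  for (k in kmax:0) heads <- c(heads, head_tuples(n, r, k))
  m <- length(heads)
  x <- matrix(0L, nrow = m, ncol = n)
  for (i in seq_len(m)) {
    for (h in heads[[i]]) x[i, (h - r + 1L):h] <- 1L
  }
  structure(list(x = x, key = apply(x, 1L, paste0, collapse = ""),
                 heads = heads, n = n, r = r),
            class = "lattice_states")
}

# all ascending head tuples (h_1 < ... < h_k, h_1 >= r, gaps >= r,
# h_k <= n) in lexicographic order
head_tuples <- function(n, r, k) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  recurse <- function(prefix, lo) {
    depth <- length(prefix)
    if (depth == k) { out[[length(out) + 1L]] <<- prefix; return(invisible()) }
    # remaining ribosomes after this one need (k - depth - 1) * r codons
    hi <- n - (k - depth - 1L) * r
    if (lo > hi) return(invisible())
    for (h in lo:hi) recurse(c(prefix, h), h + r)
  }
  recurse(integer(0), r)
  out
}

#' Closed-form count of reachable states
#'
#' `sum_k choose(n - k*r + k, k)` over ribosome counts
#' `k = 0, ..., floor(n / r)`.
#'
#' @inheritParams enumerate_states
#' @return Integer count of reachable occupancy states.
#' @examples
#' count_states(3, 2)   # 3
#' count_states(50, 12) # 1113
#' @export
count_states <- function(model, r = NULL) {
  if (inherits(model, "translation_model")) {
    n <- model$n; r <- model$r
  } else n <- as.integer(model)
  k <- 0:(n %/% r)
  as.integer(sum(choose(n - k * r + k, k)))
}

#' @export
print.lattice_states <- function(x, ...) {
  cat(sprintf("Reachable lattice states: n = %d, r = %d, %d states\n",
              x$n, x$r, length(x$key)))
  show <- utils::head(x$key, 10L)
  cat("  ", paste(show, collapse = " "),
      if (length(x$key) > 10L) "..." else "", "\n")
  invisible(x)
}

# is an occupancy vector a union of disjoint r-runs (head gaps >= r)?
is_reachable_state <- function(x, r) {
  n <- length(x)
  i <- 1L
  last_head <- -Inf
  while (i <= n) {
    if (x[i] == 0L) { i <- i + 1L; next }
    if (i + r - 1L > n || any(x[i:(i + r - 1L)] != 1L)) return(FALSE)
    head <- i + r - 1L
    if (head - last_head < r) return(FALSE)  # cannot happen with run scan
    last_head <- head
    i <- head + 1L
  }
  TRUE
}

# ---- event applicability ------------------------------------------------

# logical vector over the event-table rows; reduced predicates are the
# footprint-aware simplifications valid on reachable states (entry <=>
# codon r empty, exit <=> codon n occupied); full = window predicates
event_allowed_vec <- function(x, events, n, r, reduced = TRUE) {
  ok <- logical(nrow(events))
  ent <- events$type == "entry"
  if (any(ent))
    ok[ent] <- if (reduced) x[r] == 0L else all(x[1:r] == 0L)
  mv <- events$type %in% c("hop", "dissoc")
  if (any(mv)) {
    p <- events$pos[mv]
    if (reduced) {
      ok[mv] <- x[p] == 1L & x[p + 1L] == 0L
    } else {
      ok[mv] <- vapply(p, function(i)
        all(x[(i - r + 1L):i] == 1L) && x[i + 1L] == 0L, logical(1))
    }
  }
  ext <- events$type == "exit"
  if (any(ext))
    ok[ext] <- if (reduced) x[n] == 1L else all(x[(n - r + 1L):n] == 1L)
  ok
}

#' Events allowed in a given state
#'
#' The occurrence condition of each event: entry requires the first `r`
#' codons empty, a hop (or premature dissociation) at head position `i`
#' requires codon `i` occupied and codon `i+1` empty, and exit requires
#' codon `n` occupied.  On reachable states the entry/exit conditions
#' reduce to codon `r` empty / codon `n` occupied; both the reduced
#' predicates (default) and the full window predicates are available.
#'
#' @param x occupancy vector (0/1, length `n`) or a state key string.
#' @param model a [translation_model()].
#' @param reduced use the reduced predicates (default) or the full
#'   window predicates.
#' @return The subset of [event_table()] rows whose events are allowed
#'   in `x`.
#' @examples
#' toy <- translation_model(2, 1, alpha = 0.6, beta = 0.4, gamma = 1)
#' allowed_events(c(0, 1), toy)  # entry and exit
#' @export
allowed_events <- function(x, model, reduced = TRUE) {
  stopifnot(inherits(model, "translation_model"))
  x <- as_state(x, model$n)
  if (!is_reachable_state(x, model$r))
    stop("state is not reachable: occupied codons must form disjoint runs of length r",
         call. = FALSE)
  ev <- model$events
  ev[event_allowed_vec(x, ev, model$n, model$r, reduced), , drop = FALSE]
}

as_state <- function(x, n) {
  if (is.character(x) && length(x) == 1L)
    x <- as.integer(strsplit(x, "")[[1]])
  x <- as.integer(x)
  if (length(x) != n || any(is.na(x)) || any(x < 0L | x > 1L))
    stop(sprintf("state must be a 0/1 vector of length %d", n), call. = FALSE)
  x
}

# ---- event application --------------------------------------------------

# total on reachable states: identity when the event is not allowed
apply_event_x <- function(x, type, pos, n, r) {
  switch(type,
    entry = { x[1:r] <- 1L; x },
    hop = { x[pos - r + 1L] <- 0L; x[pos + 1L] <- 1L; x },
    dissoc = { x[(pos - r + 1L):pos] <- 0L; x },
    exit = { x[(n - r + 1L):n] <- 0L; x },
    stop("unknown event type: ", type))
}

#' Apply an event to a state
#'
#' Entry sets codons `1..r` to 1; a hop with head at `i` clears codon
#' `i - r + 1` and fills codon `i + 1`; exit clears codons `n-r+1..n`;
#' premature dissociation at `j` clears codons `j-r+1..j`.  Applying an
#' event that is not allowed in `x` returns `x` unchanged (the identity
#' branch of the Boolean event rules), so the map is total on reachable
#' states and closed over the reachable set.
#'
#' @inheritParams allowed_events
#' @param event an event identified by its head position (0 = entry,
#'   `n` = exit, `r..n-1` = hop), by its label (e.g. `"alpha"`,
#'   `"gamma_25"`, `"dissoc_25"`, `"beta"`), or by a one-row subset of
#'   [event_table()].
#' @return The resulting occupancy vector.
#' @examples
#' m <- translation_model(3, 2, alpha = 1, beta = 1, gamma = 1)
#' apply_event(c(0, 0, 0), 0, m)  # entry -> 1 1 0
#' @export
apply_event <- function(x, event, model) {
  stopifnot(inherits(model, "translation_model"))
  x <- as_state(x, model$n)
  ev <- resolve_event(event, model)
  if (!event_allowed_vec(x, ev, model$n, model$r)[1L]) return(x)
  apply_event_x(x, ev$type, ev$pos, model$n, model$r)
}

resolve_event <- function(event, model) {
  ev <- model$events
  if (is.data.frame(event)) {
    stopifnot(nrow(event) == 1L)
    return(event)
  }
  if (is.character(event)) {
    k <- which(ev$label == event)
  } else {
    pos <- as.integer(event)
    k <- which(ev$pos == pos & ev$type != "dissoc")
    if (length(k) == 0L) k <- which(ev$pos == pos)
  }
  if (length(k) != 1L)
    stop("cannot resolve event: ", deparse(substitute(event)), call. = FALSE)
  ev[k, , drop = FALSE]
}

#' Occurrence probability of an event in a single state
#'
#' The indicator `psi_i(x)`: 1 if event `i` is allowed in state `x`,
#' else 0, so that the actual event rate is
#' `p_i(x) = psi_i(x) * gamma_i`.  Averaged over a stationary
#' distribution this becomes the mean occurrence probability whose
#' balanced flux `psi_i * gamma_i = c` characterizes the steady state.
#'
#' @inheritParams apply_event
#' @return 0 or 1.
#' @export
occurrence_probability <- function(x, event, model) {
  stopifnot(inherits(model, "translation_model"))
  x <- as_state(x, model$n)
  ev <- resolve_event(event, model)
  as.numeric(event_allowed_vec(x, ev, model$n, model$r)[1L])
}
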