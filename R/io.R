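#' Load a model configuration from a YAML file
#'
#' One documented dialect: a YAML mapping with keys `n`, `r`, `alpha`,
#' `beta`, `gamma` (scalar or list), and optional regulation blocks
#' `slow_codons` (list of `{position, rate}` mappings),
#' `premature_stop` (`{position, mu}`) and `feedback`
#' (`{alpha_I, k_I, d_I, rho_m}`).  Unknown keys are rejected with
#' their key paths; defaults (`r = 1`, `rho_m = 1`) are filled by the
#' constructor.
#'
#' @param path path to a YAML file.
#' @return A [translation_model()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  model_from_config(cfg)
}

#' @rdname load_config
#' @param cfg a configuration as a named list (the parsed YAML form).
#' @export
model_from_config <- function(cfg) {
  allowed <- c("n", "r", "alpha", "beta", "gamma", "slow_codons",
               "premature_stop", "feedback")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sc <- NULL
  if (!is.null(cfg$slow_codons)) {
    entries <- cfg$slow_codons
    if (!is.list(entries) || !length(entries))
      stop("slow_codons must be a list of {position, rate} entries",
           call. = FALSE)
    for (e in entries)
      validate_block(e, c("position", "rate"), c("position", "rate"),
                     "slow_codons entry")
    sc <- list(positions = vapply(entries, function(e) as.integer(e$position),
                                  integer(1)),
               rate = vapply(entries, function(e) as.numeric(e$rate),
                             numeric(1)))
  }
  translation_model(
    n = cfg$n, r = if (is.null(cfg$r)) 1L else cfg$r,
    alpha = if (is.null(cfg$alpha)) {
      if (is.null(cfg$feedback)) stop("config requires 'alpha'", call. = FALSE)
      cfg$feedback$alpha_I
    } else cfg$alpha,
    beta = cfg$beta,
    gamma = if (is.null(cfg$gamma)) NULL else unlist(cfg$gamma),
    slow_codons = sc, premature_stop = cfg$premature_stop,
    feedback = cfg$feedback)
}

#' Save a model configuration to YAML
#'
#' Writes the fully resolved configuration; `load_config(save_config(m))`
#' reproduces the model.
#'
#' @param model a [translation_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(model, path) {
  stopifnot(inherits(model, "translation_model"))
  yaml::write_yaml(config_list(model), path)
  invisible(path)
}

# the resolved configuration of a model as a plain list (for provenance
# embedding in result files)
config_list <- function(model) {
  cfg <- list(n = model$n, r = model$r, alpha = model$alpha,
              beta = model$beta)
  if (length(model$gamma)) {
    g <- unname(model$gamma)
    cfg$gamma <- if (length(unique(g)) == 1L) g[1L] else as.list(g)
  }
  if (!is.null(model$premature_stop))
    cfg$premature_stop <- model$premature_stop[c("position", "mu")]
  if (!is.null(model$feedback))
    cfg$feedback <- model$feedback[c("alpha_I", "k_I", "d_I", "rho_m")]
  cfg
}

#' Write a result object to JSON
#'
#' Serializes a steady-state or simulation result together with the
#' fully resolved model configuration and the package version, at full
#' numeric precision (byte-identical across identical invocations).
#' States are serialized as strings of 0/1 characters, codon 1
#' leftmost.
#'
#' @param x a `"pbn_steady_state"`, `"translation_sim"`,
#'   `"heinrich_steady_state"`, `"petri_sim"` or plain list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(summary_list(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

summary_list <- function(x) {
  meta <- list(package = "ribotraffic",
               version = as.character(utils::packageVersion("ribotraffic")))
  if (inherits(x, "pbn_steady_state")) {
    list(meta = meta, config = config_list(x$model), solver = "pbn",
         states = x$states$key, pi = unname(x$pi), rho = x$rho, c = x$c,
         mean_occupancy = x$mean_occupancy)
  } else if (inherits(x, "translation_sim")) {
    out <- list(meta = meta, config = config_list(x$model),
                solver = paste0("simulation/", x$algorithm),
                rho = x$rho, c = x$c, mean_occupancy = x$mean_occupancy,
                total_time = x$total_time, n_events = as.list(x$n_events),
                steps = x$nsim, burn_in = x$burn_in,
                seed = x$seed, degenerate = x$degenerate)
    if (!is.null(x$state_freq)) out$state_freq <- as.list(x$state_freq)
    if (!is.null(x$rho_I_mean)) out$rho_I_mean <- x$rho_I_mean
    out
  } else if (inherits(x, "heinrich_steady_state")) {
    list(meta = meta, config = config_list(x$model), solver = "heinrich",
         h = x$h, rho = x$rho, W = as.list(x$W), flux = as.list(x$flux),
         c = x$c)
  } else if (inherits(x, "petri_sim")) {
    list(meta = meta, config = config_list(x$model), solver = "petri",
         rho = x$rho, c = x$rate, exit_times = x$exit_times)
  } else {
    c(list(meta = meta), unclass(x))
  }
}

#' Write per-codon densities to CSV
#'
#' Columns `codon, density`; comma-separated, header row, `.` decimal
#' mark, 6 significant digits by default.
#'
#' @param x an object with a `rho` component (any solver result).
#' @param path output path.
#' @param digits significant digits.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(x, path, digits = 6L) {
  rho <- if (!is.null(x$rho)) x$rho else stop("object carries no 'rho'")
  df <- data.frame(codon = seq_along(rho),
                   density = formatC(signif(rho, digits), format = "g",
                                     digits = digits))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an event log to TSV
#'
#' Columns `time, event, state` for a run recorded with
#' `record_events = TRUE`.
#'
#' @param sim a `"translation_sim"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(sim, path) {
  stopifnot(inherits(sim, "translation_sim"))
  if (is.null(sim$events_log))
    stop("run was not recorded with record_events = TRUE", call. = FALSE)
  utils::write.table(sim$events_log, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
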