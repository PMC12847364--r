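# Run configuration: defaults, YAML loading, validation.

#' Default analysis settings
#'
#' Every analysis constant of the decoding pipeline, surfaced as a named,
#' overridable setting: the 250 Hz working rate, the epoch window, the nine
#' 4 Hz filter-bank bands spanning 4-40 Hz with 251 filter taps, 5 CSP
#' filter pairs per band, 25 selected features over 5 discretization bins,
#' a 100-tree random forest, 5 x 10-fold cross-validation, significance
#' level 0.05 and 100 permutations.
#'
#' @return Named list of analysis settings.
#' @export
analysis_defaults <- function() {
  list(
    target_fs = 250,
    epoch_window = c(-0.5, 4.0),
    bands = lapply(seq(4, 36, by = 4), function(lo) c(lo, lo + 4)),
    numtaps = 251,
    n_pairs = 5,
    n_filters = 10,
    selector_k = 25,
    n_bins = 5,
    n_trees = 100,
    n_folds = 10,
    n_repeats = 5,
    alpha = 0.05,
    n_perm = 100,
    scenario_sizes = c(2, 4, 5, 6)
  )
}

.validate_analysis <- function(a) {
  chk <- function(ok, key, msg) if (!ok) stopf("config key '%s': %s", key, msg)
  chk(is.numeric(a$target_fs) && a$target_fs > 0, "target_fs",
      "must be a positive rate in Hz")
  chk(length(a$epoch_window) == 2 && a$epoch_window[1] < a$epoch_window[2],
      "epoch_window", "must be an increasing [start, end) pair in seconds")
  for (b in a$bands) {
    chk(length(b) == 2 && b[1] > 0 && b[1] < b[2], "bands",
        "each band must be c(low, high) with 0 < low < high")
  }
  chk(is_count(a$numtaps) && a$numtaps %% 2 == 1, "numtaps",
      "must be an odd positive integer")
  chk(is_count(a$n_pairs), "n_pairs", "must be a positive integer")
  chk(is_count(a$n_filters), "n_filters", "must be a positive integer")
  chk(is_count(a$selector_k), "selector_k", "must be a positive integer")
  chk(is_count(a$n_bins) && a$n_bins >= 2, "n_bins", "must be >= 2")
  chk(is_count(a$n_trees), "n_trees", "must be a positive integer")
  chk(is_count(a$n_folds) && a$n_folds >= 2, "n_folds", "must be >= 2")
  chk(is_count(a$n_repeats), "n_repeats", "must be a positive integer")
  chk(is.numeric(a$alpha) && a$alpha > 0 && a$alpha < 1, "alpha",
      "must lie in (0, 1)")
  chk(is_count(a$n_perm), "n_perm", "must be a positive integer")
  chk(all(a$scenario_sizes %in% 2:6), "scenario_sizes",
      "sizes must lie in 2..6")
  a
}

#' Load and validate a run configuration
#'
#' Reads a YAML file with up to three top-level sections — `protocol`,
#' `sim`, `analysis` — each containing overrides for [protocol_config()],
#' [sim_config()] and [analysis_defaults()] respectively. Missing keys get
#' their defaults; unknown keys are rejected with an error naming the key.
#' An empty (or missing-section) file yields the full default configuration.
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @return List with validated `protocol` ([protocol_config()]), `sim`
#'   ([sim_config()]) and `analysis` (named list) components, plus a
#'   `hash` fingerprint.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  unknown <- setdiff(names(user), c("protocol", "sim", "analysis"))
  if (length(unknown) > 0) {
    stopf("unknown config section(s): %s", paste(unknown, collapse = ", "))
  }
  build <- function(section, fn, defaults_names) {
    args <- user[[section]] %||% list()
    bad <- setdiff(names(args), defaults_names)
    if (length(bad) > 0) {
      stopf("unknown key(s) in config section '%s': %s", section,
            paste(bad, collapse = ", "))
    }
    # YAML lists arrive as plain lists; flatten numeric vectors
    args <- lapply(args, function(v) {
      if (is.list(v) && all(vapply(v, is.numeric, logical(1))) &&
          all(lengths(v) == 1)) unlist(v) else v
    })
    do.call(fn, args)
  }
  protocol <- build("protocol", protocol_config,
                    setdiff(names(formals(protocol_config)), ""))
  sim <- build("sim", sim_config, setdiff(names(formals(sim_config)), ""))
  analysis <- analysis_defaults()
  a_user <- user$analysis %||% list()
  bad <- setdiff(names(a_user), names(analysis))
  if (length(bad) > 0) {
    stopf("unknown key(s) in config section 'analysis': %s",
          paste(bad, collapse = ", "))
  }
  for (k in names(a_user)) {
    v <- a_user[[k]]
    if (k == "bands") {
      v <- lapply(v, unlist)
    } else if (is.list(v)) {
      v <- unlist(v)
    }
    analysis[[k]] <- v
  }
  analysis <- .validate_analysis(analysis)
  out <- list(protocol = protocol, sim = sim, analysis = analysis)
  out$hash <- config_hash(out)
  out
}
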