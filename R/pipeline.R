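# End-to-end study orchestration with deterministic seed fan-out.

.stage_log <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run a full simulated study
#'
#' Simulates `n_participants` sessions under one configuration, runs the
#' preprocessing and decoding pipeline for every configured scenario size,
#' computes binomial significance thresholds, and writes report tables and
#' a run manifest. One global seed fans out deterministically to every
#' participant, scenario and stage via [derive_seed()]; re-running with the
#' same configuration and seed reproduces all outputs.
#'
#' @param config A [load_config()] result, a YAML path, or `NULL` for
#'   defaults.
#' @param out_dir Output directory for tables and the manifest.
#' @param seed Global integer seed.
#' @param n_participants Number of simulated participants.
#' @param participant_scale_sd Log-normal spread of the per-participant
#'   effect-size multiplier (0 = identical participants).
#' @param scenario_sizes Overrides `config$analysis$scenario_sizes`.
#' @param max_scenarios_per_size Optional cap on scenarios per size (first
#'   `n` in enumeration order), to bound runtime on exploratory runs.
#' @return Invisibly, a list with `results` (scenario_result list),
#'   `report`, `thresholds` and `manifest`.
#' @export
run_study <- function(config = NULL, out_dir, seed = 1L,
                      n_participants = 1, participant_scale_sd = 0.25,
                      scenario_sizes = NULL,
                      max_scenarios_per_size = NULL) {
  if (is.null(config) || is.character(config)) {
    config <- load_config(config)
  }
  protocol <- config$protocol
  analysis <- config$analysis
  sizes <- scenario_sizes %||% analysis$scenario_sizes
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  bank <- design_filterbank(
    filterbank_spec(analysis$bands, analysis$numtaps), analysis$target_fs)
  results <- list()
  stages <- list()
  for (p in seq_len(n_participants)) {
    pid <- sprintf("P%02d", p)
    sim_p <- config$sim
    sim_p$participant_scale <- with_seed(
      derive_seed(seed, "scale", p),
      exp(stats::rnorm(1, 0, participant_scale_sd)))
    .stage_log("simulate %s (effect multiplier %.2f)", pid,
               sim_p$participant_scale)
    sess <- simulate_session(protocol, sim_p, seed = derive_seed(seed, p),
                             participant_id = pid)
    .stage_log("preprocess %s: %d events @ %g Hz -> %g Hz", pid,
               nrow(sess$raw$events), sess$raw$fs, analysis$target_fs)
    epochs <- preprocess(sess$raw, analysis, plan = sess$plan,
                         subjective = sess$subjective)
    for (k in sizes) {
      scenarios <- enumerate_scenarios(protocol$task_names, k)
      if (!is.null(max_scenarios_per_size)) {
        scenarios <- utils::head(scenarios, max_scenarios_per_size)
      }
      for (sc in scenarios) {
        cv <- cv_config(n_folds = analysis$n_folds,
                        n_repeats = analysis$n_repeats,
                        selector_k = analysis$selector_k,
                        n_bins = analysis$n_bins,
                        n_pairs = analysis$n_pairs,
                        n_filters = analysis$n_filters,
                        n_trees = analysis$n_trees,
                        seed = derive_seed(seed, p, "cv", k,
                                           paste(sc$tasks, collapse = "+")))
        res <- crossvalidate_scenario(epochs, sc, cv, bank = bank)
        .stage_log("decode %s %d-class [%s]: %.1f%%", pid, k,
                   paste(sc$tasks, collapse = "+"), res$mean)
        results[[length(results) + 1]] <- res
      }
    }
    stages[[pid]] <- list(participant = pid,
                          seed = derive_seed(seed, p),
                          n_trials = nrow(sess$plan$trials))
  }
  report <- build_report(results, alpha = analysis$alpha,
                         out_dir = out_dir, tasks = protocol$task_names)
  thresholds <- lapply(report$thresholds, function(t) t$threshold_pct)
  manifest <- list(
    config_hash = config$hash %||% config_hash(config),
    seed = as.integer(seed),
    n_participants = n_participants,
    scenario_sizes = sizes,
    stages = stages,
    package_version = as.character(utils::packageVersion("imagerybci"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(results = results, report = report,
                 thresholds = thresholds, manifest = manifest))
}

#' Run one pipeline stage in isolation
#'
#' Executes a single stage against on-disk artifacts, guarded by the config
#' fingerprint: each stage records the configuration hash next to its
#' output, and a downstream stage refuses to consume an artifact produced
#' under a different configuration.
#'
#' Stages: `"simulate"` (writes a BrainVision triplet, events TSV and
#' subjective TSV), `"preprocess"` (BrainVision -> epoch container),
#' `"decode"` (epoch container -> per-scenario accuracy TSV),
#' `"stats"` (accuracy TSV -> thresholds TSV).
#'
#' @param stage_name One of `"simulate"`, `"preprocess"`, `"decode"`,
#'   `"stats"`.
#' @param config A [load_config()] result, YAML path, or `NULL`.
#' @param in_path Input artifact basepath (not used by `"simulate"`).
#' @param out_path Output artifact basepath.
#' @param seed Integer seed.
#' @param scenario_size Scenario size for the `"decode"` stage.
#' @return Invisibly, the output basepath.
#' @export
run_stage <- function(stage_name, config = NULL, in_path = NULL, out_path,
                      seed = 1L, scenario_size = 2) {
  if (is.null(config) || is.character(config)) config <- load_config(config)
  hash <- config$hash %||% config_hash(config)
  stamp <- function(base) {
    jsonlite::write_json(list(config_hash = hash, stage = stage_name),
                         paste0(base, ".stage.json"), auto_unbox = TRUE)
  }
  check <- function(base) {
    meta_path <- paste0(base, ".stage.json")
    if (!file.exists(meta_path)) {
      stopf("input artifact %s has no stage metadata; rerun its stage", base)
    }
    meta <- jsonlite::read_json(meta_path)
    if (!identical(meta$config_hash, hash)) {
      stopf("stale artifact %s: produced under config %s but current is %s",
            base, meta$config_hash, hash)
    }
  }
  dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
  if (stage_name == "simulate") {
    sess <- simulate_session(config$protocol, config$sim, seed = seed)
    write_brainvision(sess$raw, out_path)
    write_events_tsv(sess$raw, paste0(out_path, ".events.tsv"))
    write_subjective_tsv(sess$subjective, paste0(out_path, ".subjective.tsv"))
    .stage_log("simulate: %d trials -> %s", nrow(sess$plan$trials), out_path)
  } else if (stage_name == "preprocess") {
    check(in_path)
    raw <- read_brainvision(paste0(in_path, ".vhdr"),
                            task_names = config$protocol$task_names)
    epochs <- preprocess(raw, config$analysis)
    se_path <- paste0(in_path, ".subjective.tsv")
    if (file.exists(se_path)) {
      tab <- utils::read.table(se_path, sep = "\t", header = TRUE,
                               comment.char = "#",
                               stringsAsFactors = FALSE)
      epochs$self_eval <- factor(tab$self_eval,
                                 levels = c("correct", "not_correct",
                                            "correct_not_well"))
    }
    write_epochs(epochs, out_path)
    .stage_log("preprocess: %d epochs -> %s", dim(epochs$data)[1], out_path)
  } else if (stage_name == "decode") {
    check(in_path)
    epochs <- read_epochs(in_path)
    scenarios <- enumerate_scenarios(config$protocol$task_names,
                                     scenario_size)
    a <- config$analysis
    rows <- lapply(scenarios, function(sc) {
      cv <- cv_config(n_folds = a$n_folds, n_repeats = a$n_repeats,
                      selector_k = a$selector_k, n_bins = a$n_bins,
                      n_pairs = a$n_pairs, n_filters = a$n_filters,
                      n_trees = a$n_trees,
                      seed = derive_seed(seed, "cv",
                                         paste(sc$tasks, collapse = "+")))
      res <- crossvalidate_scenario(epochs, sc, cv)
      data.frame(tasks = paste(sc$tasks, collapse = "+"),
                 mean_pct = res$mean, sd_pct = res$sd,
                 n_folds = length(res$fold_acc))
    })
    utils::write.table(do.call(rbind, rows), paste0(out_path, ".tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .stage_log("decode: %d scenarios -> %s.tsv", length(rows), out_path)
  } else if (stage_name == "stats") {
    check(in_path)
    tab <- utils::read.table(paste0(in_path, ".tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
    k <- lengths(strsplit(tab$tasks, "+", fixed = TRUE))
    per_class <- config$protocol$trials_per_task_per_block *
      config$protocol$n_blocks
    thr <- vapply(k, function(kk) {
      binomial_threshold(per_class * kk, kk,
                         config$analysis$alpha)$threshold_pct
    }, numeric(1))
    out <- cbind(tab, threshold_pct = thr,
                 above_threshold = tab$mean_pct > thr)
    utils::write.table(out, paste0(out_path, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .stage_log("stats: %d rows -> %s.tsv", nrow(out), out_path)
  } else {
    stopf("unknown stage '%s'", stage_name)
  }
  stamp(out_path)
  invisible(out_path)
}
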