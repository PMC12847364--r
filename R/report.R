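# Report generation: per-size accuracy tables, thresholds, confusions.

.scenario_key <- function(res) paste(res$scenario$tasks, collapse = "+")

#' Build report tables from scenario results
#'
#' Aggregates a flat list of `scenario_result`s (across participants) into
#' per-size tables of grand mean accuracy with standard deviation across
#' participants, the binomial significance threshold for each size, the
#' pairwise upper-triangular matrix layout for the 2-class scenarios, and
#' pooled confusion matrices. Tables are written as TSV files, each
#' carrying the cross-validation config fingerprint in a footer comment.
#'
#' @param results List of `scenario_result` objects; mixing different
#'   cross-validation configurations is an error.
#' @param alpha Significance level for the threshold rows.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing and returns the tables only.
#' @param tasks Task vocabulary ordering the pairwise layout.
#' @return Invisibly, a list with `tables` (one data.frame per scenario
#'   size), `pairwise` (2-class matrix layout, if any 2-class results),
#'   `thresholds`, `confusions`, and `files`.
#' @export
build_report <- function(results, alpha = 0.05, out_dir = NULL,
                         tasks = imagery_tasks()) {
  if (length(results) == 0) stopf("no results to report")
  for (r in results) stopifnot(inherits(r, "scenario_result"))
  hashes <- vapply(results, function(r) {
    config_hash(r$cv[setdiff(names(r$cv), "seed")])
  }, character(1))
  if (length(unique(hashes)) > 1) {
    stopf("results mix different cross-validation configurations")
  }
  hash <- hashes[1]
  sizes <- vapply(results, function(r) r$scenario$k, numeric(1))
  tables <- list(); thresholds <- list(); confusions <- list()
  files <- character(0)
  for (k in sort(unique(sizes))) {
    rs <- results[sizes == k]
    keys <- vapply(rs, .scenario_key, character(1))
    df <- do.call(rbind, lapply(unique(keys), function(key) {
      sub <- rs[keys == key]
      means <- vapply(sub, function(r) r$mean, numeric(1))
      data.frame(tasks = key,
                 mean_pct = mean(means),
                 sd_pct = if (length(means) > 1) stats::sd(means) else NA_real_,
                 n_participants = length(means),
                 n_folds = length(sub[[1]]$fold_acc),
                 stringsAsFactors = FALSE)
    }))
    n_trials <- max(vapply(rs, function(r) r$n_trials, numeric(1)))
    thr <- binomial_threshold(n_trials, k, alpha)
    tables[[as.character(k)]] <- df
    thresholds[[as.character(k)]] <- thr
    # pooled confusion over participants (matching class sets only)
    conf <- Reduce(`+`, lapply(rs[keys == keys[1]],
                               function(r) r$confusion))
    confusions[[keys[1]]] <- conf
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      path <- file.path(out_dir, sprintf("accuracy_%dclass.tsv", k))
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      cat(sprintf("# significance_threshold_pct\t%.1f\n# config_hash\t%s\n",
                  thr$threshold_pct, hash),
          file = path, append = TRUE)
      files <- c(files, path)
    }
  }
  pairwise <- NULL
  if ("2" %in% names(tables)) {
    pairwise <- matrix(NA_real_, length(tasks), length(tasks),
                       dimnames = list(tasks, tasks))
    for (i in seq_len(nrow(tables[["2"]]))) {
      pair <- strsplit(tables[["2"]]$tasks[i], "+", fixed = TRUE)[[1]]
      if (all(pair %in% tasks)) {
        a <- min(match(pair, tasks)); b <- max(match(pair, tasks))
        pairwise[a, b] <- tables[["2"]]$mean_pct[i]
      }
    }
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, "accuracy_2class_matrix.tsv")
      utils::write.table(round(pairwise, 1), path, sep = "\t", quote = FALSE,
                         col.names = NA)
      files <- c(files, path)
    }
  }
  if (!is.null(out_dir)) {
    for (key in names(confusions)) {
      path <- file.path(out_dir,
                        sprintf("confusion_%s.tsv", gsub("\\+", "_", key)))
      utils::write.table(confusions[[key]], path, sep = "\t", quote = FALSE,
                         col.names = NA)
      files <- c(files, path)
    }
  }
  invisible(list(tables = tables, pairwise = pairwise,
                 thresholds = thresholds, confusions = confusions,
                 files = files, config_hash = hash))
}
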