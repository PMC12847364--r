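# Scenario enumeration, random-forest classification, and leakage-safe
# repeated stratified cross-validation.

#' Enumerate classification scenarios
#'
#' All task subsets of size `k` from the 7-task vocabulary, subject to the
#' design rule that for `k > 2` a subset may contain at most one of the two
#' singing-imagery variants (both may appear together only as a pair in the
#' binary analysis). With the default vocabulary this yields 21, 25, 11 and
#' 2 scenarios for k = 2, 4, 5 and 6. Order is deterministic
#' (lexicographic in task positions).
#'
#' @param tasks Task vocabulary (default [imagery_tasks()]).
#' @param k Subset size, one of 2, 4, 5, 6.
#' @return List of `scenario_spec` objects (fields `tasks`, `k`).
#' @export
#' @examples
#' length(enumerate_scenarios(k = 4))  # 25
enumerate_scenarios <- function(tasks = imagery_tasks(), k) {
  if (!k %in% c(2, 4, 5, 6)) {
    stopf("scenario size k must be one of 2, 4, 5, 6 (got %s)", k)
  }
  combos <- utils::combn(tasks, k, simplify = FALSE)
  si <- c("SIkin", "SInoKin")
  if (k > 2 && all(si %in% tasks)) {
    combos <- Filter(function(s) sum(si %in% s) <= 1, combos)
  }
  lapply(combos, function(s) {
    structure(list(tasks = s, k = k), class = "scenario_spec")
  })
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %d-class: %s\n", x$k,
              paste(x$tasks, collapse = " + ")))
  invisible(x)
}

#' Cross-validation configuration
#'
#' @param n_folds Folds per repeat (default 10).
#' @param n_repeats Repeats with reshuffled folds (default 5).
#' @param stratified Stratify folds by class (default `TRUE`), guaranteeing
#'   every class appears in every training fold.
#' @param selector_k Features kept by mRMR (default 25).
#' @param n_bins Discretization bins for mutual information (default 5).
#' @param n_pairs CSP filter pairs per band for binary scenarios.
#' @param n_filters CSP filters per band for multiclass scenarios.
#' @param n_trees Trees in the random forest (default 100).
#' @param csp `"auto"` (binary CSP for 2-class scenarios, joint
#'   diagonalization otherwise) or `"multiclass"` (use the multiclass
#'   fitter for binary problems too).
#' @param refit_selector Fit discretization and mRMR inside every training
#'   fold (default `TRUE`, the leakage-safe rule). `FALSE` chooses the
#'   feature ranks once on the full data before splitting — a mildly leaky
#'   variant kept for methodological comparison only.
#' @param leak_demo Diagnostic switch: fit CSP, discretization and
#'   selection once on all trials and train only the classifier per fold.
#'   Inflates null accuracy by construction; never use for results.
#' @param loading Diagonal loading for covariance estimation (see
#'   [fit_csp_binary()]).
#' @param seed Integer seed controlling fold shuffling, forest seeds.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(n_folds = 10, n_repeats = 5, stratified = TRUE,
                      selector_k = 25, n_bins = 5, n_pairs = 5,
                      n_filters = 10, n_trees = 100,
                      csp = c("auto", "multiclass"),
                      refit_selector = TRUE, leak_demo = FALSE,
                      loading = 0, seed = 1L) {
  csp <- match.arg(csp)
  if (!is_count(n_folds) || n_folds < 2) stopf("n_folds must be >= 2")
  if (!is_count(n_repeats)) stopf("n_repeats must be a positive integer")
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 stratified = isTRUE(stratified),
                 selector_k = as.integer(selector_k),
                 n_bins = as.integer(n_bins),
                 n_pairs = as.integer(n_pairs),
                 n_filters = as.integer(n_filters),
                 n_trees = as.integer(n_trees),
                 csp = csp,
                 refit_selector = isTRUE(refit_selector),
                 leak_demo = isTRUE(leak_demo),
                 loading = loading,
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Train the random-forest classifier
#'
#' A bagged ensemble of `n_trees` (default 100) fully grown decision trees:
#' Gini impurity splits, unrestricted depth (nodes split until pure or
#' smaller than two samples), bootstrap resampling, and
#' `floor(sqrt(n_features))` split candidates per node; prediction is the
#' majority vote. Backed by `ranger`.
#'
#' @param X Numeric feature matrix (trials x features).
#' @param y Class labels (>= 2 classes present).
#' @param cfg A [cv_config()] (for `n_trees`).
#' @param seed Integer seed for the forest.
#' @return A fitted `ranger` object.
#' @export
train_classifier <- function(X, y, cfg = cv_config(), seed = cfg$seed) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stopf("classifier needs >= 2 classes in y")
  X <- as.matrix(X)
  colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  ranger::ranger(x = X, y = y,
                 num.trees = cfg$n_trees,
                 mtry = max(1, floor(sqrt(ncol(X)))),
                 min.node.size = 1,
                 splitrule = "gini",
                 replace = TRUE,
                 num.threads = 1,
                 seed = seed)
}

.predict_classifier <- function(fit, X, seed = 1L) {
  X <- as.matrix(X)
  colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  # an explicit seed keeps majority-vote tie-breaking reproducible
  stats::predict(fit, data = X, num.threads = 1, seed = seed)$predictions
}

#' Balanced accuracy
#'
#' Mean of per-class recalls over the classes present in `truth`; equals
#' plain accuracy when classes are exactly balanced.
#'
#' @param truth,pred Label vectors of equal length.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, pred) {
  truth <- factor(truth)
  pred <- factor(pred, levels = levels(truth))
  recalls <- vapply(levels(droplevels(truth)), function(cl) {
    idx <- truth == cl
    mean(pred[idx] == cl)
  }, numeric(1))
  mean(recalls)
}

# Stratified fold assignment: within each class, shuffle and deal trials
# round-robin into folds, starting from a random fold so that remainders
# spread evenly. Unstratified: plain shuffled deal.
.fold_assignment <- function(labels, n_folds, stratified) {
  n <- length(labels)
  folds <- integer(n)
  if (stratified) {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      start <- sample.int(n_folds, 1)
      folds[idx] <- 1 + (start + seq_along(idx) - 2) %% n_folds
    }
  } else {
    folds[sample.int(n)] <- rep_len(seq_len(n_folds), n)
  }
  folds
}

# Fold-wise pipeline on precomputed band covariances. Returns per-fold
# balanced accuracies, pooled confusion counts, and selected-feature
# frequencies. Everything label-dependent (CSP, discretization edges, mRMR,
# forest) is fitted on the training fold only unless cv$refit_selector is
# FALSE (leaky variant) — the covariances themselves are label-free.
.cv_core <- function(bc, labels, cv) {
  labels <- droplevels(factor(labels))
  k <- nlevels(labels)
  n <- length(labels)
  if (cv$selector_k > length(bc$bands) *
        (if (k == 2 && cv$csp == "auto") 2 * cv$n_pairs else cv$n_filters)) {
    stopf("selector_k exceeds the number of extracted features")
  }
  fit_csp <- function(idx) {
    if (k == 2 && cv$csp == "auto") {
      fit_csp_binary(bc_subset(bc, idx), n_pairs = cv$n_pairs,
                     loading = cv$loading)
    } else {
      fit_csp_multiclass(bc_subset(bc, idx), n_filters = cv$n_filters,
                         loading = cv$loading)
    }
  }
  full_model <- NULL; full_X <- NULL; full_sel <- NULL
  if (!cv$refit_selector || isTRUE(cv$leak_demo)) {
    # feature extraction and selection fitted once on ALL trials. This is
    # the deliberately leaky variant: as a diagnostic (`leak_demo`) the
    # fold loop reuses everything and trains only the classifier, which
    # measurably inflates null accuracy.
    full_model <- fit_csp(seq_len(n))
    full_X <- extract_logvar_features(bc, full_model)$X
    disc_full <- discretize_features(full_X, cv$n_bins)
    full_sel <- mrmr_select(disc_full$codes, labels, cv$selector_k)
  }
  acc <- matrix(NA_real_, cv$n_repeats, cv$n_folds)
  confusion <- matrix(0L, k, k, dimnames = list(levels(labels),
                                                levels(labels)))
  sel_freq <- NULL
  for (rep_i in seq_len(cv$n_repeats)) {
    folds <- with_seed(derive_seed(cv$seed, "folds", rep_i),
                       .fold_assignment(labels, cv$n_folds, cv$stratified))
    for (fold_i in seq_len(cv$n_folds)) {
      test <- which(folds == fold_i)
      train <- which(folds != fold_i)
      if (length(test) == 0) next  # fewer trials than folds; fold stays NA
      if (nlevels(droplevels(labels[train])) < k) {
        stopf("training fold %d/%d lost a class; use stratified folds",
              rep_i, fold_i)
      }
      if (isTRUE(cv$leak_demo)) {
        X_train <- full_X[train, , drop = FALSE]
        X_test <- full_X[test, , drop = FALSE]
        sel <- full_sel
      } else {
        model <- fit_csp(train)
        X_train <- extract_logvar_features(bc_subset(bc, train), model)$X
        X_test <- extract_logvar_features(bc_subset(bc, test), model)$X
        if (cv$refit_selector) {
          disc <- discretize_features(X_train, cv$n_bins)
          sel <- mrmr_select(disc$codes, labels[train], cv$selector_k)
        } else {
          sel <- full_sel  # feature ranks chosen once on all data
        }
      }
      if (is.null(sel_freq)) {
        sel_freq <- numeric(ncol(X_train))
      }
      sel_freq[sel] <- sel_freq[sel] + 1
      fit <- train_classifier(X_train[, sel, drop = FALSE], labels[train],
                              cv, seed = derive_seed(cv$seed, "rf", rep_i,
                                                     fold_i))
      pred <- .predict_classifier(fit, X_test[, sel, drop = FALSE],
                                  seed = derive_seed(cv$seed, "pred", rep_i,
                                                     fold_i))
      acc[rep_i, fold_i] <- balanced_accuracy(labels[test], pred)
      for (i in seq_along(test)) {
        confusion[as.integer(labels[test[i]]), as.integer(pred[i])] <-
          confusion[as.integer(labels[test[i]]), as.integer(pred[i])] + 1L
      }
    }
  }
  list(acc = acc, confusion = confusion, sel_freq = sel_freq)
}

# Subset a band_covs object by trial index.
bc_subset <- function(bc, idx) {
  structure(list(covs = bc$covs[, , idx, , drop = FALSE], bands = bc$bands,
                 labels = droplevels(bc$labels[idx]),
                 block = bc$block[idx], self_eval = bc$self_eval[idx],
                 channel_names = bc$channel_names,
                 participant_id = bc$participant_id),
            class = "band_covs")
}

#' Cross-validate one classification scenario
#'
#' Runs the full decoding pipeline — filter bank, CSP (binary or
#' joint-diagonalization multiclass), log-variance features,
#' equal-frequency discretization, mRMR selection, random forest — under
#' `n_repeats` x `n_folds` stratified cross-validation. Every
#' label-dependent stage is fitted on the training fold only; test folds
#' contribute exclusively to evaluation. Reports balanced accuracy per
#' fold and the pooled test-fold confusion matrix.
#'
#' @param epochs An `epoch_set` containing (at least) the scenario's tasks.
#' @param scenario A `scenario_spec` (or character vector of task labels).
#' @param cv A [cv_config()].
#' @param bank Optional pre-designed [design_filterbank()]; defaults to the
#'   standard 9-band bank at the epochs' rate.
#' @return An object of class `scenario_result`: `fold_acc`
#'   (n_repeats x n_folds, percent), `mean`, `sd`, `confusion`,
#'   `sel_freq`, `scenario`, `n_trials`.
#' @export
crossvalidate_scenario <- function(epochs, scenario, cv = cv_config(),
                                   bank = NULL) {
  if (is.character(scenario)) {
    scenario <- structure(list(tasks = scenario, k = length(scenario)),
                          class = "scenario_spec")
  }
  stopifnot(inherits(epochs, "epoch_set"))
  missing <- setdiff(scenario$tasks, levels(epochs$labels))
  if (length(missing) > 0) {
    stopf("epochs lack scenario task(s): %s", paste(missing, collapse = ", "))
  }
  if (is.null(bank)) {
    bank <- design_filterbank(filterbank_spec(), fs = epochs$fs)
  }
  keep <- which(epochs$labels %in% scenario$tasks)
  sub <- epoch_subset(epochs, keep)
  bc <- band_covariances(apply_filterbank(sub, bank))
  result_from_core(.cv_core(bc, sub$labels, cv), scenario, cv,
                   length(keep), epochs$participant_id)
}

# Internal: shared constructor for scenario results.
result_from_core <- function(core, scenario, cv, n_trials,
                             participant_id = NA_character_) {
  structure(
    list(fold_acc = 100 * core$acc,
         mean = mean(100 * core$acc, na.rm = TRUE),
         sd = stats::sd(100 * core$acc, na.rm = TRUE),
         confusion = core$confusion,
         sel_freq = core$sel_freq,
         scenario = scenario,
         cv = cv,
         n_trials = n_trials,
         participant_id = participant_id),
    class = "scenario_result")
}

# Subset an epoch_set by trial index.
epoch_subset <- function(epochs, idx) {
  structure(
    list(data = epochs$data[idx, , , drop = FALSE], fs = epochs$fs,
         window = epochs$window,
         labels = droplevels(epochs$labels[idx]),
         block = epochs$block[idx], self_eval = epochs$self_eval[idx],
         channel_names = epochs$channel_names,
         participant_id = epochs$participant_id),
    class = "epoch_set")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s: %.1f%% (sd %.1f) over %d folds, %d trials\n",
              paste(x$scenario$tasks, collapse = "+"), x$mean, x$sd,
              length(x$fold_acc), x$n_trials))
  invisible(x)
}
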