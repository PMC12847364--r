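# Chance-level thresholds, permutation nulls, effect sizes, correlations,
# and the trial-discard analysis.

#' Binomial chance-level significance threshold
#'
#' The inverse binomial-CDF rule for decoding accuracy: the threshold is
#' the smallest correct-count `k` with
#' `BinomCDF(k; n_trials, 1/n_classes) >= 1 - alpha`, expressed in percent.
#' For the full paradigm (70 trials per class) this gives 57.1% for 2
#' classes (n = 140), 29.3% for 4 classes (n = 280) and 19.8% for 6
#' classes (n = 420) at `alpha = 0.05`.
#'
#' @param n_trials Total classified trials in the scenario.
#' @param n_classes Number of classes (chance rate `1/n_classes`).
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return An object of class `significance_threshold` with fields
#'   `threshold_pct` (rounded to one decimal, as conventionally printed),
#'   `threshold_exact`, `k_correct`, `n_trials`, `n_classes`, `alpha`.
#' @export
#' @examples
#' binomial_threshold(140, 2)$threshold_pct  # 57.1
binomial_threshold <- function(n_trials, n_classes, alpha = 0.05) {
  if (!is_count(n_trials)) stopf("n_trials must be a positive integer")
  if (!is_count(n_classes) || n_classes < 2) stopf("n_classes must be >= 2")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stopf("alpha must lie in (0, 1)")
  }
  k <- stats::qbinom(1 - alpha, n_trials, 1 / n_classes)
  exact <- 100 * k / n_trials
  structure(list(threshold_pct = round(exact, 1),
                 threshold_exact = exact,
                 k_correct = k,
                 n_trials = n_trials, n_classes = n_classes, alpha = alpha),
            class = "significance_threshold")
}

#' @export
print.significance_threshold <- function(x, ...) {
  cat(sprintf(
    "<significance_threshold> %.1f%% (%d/%d correct, %d classes, alpha=%g)\n",
    x$threshold_pct, x$k_correct, x$n_trials, x$n_classes, x$alpha))
  invisible(x)
}

#' Two-sided binomial chance band
#'
#' The central `conf` interval of accuracies expected from random guessing
#' over `n_trials` decisions at rate `1/n_classes`, in percent. Used as a
#' null-calibration (leakage-detector) band for pipelines run on
#' effect-free data.
#'
#' @param n_trials Number of classified trials.
#' @param n_classes Number of classes.
#' @param conf Coverage, default 0.95.
#' @return Length-2 numeric `c(lower_pct, upper_pct)`.
#' @export
chance_band <- function(n_trials, n_classes, conf = 0.95) {
  a <- (1 - conf) / 2
  100 * stats::qbinom(c(a, 1 - a), n_trials, 1 / n_classes) / n_trials
}

#' Permutation-based significance of a decoding result
#'
#' Shuffles the trial labels `n_perm` times and re-runs the full
#' cross-validated pipeline on each shuffle, yielding a null distribution
#' of chance-level accuracies. Reports the empirical p-value
#' `(1 + #{null >= observed}) / (n_perm + 1)` alongside a one-sample
#' t-comparison of the null distribution against the observed accuracy
#' (the latter mirrors a common reporting convention; testing a
#' distribution against a scalar is statistically unconventional, so both
#' are labeled).
#'
#' @param epochs An `epoch_set`.
#' @param scenario A `scenario_spec` or character vector of tasks.
#' @param cv A [cv_config()].
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the shuffles.
#' @param bank Optional [design_filterbank()].
#' @return An object of class `permutation_result`: `observed_pct`, `null`
#'   (vector of permuted accuracies), `p_empirical`, `p_t`, `n_perm`,
#'   `seed`, and `warning` metadata when `n_perm` is too small for a
#'   p below 0.05.
#' @export
permutation_null <- function(epochs, scenario, cv = cv_config(),
                             n_perm = 100, seed = 1L, bank = NULL) {
  if (!is_count(n_perm)) stopf("n_perm must be a positive integer")
  if (is.character(scenario)) {
    scenario <- structure(list(tasks = scenario, k = length(scenario)),
                          class = "scenario_spec")
  }
  if (is.null(bank)) {
    bank <- design_filterbank(filterbank_spec(), fs = epochs$fs)
  }
  keep <- which(epochs$labels %in% scenario$tasks)
  sub <- epoch_subset(epochs, keep)
  bc <- band_covariances(apply_filterbank(sub, bank))
  observed <- mean(100 * .cv_core(bc, sub$labels, cv)$acc)
  null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    perm <- with_seed(derive_seed(seed, "perm", i),
                      sample(length(sub$labels)))
    cv_i <- cv
    cv_i$seed <- derive_seed(seed, "permcv", i)
    null[i] <- mean(100 * .cv_core(bc, sub$labels[perm], cv_i)$acc)
  }
  p_emp <- (1 + sum(null >= observed)) / (n_perm + 1)
  p_t <- if (n_perm >= 2 && stats::sd(null) > 0) {
    stats::t.test(null, mu = observed, alternative = "less")$p.value
  } else {
    NA_real_
  }
  warn <- if (n_perm < 19) {
    sprintf("n_perm=%d cannot resolve p < 0.05 (floor is %.3f)", n_perm,
            1 / (n_perm + 1))
  } else {
    NULL
  }
  structure(list(observed_pct = observed, null = null,
                 p_empirical = p_emp, p_t = p_t, n_perm = n_perm,
                 seed = as.integer(seed), warning = warn,
                 scenario = scenario),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed %.1f%%, null %.1f +- %.1f%%, p_emp=%.4g\n",
    x$observed_pct, mean(x$null), stats::sd(x$null), x$p_empirical))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Paired comparison of two conditions
#'
#' Two-sided paired t-test and paired Cohen's d
#' (`mean(x - y) / sd(x - y)`). A zero-variance difference is flagged as
#' degenerate instead of producing an undefined effect size.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return List with `t`, `df`, `p`, `cohens_d`, `mean_diff`, `degenerate`.
#' @export
#' @examples
#' compare_conditions(c(2, 4, 6), c(1, 2, 3))  # d = 2
compare_conditions <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stopf("x and y must be paired vectors of equal length >= 2")
  }
  d <- x - y
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, df = length(d) - 1,
                p = if (all(d == 0)) 1 else NA_real_,
                cohens_d = if (all(d == 0)) 0 else NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = mean(d) / stats::sd(d),
       mean_diff = mean(d), degenerate = FALSE)
}

#' Correlation between per-participant quantities
#'
#' Product-moment correlation with a two-sided test by default; a
#' rank-based (Spearman) option is available.
#'
#' @param a,b Numeric vectors of equal length >= 3.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `p`, `n`, `method`, `degenerate` (constant
#'   input).
#' @export
correlate <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(a) != length(b) || length(a) < 3) {
    stopf("a and b must have equal length >= 3")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(a), method = method,
                degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(a, b, method = method))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a),
       method = method, degenerate = FALSE)
}

#' Effect of discarding self-evaluated "bad" trials
#'
#' Arm 1 removes the trials the participant flagged (mode `"flagged_only"`:
#' the "did not perform correctly" answers; `"flagged_plus_weak"`: those
#' plus "correctly but not very well"). Arm 2 removes an equal number of
#' randomly chosen trials, count-matched per class so both arms leave
#' identical class totals. Both arms re-run the cross-validated scenario;
#' the paired accuracies indicate whether self-evaluation flags mark
#' genuinely poor data.
#'
#' @param epochs An `epoch_set` whose `self_eval` field is populated (or
#'   supplied via `self_eval`).
#' @param scenario A `scenario_spec` or character vector of tasks.
#' @param mode `"flagged_only"` or `"flagged_plus_weak"`.
#' @param cv A [cv_config()].
#' @param seed Integer seed for the matched random removal.
#' @param self_eval Optional factor overriding `epochs$self_eval`.
#' @param bank Optional [design_filterbank()].
#' @return An object of class `discard_comparison`: `accuracy_discarded`,
#'   `accuracy_random_matched`, `n_removed`, `mode`, plus both full
#'   `scenario_result`s.
#' @export
discard_analysis <- function(epochs, scenario,
                             mode = c("flagged_only", "flagged_plus_weak"),
                             cv = cv_config(), seed = 1L, self_eval = NULL,
                             bank = NULL) {
  mode <- match.arg(mode)
  if (is.character(scenario)) {
    scenario <- structure(list(tasks = scenario, k = length(scenario)),
                          class = "scenario_spec")
  }
  se <- self_eval %||% epochs$self_eval
  if (length(se) != dim(epochs$data)[1] || all(is.na(se))) {
    stopf("self_eval must cover every trial")
  }
  flagged_levels <- if (mode == "flagged_only") {
    "not_correct"
  } else {
    c("not_correct", "correct_not_well")
  }
  keep_scenario <- which(epochs$labels %in% scenario$tasks)
  sub <- epoch_subset(epochs, keep_scenario)
  se <- se[keep_scenario]
  flagged <- which(se %in% flagged_levels)
  # per-class removal counts for the matched arm
  removed_per_class <- table(factor(sub$labels[flagged],
                                    levels = levels(sub$labels)))
  total_per_class <- table(sub$labels)
  if (any(removed_per_class >= total_per_class - 1)) {
    stopf("mode '%s' removes (nearly) an entire class", mode)
  }
  random_removed <- with_seed(derive_seed(seed, "discard"), {
    unlist(lapply(levels(sub$labels), function(cl) {
      pool <- which(sub$labels == cl)
      if (removed_per_class[[cl]] == 0) return(integer(0))
      sample(pool, removed_per_class[[cl]])
    }))
  })
  stopifnot(length(random_removed) == length(flagged))
  if (is.null(bank)) {
    bank <- design_filterbank(filterbank_spec(), fs = sub$fs)
  }
  bc <- band_covariances(apply_filterbank(sub, bank))
  run_arm <- function(drop_idx) {
    keep <- setdiff(seq_along(sub$labels), drop_idx)
    bck <- bc_subset(bc, keep)
    result_from_core(.cv_core(bck, bck$labels, cv), scenario, cv,
                     length(keep), sub$participant_id)
  }
  res_flag <- run_arm(flagged)
  res_rand <- run_arm(random_removed)
  structure(list(mode = mode,
                 accuracy_discarded = res_flag$mean,
                 accuracy_random_matched = res_rand$mean,
                 n_removed = length(flagged),
                 result_discarded = res_flag,
                 result_random = res_rand),
            class = "discard_comparison")
}

#' @export
print.discard_comparison <- function(x, ...) {
  cat(sprintf(
    "<discard_comparison> %s: flagged-removed %.1f%% vs random-matched %.1f%% (n_removed=%d)\n",
    x$mode, x$accuracy_discarded, x$accuracy_random_matched, x$n_removed))
  invisible(x)
}
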