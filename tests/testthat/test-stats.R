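test_that("binomial thresholds reproduce the full-protocol printed values", {
  expect_equal(binomial_threshold(140, 2)$threshold_pct, 57.1)
  expect_equal(binomial_threshold(280, 4)$threshold_pct, 29.3)
  expect_equal(binomial_threshold(420, 6)$threshold_pct, 19.8)
  # small-sample worked example: Binomial(10, 0.5), smallest k with
  # CDF >= 0.95 is 8 -> 80%
  expect_equal(binomial_threshold(10, 2)$threshold_pct, 80.0)
  # the 5-class full-protocol case: the inverse-CDF rule gives 82/350,
  # i.e. 23.4% when rounded to one decimal (a printed 23.3% does not
  # follow from this rule; see the threshold documentation)
  thr5 <- binomial_threshold(350, 5)
  expect_equal(thr5$k_correct, 82)
  expect_equal(thr5$threshold_pct, 23.4)
  expect_error(binomial_threshold(0, 2), "positive")
  expect_error(binomial_threshold(100, 2, alpha = 0), "alpha")
})

test_that("thresholds decrease toward theoretical chance as trials grow", {
  for (k in c(2, 4, 6)) {
    ns <- c(20, 50, 100, 200, 500, 1000)
    th <- vapply(ns, function(n) {
      binomial_threshold(n, k)$threshold_exact
    }, numeric(1))
    expect_true(all(diff(th) < 0))
    excess <- th - 100 / k
    expect_true(all(diff(excess) < 0))
    expect_true(all(th > 100 / k))
  }
})

test_that("paired comparisons match hand-computed t and Cohen's d", {
  res <- compare_conditions(c(2, 4, 6), c(1, 2, 3))  # x - y = 1, 2, 3
  expect_equal(res$cohens_d, 2)
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_false(res$degenerate)
  # degenerate cases are flagged, not silently propagated
  same <- compare_conditions(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_equal(same$p, 1)
  expect_equal(same$cohens_d, 0)
  shifted <- compare_conditions(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_true(shifted$degenerate)  # sd of difference is zero
  expect_true(is.na(shifted$cohens_d))
  expect_error(compare_conditions(1:3, 1:4), "equal length")
})

test_that("correlations match hand-computed values and flag constants", {
  expect_equal(correlate(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(correlate(1:5, -(1:5))$r, -1)
  expect_equal(correlate(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  expect_true(correlate(rep(1, 5), 1:5)$degenerate)
  sp <- correlate(1:6, (1:6)^3, method = "spearman")
  expect_equal(sp$r, 1)
  expect_error(correlate(1:2, 1:2), ">= 3")
})

test_that("permutation nulls bound the empirical p away from zero and center on chance", {
  ep <- cached("perm_epochs", {
    cfg <- reduced_protocol(n_channels = 8, trials = 8, tasks = c("L", "R"))
    make_epochs(effect = 1.3, seed = 21, cfg = cfg)
  })
  cv <- cv_config(n_folds = 4, n_repeats = 1, n_pairs = 3, seed = 3)
  pr <- permutation_null(ep, c("L", "R"), cv, n_perm = 19, seed = 5)
  expect_gte(pr$p_empirical, 1 / 20)
  expect_lte(pr$p_empirical, 1)
  # observed above every permuted value -> p exactly 1/(n_perm + 1)
  if (all(pr$null < pr$observed_pct)) {
    expect_equal(pr$p_empirical, 1 / 20)
  }
  # null distribution centered near theoretical chance
  expect_lt(abs(mean(pr$null) - 50), 12)
  expect_identical(
    permutation_null(ep, c("L", "R"), cv, n_perm = 5, seed = 5)$null,
    pr$null[1:5])
  small <- permutation_null(ep, c("L", "R"), cv, n_perm = 3, seed = 5)
  expect_match(small$warning, "cannot resolve")
})

test_that("discard arms always remove identical per-class counts", {
  ep <- cached("discard_epochs", {
    cfg <- protocol_config(task_names = c("L", "R", "F"),
                           trials_per_task_per_block = 8, n_blocks = 1,
                           fs = 250, n_channels = 8)
    sim <- sim_config(effect_size = 1.3, seed = 22,
                      self_eval_mode = "informative",
                      self_eval_probs = c(correct = 0.6, not_correct = 0.25,
                                          correct_not_well = 0.15))
    make_epochs(cfg = cfg, seed = 22, sim = sim)
  })
  cv <- cv_config(n_folds = 4, n_repeats = 1, n_filters = 6, seed = 1)
  d <- discard_analysis(ep, c("L", "R", "F"), mode = "flagged_only",
                        cv = cv, seed = 2)
  expect_equal(d$n_removed, sum(ep$self_eval == "not_correct"))
  expect_equal(d$result_discarded$n_trials, d$result_random$n_trials)
  d2 <- discard_analysis(ep, c("L", "R", "F"), mode = "flagged_plus_weak",
                         cv = cv, seed = 2)
  expect_equal(d2$n_removed, sum(ep$self_eval != "correct"))
})

test_that("with no flagged trials both discard arms equal the baseline", {
  cfg <- protocol_config(task_names = c("L", "R"),
                         trials_per_task_per_block = 8, n_blocks = 1,
                         fs = 250, n_channels = 8)
  sim <- sim_config(effect_size = 1.0, seed = 23,
                    self_eval_probs = c(correct = 1, not_correct = 0,
                                        correct_not_well = 0))
  ep <- make_epochs(cfg = cfg, seed = 23, sim = sim)
  cv <- cv_config(n_folds = 4, n_repeats = 1, n_pairs = 3, seed = 4)
  d <- discard_analysis(ep, c("L", "R"), mode = "flagged_plus_weak",
                        cv = cv, seed = 5)
  base <- crossvalidate_scenario(ep, c("L", "R"), cv)
  expect_equal(d$n_removed, 0)
  expect_equal(d$accuracy_discarded, base$mean)
  expect_equal(d$accuracy_random_matched, base$mean)
})
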