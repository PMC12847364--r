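test_that("scenario enumeration matches the combinatorial table layouts", {
  expect_length(enumerate_scenarios(k = 2), 21)   # C(7,2) pairs
  expect_length(enumerate_scenarios(k = 4), 25)   # C(7,4) minus both-SI
  expect_length(enumerate_scenarios(k = 5), 11)
  expect_length(enumerate_scenarios(k = 6), 2)
  expect_error(enumerate_scenarios(k = 3), "one of 2, 4, 5, 6")
  # the SI pair is allowed in the binary analysis only
  has_both <- function(s) all(c("SIkin", "SInoKin") %in% s$tasks)
  expect_equal(sum(vapply(enumerate_scenarios(k = 2), has_both, logical(1))), 1)
  for (k in c(4, 5, 6)) {
    expect_false(any(vapply(enumerate_scenarios(k = k), has_both,
                            logical(1))))
  }
  # the two 6-class scenarios are conventional tasks + one SI variant each
  six <- enumerate_scenarios(k = 6)
  expect_true(all(vapply(six, function(s) {
    all(c("L", "R", "F", "T", "REST") %in% s$tasks)
  }, logical(1))))
})

test_that("the forest separates separable toy data and validates labels", {
  set.seed(11)
  X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 4), 20))
  y <- rep(c("a", "b"), each = 20)
  fit <- train_classifier(X, y, cv_config(), seed = 1)
  expect_equal(fit$num.trees, 100)
  pred <- imagerybci:::.predict_classifier(fit, X)
  expect_equal(as.character(pred), y)
  expect_error(train_classifier(X, rep("a", 40), cv_config()), ">= 2 classes")
})

test_that("balanced accuracy equals plain accuracy on balanced data", {
  set.seed(12)
  truth <- factor(rep(c("a", "b", "c"), each = 10))
  pred <- factor(sample(c("a", "b", "c"), 30, replace = TRUE),
                 levels = levels(truth))
  expect_equal(balanced_accuracy(truth, pred), mean(truth == pred))
  # and weights recalls equally on imbalanced data
  truth2 <- factor(c(rep("a", 8), rep("b", 2)))
  pred2 <- factor(rep("a", 10), levels = c("a", "b"))
  expect_equal(balanced_accuracy(truth2, pred2), 0.5)
})

test_that("cross-validation is reproducible, balanced, and accounts every trial", {
  ep <- strong_epochs()
  cv <- cv_config(n_folds = 5, n_repeats = 2, seed = 31)
  r1 <- crossvalidate_scenario(ep, c("L", "R"), cv)
  r2 <- crossvalidate_scenario(ep, c("L", "R"), cv)
  expect_identical(r1$fold_acc, r2$fold_acc)
  expect_identical(r1$confusion, r2$confusion)
  expect_equal(dim(r1$fold_acc), c(2, 5))
  # confusion rows sum to per-class trial counts x repeats
  expect_equal(unname(rowSums(r1$confusion)), c(20, 20))
  expect_equal(sum(r1$confusion), r1$n_trials * cv$n_repeats)
  r3 <- crossvalidate_scenario(ep, c("L", "R"),
                               cv_config(n_folds = 5, n_repeats = 2,
                                         seed = 32))
  expect_false(identical(r1$fold_acc, r3$fold_acc))
  expect_error(crossvalidate_scenario(ep, c("L", "XX"), cv), "lack")
})

test_that("five repeats of 10-fold cross-validation yield 50 fold accuracies", {
  ep <- strong_epochs()
  cv <- cv_config(n_folds = 10, n_repeats = 5, seed = 13)
  res <- crossvalidate_scenario(ep, c("L", "REST"), cv)
  expect_equal(dim(res$fold_acc), c(5, 10))
  expect_equal(sum(!is.na(res$fold_acc)), 50)
  expect_true(res$mean >= 0 && res$mean <= 100)
  # a strongly modulated pair decodes far above chance
  expect_gt(res$mean, binomial_threshold(20, 2)$threshold_exact)
})

test_that("fitting the feature pipeline on all data before splitting inflates null accuracy", {
  # leakage guard: the shipped fold-wise pipeline stays near chance on
  # effect-free data while the deliberately leaky variant does not
  cfg <- reduced_protocol(n_channels = 16, trials = 10, tasks = c("L", "R"))
  safe <- c(); leak <- c()
  for (s in 1:2) {
    ep <- make_epochs(effect = 0, seed = 100 + s, cfg = cfg)
    safe <- c(safe, crossvalidate_scenario(
      ep, c("L", "R"), cv_config(n_repeats = 2, seed = s))$mean)
    leak <- c(leak, crossvalidate_scenario(
      ep, c("L", "R"), cv_config(n_repeats = 2, leak_demo = TRUE,
                                 seed = s))$mean)
  }
  band <- chance_band(20 * 2, 2)
  expect_gt(mean(leak), band[2])           # leaky variant: grossly inflated
  expect_gt(mean(leak) - mean(safe), 20)   # and far above the safe pipeline
})
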