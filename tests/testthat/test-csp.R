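test_that("binary CSP solves the diagonal-covariance case in closed form", {
  # S1 = diag(4, 1), S2 = diag(1, 4): trace-normalized class covariances
  # give generalized eigenvalues {0.8, 0.2} with axis-aligned filters
  bc <- exact_band_covs(list(diag(c(4, 1)), diag(c(1, 4))))
  model <- fit_csp_binary(bc, n_pairs = 1)
  expect_equal(model$scores[[1]], c(0.8, 0.2))
  W <- model$W[[1]]
  # filters along coordinate axes up to sign/scale
  expect_lt(abs(W[1, 2] / W[1, 1]), 1e-8)
  expect_lt(abs(W[2, 1] / W[2, 2]), 1e-8)
})

test_that("identical class covariances give eigenvalues of one half", {
  S <- crossprod(matrix(rnorm(16), 4))
  bc <- exact_band_covs(list(S, S))
  model <- fit_csp_binary(bc, n_pairs = 2)
  expect_equal(model$scores[[1]], rep(0.5, 4), tolerance = 1e-10)
})

test_that("binary CSP keeps 5 pairs per band on rich data and whitens the composite", {
  ep <- strong_epochs()
  bc <- cached("strong_bc", {
    bank <- design_filterbank(filterbank_spec(), fs = ep$fs)
    imagerybci:::band_covariances(apply_filterbank(ep, bank))
  })
  keep <- which(bc$labels %in% c("L", "R"))
  bclr <- imagerybci:::bc_subset(bc, keep)
  model <- fit_csp_binary(bclr, n_pairs = 5)
  expect_length(model$W, 9)
  for (b in seq_along(model$W)) {
    expect_equal(nrow(model$W[[b]]), 10)
    # W (S1 + S2) W' = I on the selected filters
    S1 <- imagerybci:::.class_cov(bclr$covs, which(bclr$labels == "L"), b)
    S2 <- imagerybci:::.class_cov(bclr$covs, which(bclr$labels == "R"), b)
    G <- model$W[[b]] %*% (S1 + S2) %*% t(model$W[[b]])
    expect_lt(max(abs(G - diag(10))), 1e-6)
    # eigenvalue ordering maintained
    expect_true(all(diff(model$scores[[b]]) <= 1e-12))
  }
})

test_that("CSP filter directions are invariant to global amplitude scaling", {
  set.seed(4)
  bc <- gaussian_band_covs(list(crossprod(matrix(rnorm(16), 4)) + diag(4),
                                crossprod(matrix(rnorm(16), 4)) + diag(4)),
                           n_trials = 12)
  m1 <- fit_csp_binary(bc, n_pairs = 2)
  bc2 <- bc
  bc2$covs <- bc$covs * 25  # all epochs scaled by 5
  m2 <- fit_csp_binary(bc2, n_pairs = 2)
  for (j in 1:4) {
    cs <- abs(sum(m1$W[[1]][j, ] * m2$W[[1]][j, ])) /
      sqrt(sum(m1$W[[1]][j, ]^2) * sum(m2$W[[1]][j, ]^2))
    expect_gt(cs, 0.9999)
  }
})

test_that("binary CSP matches a brute-force Rayleigh-quotient oracle on 4 channels", {
  set.seed(5)
  A <- matrix(rnorm(16), 4)
  S1 <- crossprod(A) + diag(c(5, 1, 1, 1))
  S2 <- crossprod(A) + diag(c(1, 1, 1, 4))
  bc <- gaussian_band_covs(list(S1, S2), n_trials = 40, n_samp = 2000)
  model <- fit_csp_binary(bc, n_pairs = 1)
  # oracle: directly maximize w'C1w / w'(C1+C2)w over directions, from the
  # same class-mean covariances the fit saw, via multi-start optimization
  C1 <- imagerybci:::.class_cov(bc$covs, which(bc$labels == "c1"), 1)
  C2 <- imagerybci:::.class_cov(bc$covs, which(bc$labels == "c2"), 1)
  rayleigh <- function(w) -(w %*% C1 %*% w) / (w %*% (C1 + C2) %*% w)
  best <- NULL
  for (i in 1:30) {
    o <- optim(rnorm(4), rayleigh, method = "BFGS")
    if (is.null(best) || o$value < best$value) best <- o
  }
  w_oracle <- best$par / sqrt(sum(best$par^2))
  w_fit <- model$W[[1]][1, ] / sqrt(sum(model$W[[1]][1, ]^2))
  angle <- acos(pmin(1, abs(sum(w_oracle * w_fit)))) * 180 / pi
  expect_lt(angle, 2)
})

test_that("multiclass CSP on two classes spans the binary CSP subspace", {
  set.seed(6)
  S1 <- crossprod(matrix(rnorm(16), 4)) + diag(c(6, 1, 1, 1))
  S2 <- crossprod(matrix(rnorm(16), 4)) + diag(c(1, 1, 1, 6))
  bc <- gaussian_band_covs(list(S1, S2), n_trials = 30, n_samp = 1000)
  mb <- fit_csp_binary(bc, n_pairs = 2)
  mm <- fit_csp_multiclass(bc, n_filters = 4)
  # principal angles between the two 4-filter row spaces
  qa <- qr.Q(qr(t(mb$W[[1]])))
  qb <- qr.Q(qr(t(mm$W[[1]])))
  angles <- acos(pmin(1, svd(crossprod(qa, qb))$d)) * 180 / pi
  expect_lt(max(angles), 5)
})

test_that("equal class covariances give near-zero information scores and index tie-break", {
  S <- crossprod(matrix(rnorm(25), 5)) + diag(5)
  bc <- exact_band_covs(list(S, S, S), n_trials = 3)
  model <- fit_csp_multiclass(bc, n_filters = 5)
  expect_lt(max(abs(unlist(model$scores))), 1e-8)
  expect_length(model$scores[[1]], 5)
})

test_that("commuting class covariances are jointly diagonalized to machine precision", {
  set.seed(7)
  V <- qr.Q(qr(matrix(rnorm(36), 6)))  # shared eigenbasis
  S_list <- lapply(1:3, function(i) V %*% diag(runif(6, 0.5, 3)) %*% t(V))
  bc <- exact_band_covs(S_list, n_trials = 3)
  model <- fit_csp_multiclass(bc, n_filters = 6)
  W <- model$W[[1]]
  offd <- 0
  for (S in S_list) {
    Sn <- S / sum(diag(S))
    D <- W %*% Sn %*% t(W)
    offd <- offd + sum(D^2) - sum(diag(D)^2)
  }
  expect_lt(offd, 1e-8)
})

test_that("log-variance features have 90 columns by default and obey the scaling law", {
  bc <- cached("strong_bc", {
    ep <- strong_epochs()
    bank <- design_filterbank(filterbank_spec(), fs = ep$fs)
    imagerybci:::band_covariances(apply_filterbank(ep, bank))
  })
  model <- fit_csp_multiclass(bc, n_filters = 10)
  feats <- extract_logvar_features(bc, model)
  expect_equal(ncol(feats$X), 90)
  expect_true(all(is.finite(feats$X)))
  expect_equal(feats$band, rep(1:9, each = 10))
  # doubling one trial's amplitude shifts its features by log(4)
  bc2 <- bc
  bc2$covs[, , 1, ] <- bc$covs[, , 1, ] * 4
  feats2 <- extract_logvar_features(bc2, model)
  expect_equal(feats2$X[1, ] - feats$X[1, ],
               rep(log(4), 90), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(feats2$X[2, ], feats$X[2, ], ignore_attr = TRUE)
})

test_that("class-separated features emerge at strong effect size", {
  bc <- cached("strong_bc", {
    ep <- strong_epochs()
    bank <- design_filterbank(filterbank_spec(), fs = ep$fs)
    imagerybci:::band_covariances(apply_filterbank(ep, bank))
  })
  keep <- which(bc$labels %in% c("L", "REST"))
  bck <- imagerybci:::bc_subset(bc, keep)
  model <- fit_csp_binary(bck, n_pairs = 5)
  feats <- extract_logvar_features(bck, model)
  # best single feature separates the classes visibly
  sep <- apply(feats$X, 2, function(x) {
    abs(mean(x[feats$labels == "L"]) - mean(x[feats$labels == "REST"])) /
      stats::sd(x)
  })
  expect_gt(max(sep), 1)
})

test_that("degenerate inputs are rejected with actionable errors", {
  bc <- exact_band_covs(list(diag(2), diag(2)))
  expect_error(fit_csp_binary(bc, n_pairs = 5), "n_pairs")
  one_trial <- imagerybci:::bc_subset(bc, c(1, 5))
  expect_error(fit_csp_binary(one_trial, n_pairs = 1), ">= 2 trials")
  lab3 <- factor(rep(c("a", "b", "c"), length.out = 8))
  expect_error(fit_csp_binary(bc, labels = lab3), "exactly 2")
})
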