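# Common spatial patterns: binary (generalized eigenproblem) and multiclass
# (approximate joint diagonalization with information-based filter ranking),
# plus log-variance feature extraction.

.as_band_covs <- function(x) {
  if (inherits(x, "band_covs")) return(x)
  if (inherits(x, "band_epochs")) return(band_covariances(x))
  stopf("expected band_epochs or band_covs, got %s", class(x)[1])
}

# Trace-normalized class-mean covariance for trial subset `idx` in band `b`.
.class_cov <- function(covs, idx, b, loading = 0) {
  n_ch <- dim(covs)[1]
  A <- matrix(covs[, , idx, b], n_ch * n_ch, length(idx))
  traces <- colSums(A[seq(1, n_ch * n_ch, by = n_ch + 1), , drop = FALSE])
  C <- matrix(A %*% (1 / traces), n_ch) / length(idx)
  if (loading > 0) C <- C + loading * (sum(diag(C)) / n_ch) * diag(n_ch)
  C
}

# Rank-aware whitening transform: rows of the returned matrix P (r x n)
# whiten C on its principal subspace (P C P' = I_r). Directions with
# eigenvalues below max * tol are dropped — average-referenced EEG is
# exactly rank n_channels - 1, and the null direction carries no signal.
.whitener <- function(C, tol = 1e-9) {
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > max(e$values) * tol
  P <- t(e$vectors[, keep, drop = FALSE]) / sqrt(e$values[keep])
  P
}

#' Fit binary common spatial patterns
#'
#' Per band: per-trial covariances are trace-normalized and averaged per
#' class into `S1`, `S2`; the generalized eigenproblem
#' `S1 w = lambda (S1 + S2) w` is solved by whitening with `S1 + S2`;
#' eigenvalues are sorted descending and `n_pairs` filters are kept from
#' each end of the spectrum. Filters are scaled so that
#' `w' (S1 + S2) w = 1`.
#'
#' @param x A `band_epochs` or `band_covs` object.
#' @param labels Optional factor overriding the labels carried in `x`; must
#'   contain exactly two classes.
#' @param n_pairs Filter pairs retained per band (default 5, i.e. 10
#'   filters).
#' @param loading Diagonal-loading fraction added to class covariances
#'   (`epsilon * trace/n_channels * I`); 0 disables.
#' @return An object of class `csp_model` with per-band filter matrices
#'   (`n_filters x n_channels`) and eigenvalue scores.
#' @export
fit_csp_binary <- function(x, labels = NULL, n_pairs = 5, loading = 0) {
  bc <- .as_band_covs(x)
  labels <- droplevels(factor(labels %||% bc$labels))
  if (nlevels(labels) != 2) {
    stopf("binary CSP needs exactly 2 classes, got %d", nlevels(labels))
  }
  counts <- table(labels)
  if (any(counts < 2)) stopf("each class needs >= 2 trials")
  covs <- bc$covs
  n_ch <- dim(covs)[1]
  if (2 * n_pairs > n_ch) {
    stopf("n_pairs=%d needs at least %d channels, have %d", n_pairs,
          2 * n_pairs, n_ch)
  }
  idx1 <- which(labels == levels(labels)[1])
  idx2 <- which(labels == levels(labels)[2])
  W <- list(); scores <- list()
  for (b in seq_along(bc$bands)) {
    S1 <- .class_cov(covs, idx1, b, loading)
    S2 <- .class_cov(covs, idx2, b, loading)
    P <- .whitener(S1 + S2)
    r <- nrow(P)
    if (2 * n_pairs > r) {
      stopf(paste0("composite covariance in band %d has rank %d < %d ",
                   "filters; enable diagonal loading (`loading > 0`) or ",
                   "reduce n_pairs"), b, r, 2 * n_pairs)
    }
    e <- eigen(P %*% S1 %*% t(P), symmetric = TRUE)  # eigenvalues in (0, 1)
    sel <- c(seq_len(n_pairs), seq(r - n_pairs + 1, r))  # both spectrum ends
    Wb <- t(e$vectors[, sel, drop = FALSE]) %*% P  # rows: filters
    W[[b]] <- Wb
    scores[[b]] <- e$values[sel]
  }
  structure(list(W = W, scores = scores, bands = bc$bands,
                 classes = levels(labels), type = "binary",
                 n_filters = 2 * n_pairs,
                 channel_names = bc$channel_names),
            class = "csp_model")
}

# Approximate joint diagonalization of a set of symmetric positive-definite
# matrices by Pham's (2001) iterative pairwise algorithm, the standard AJD
# for covariance sets. `Cs` is an array [n, n, K]; returns the (generally
# non-orthogonal) diagonalizer `B` with `B C_k B'` near-diagonal for all k,
# the transformed matrices, and the iteration count. Errors at the sweep
# cap with the residual off-diagonal energy.
.ajd_pham <- function(Cs, tol = 1e-6, max_sweeps = 100) {
  n <- dim(Cs)[1]; K <- dim(Cs)[3]
  # work on the horizontal concatenation [C1 C2 ... CK] so each pairwise
  # transform is a handful of vectorized row/column combinations
  M <- matrix(Cs, n, n * K)
  B <- diag(n)
  epsilon <- n * (n - 1) * tol
  offs <- (seq_len(K) - 1) * n
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    decr <- 0
    for (i in seq(2, n)) {
      for (j in seq_len(i - 1)) {
        ci <- offs + i; cj <- offs + j
        c1 <- M[i, ci]; c2 <- M[j, cj]
        cij <- M[i, cj]
        g12 <- sum(cij / c1) / K
        g21 <- sum(cij / c2) / K
        omega21 <- sum(c1 / c2) / K
        omega12 <- sum(c2 / c1) / K
        omega <- sqrt(omega12 * omega21)
        tmp <- sqrt(omega21 / omega12)
        tmp1 <- (tmp * g12 + g21) / (omega + 1)
        tmp2 <- (tmp * g12 - g21) / max(omega - 1, 1e-9)
        h12 <- tmp1 + tmp2
        h21 <- (tmp1 - tmp2) / tmp
        decr <- decr + K * (g12 * h12 + g21 * h21) / 2
        denom <- Re(1 + sqrt(as.complex(1 - h12 * h21)))
        a12 <- -h12 / denom  # tau = [[1, a12], [a21, 1]]
        a21 <- -h21 / denom
        # rows i, j of every matrix
        ri <- M[i, ]; rj <- M[j, ]
        M[i, ] <- ri + a12 * rj
        M[j, ] <- a21 * ri + rj
        # columns i, j of every matrix
        qi <- M[, ci]; qj <- M[, cj]
        M[, ci] <- qi + a12 * qj
        M[, cj] <- a21 * qi + qj
        bi <- B[i, ]; bj <- B[j, ]
        B[i, ] <- bi + a12 * bj
        B[j, ] <- a21 * bi + bj
      }
    }
    if (decr < epsilon) {
      converged <- TRUE
      break
    }
  }
  Cs <- array(M, c(n, n, K))
  if (!converged) {
    stopf(paste0("joint diagonalization did not converge in %d sweeps ",
                 "(off-diagonal energy %.3g)"),
          max_sweeps, .offdiag_energy(Cs))
  }
  list(B = B, Cs = Cs, sweeps = sweep)
}

.offdiag_energy <- function(Cs) {
  total <- 0
  for (k in seq_len(dim(Cs)[3])) {
    C <- Cs[, , k]
    total <- total + sum(C^2) - sum(diag(C)^2)
  }
  total
}

#' Fit multiclass common spatial patterns by joint diagonalization
#'
#' Per band: class-mean covariances (trace-normalized) are whitened by the
#' grand-average covariance, then approximately jointly diagonalized by
#' Pham's iterative pairwise algorithm for positive-definite matrix sets.
#' The resulting spatial filters are ranked by an information score
#' computed from the per-class projected variances under a Gaussian
#' assumption: for filter `w` with per-class variances `v_c` and class
#' priors `p_c`,
#' `score = -( sum_c p_c log sqrt(v_c) + 3/16 (sum_c p_c (v_c^2 - 1))^2 )`.
#' The top `n_filters` are kept; ties break toward the lower filter index.
#'
#' @param x A `band_epochs` or `band_covs` object.
#' @param labels Optional factor overriding the labels carried in `x`.
#' @param n_filters Filters retained per band (default 10, matching the
#'   binary configuration so downstream feature dimensionality is the same
#'   in every scenario).
#' @param loading Diagonal-loading fraction (see [fit_csp_binary()]).
#' @param max_sweeps Sweep cap for the joint diagonalization;
#'   non-convergence raises an error reporting the final off-diagonal
#'   energy.
#' @param tol Per-element convergence tolerance on the criterion decrement.
#' @return A `csp_model` (type `"multiclass"`).
#' @export
fit_csp_multiclass <- function(x, labels = NULL, n_filters = 10,
                               loading = 0, max_sweeps = 100, tol = 1e-6) {
  bc <- .as_band_covs(x)
  labels <- droplevels(factor(labels %||% bc$labels))
  k <- nlevels(labels)
  if (k < 2) stopf("multiclass CSP needs >= 2 classes")
  counts <- table(labels)
  if (any(counts < 2)) stopf("each class needs >= 2 trials")
  covs <- bc$covs
  n_ch <- dim(covs)[1]
  n_filters <- min(n_filters, n_ch)
  priors <- as.numeric(counts) / length(labels)
  W <- list(); scores <- list()
  for (b in seq_along(bc$bands)) {
    Sc <- array(NA_real_, c(n_ch, n_ch, k))
    for (ci in seq_len(k)) {
      Sc[, , ci] <- .class_cov(covs, which(labels == levels(labels)[ci]), b,
                               loading)
    }
    Sbar <- matrix(0, n_ch, n_ch)
    for (ci in seq_len(k)) Sbar <- Sbar + priors[ci] * Sc[, , ci]
    P <- .whitener(Sbar)
    r <- nrow(P)
    nf_b <- min(n_filters, r)
    Cw <- array(NA_real_, c(r, r, k))
    for (ci in seq_len(k)) Cw[, , ci] <- P %*% Sc[, , ci] %*% t(P)
    ajd <- .ajd_pham(Cw, tol = tol, max_sweeps = max_sweeps)
    Wb_full <- ajd$B %*% P  # rows are candidate filters
    # rescale each filter to unit grand-average variance, so the projected
    # per-class variances v_c satisfy sum_c p_c v_c = 1
    vbar <- rowSums((Wb_full %*% Sbar) * Wb_full)
    Wb_full <- Wb_full / sqrt(vbar)
    V <- sapply(seq_len(k), function(ci) {
      rowSums((Wb_full %*% Sc[, , ci]) * Wb_full)
    })  # r x k projected class variances
    info <- vapply(seq_len(r), function(j) {
      v <- V[j, ]
      -(sum(priors * log(sqrt(v))) + (3 / 16) * sum(priors * (v^2 - 1))^2)
    }, numeric(1))
    ord <- order(-info, seq_len(r))[seq_len(nf_b)]
    W[[b]] <- Wb_full[ord, , drop = FALSE]
    scores[[b]] <- info[ord]
  }
  structure(list(W = W, scores = scores, bands = bc$bands,
                 classes = levels(labels), type = "multiclass",
                 n_filters = nrow(W[[1]]),
                 channel_names = bc$channel_names),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %s, %d bands x %d filters, classes: %s\n",
              x$type, length(x$W), x$n_filters,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Extract log-variance features
#'
#' For every trial, band `b` and spatial filter `j`, the feature is
#' `log(var(w_bj' x))` — computed as the quadratic form of the filter with
#' the trial's band covariance. With the default 9 bands x 10 filters this
#' yields 90 columns.
#'
#' @param x A `band_epochs` or `band_covs` object.
#' @param model A `csp_model` fitted on data with matching bands/channels.
#' @return An object of class `trial_feature_table`: `X` (trials x features
#'   matrix), `band`/`filter` column provenance, `labels`,
#'   `participant_id`.
#' @export
extract_logvar_features <- function(x, model) {
  bc <- .as_band_covs(x)
  stopifnot(inherits(model, "csp_model"))
  if (length(model$bands) != length(bc$bands)) {
    stopf("model has %d bands but data has %d", length(model$bands),
          length(bc$bands))
  }
  covs <- bc$covs
  n_tr <- dim(covs)[3]
  n_bands <- length(bc$bands)
  n_f <- nrow(model$W[[1]])
  X <- matrix(NA_real_, n_tr, n_bands * n_f)
  band_ix <- rep(seq_len(n_bands), each = n_f)
  filt_ix <- rep(seq_len(n_f), n_bands)
  for (b in seq_len(n_bands)) {
    Wb <- model$W[[b]]
    cols <- (b - 1) * n_f + seq_len(n_f)
    for (i in seq_len(n_tr)) {
      v <- rowSums((Wb %*% covs[, , i, b]) * Wb)  # diag(W C W')
      if (any(v <= 0)) {
        stopf(
          "zero-variance projection in trial %d, band %d; enable diagonal loading",
          i, b)
      }
      X[i, cols] <- log(v)
    }
  }
  colnames(X) <- sprintf("b%d_f%d", band_ix, filt_ix)
  structure(list(X = X, band = band_ix, filter = filt_ix,
                 labels = bc$labels, participant_id = bc$participant_id),
            class = "trial_feature_table")
}

#' @export
print.trial_feature_table <- function(x, ...) {
  cat(sprintf("<trial_feature_table> %d trials x %d features\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Write a feature table to TSV
#'
#' @param features A `trial_feature_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_features_tsv <- function(features, path) {
  df <- data.frame(trial = seq_len(nrow(features$X)),
                   label = as.character(features$labels), features$X,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
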