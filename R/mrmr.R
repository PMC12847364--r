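# Minimum-redundancy maximum-relevance feature selection (MID criterion)
# over equal-frequency discretized features.

#' Equal-frequency discretization of a feature matrix
#'
#' Per column: bin edges are order statistics of the (training) data at the
#' `1/n_bins, ..., (n_bins-1)/n_bins` quantile positions, so distinct
#' values split into bins of equal size (+-1). The edges are returned so
#' the identical binning can be applied to held-out data with
#' [apply_discretization()]. The binning depends only on value ranks, so
#' any strictly monotone transform of a column leaves it unchanged.
#' Constant columns collapse to a single bin and are flagged.
#'
#' @param X Numeric matrix (trials x features).
#' @param n_bins Number of bins, `>= 2`.
#' @return List with `codes` (integer matrix, values in `1..n_bins`),
#'   `edges` (list of per-column edge vectors) and `constant` (logical
#'   vector flagging single-bin columns).
#' @export
discretize_features <- function(X, n_bins = 5) {
  X <- as.matrix(X)
  if (!is_count(n_bins) || n_bins < 2) stopf("n_bins must be >= 2")
  n <- nrow(X)
  edges <- vector("list", ncol(X))
  constant <- logical(ncol(X))
  codes <- matrix(1L, n, ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    srt <- sort(x)
    e <- unique(srt[ceiling(n * seq_len(n_bins - 1) / n_bins)])
    e <- e[e < srt[n]]  # an edge equal to the max would create an empty top bin
    edges[[j]] <- e
    constant[j] <- length(e) == 0
    codes[, j] <- findInterval(x, e, left.open = TRUE) + 1L
  }
  list(codes = codes, edges = edges, constant = constant, n_bins = n_bins)
}

#' Apply previously computed discretization edges
#'
#' @param disc A [discretize_features()] result (fitted on training data).
#' @param X New data with the same columns.
#' @return Integer code matrix.
#' @export
apply_discretization <- function(disc, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(disc$edges)) {
    stopf("X has %d columns but discretization was fitted on %d", ncol(X),
          length(disc$edges))
  }
  codes <- matrix(1L, nrow(X), ncol(X))
  for (j in seq_len(ncol(X))) {
    codes[, j] <- findInterval(X[, j], disc$edges[[j]], left.open = TRUE) + 1L
  }
  codes
}

#' Plug-in mutual information between two discrete vectors
#'
#' Maximum-likelihood (contingency-table) estimate in nats.
#'
#' @param a,b Integer or factor vectors of equal length.
#' @return Mutual information in nats.
#' @export
mutual_information <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  .mi_codes(a, max(a), b, max(b))
}

# Fast path: a, b already 1-based integer codes with known alphabet sizes.
.mi_codes <- function(a, na, b, nb) {
  n <- length(a)
  joint <- tabulate(a + na * (b - 1L), nbins = na * nb) / n
  pa <- tabulate(a, nbins = na) / n
  pb <- tabulate(b, nbins = nb) / n
  pp <- as.vector(pa %o% pb)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / pp[nz]))
}

#' Greedy mRMR feature selection (mutual-information difference)
#'
#' The first pick maximizes relevance `I(f; y)`; each subsequent pick
#' maximizes `I(f; y) - mean_{s in selected} I(f; s)`. Mutual information
#' uses the plug-in contingency-table estimator on the discretized inputs.
#' Ties break deterministically toward the lower column index.
#'
#' @param Xd Integer code matrix (trials x features), e.g. from
#'   [discretize_features()].
#' @param y Class labels.
#' @param k Number of features to select, `<= ncol(Xd)`.
#' @return Integer vector of `k` selected column indices, in pick order.
#' @export
mrmr_select <- function(Xd, y, k) {
  Xd <- as.matrix(Xd)
  if (nrow(Xd) == 0 || ncol(Xd) == 0) stopf("empty feature matrix")
  if (k > ncol(Xd)) stopf("k=%d exceeds the %d available features", k,
                          ncol(Xd))
  y <- as.integer(factor(y))
  ny <- max(y)
  p <- ncol(Xd)
  storage.mode(Xd) <- "integer"
  nlev <- pmax(apply(Xd, 2, max), 1L)
  relevance <- vapply(seq_len(p), function(j) {
    .mi_codes(Xd[, j], nlev[j], y, ny)
  }, numeric(1))
  selected <- integer(0)
  red_sum <- numeric(p)  # sum over selected of I(f; s)
  candidates <- rep(TRUE, p)
  for (step in seq_len(k)) {
    crit <- if (step == 1) {
      relevance
    } else {
      relevance - red_sum / length(selected)
    }
    crit[!candidates] <- -Inf
    pick <- which.max(crit)  # which.max returns the first (lowest) index on ties
    selected <- c(selected, pick)
    candidates[pick] <- FALSE
    if (step < k) {
      for (j in which(candidates)) {
        red_sum[j] <- red_sum[j] + .mi_codes(Xd[, j], nlev[j], Xd[, pick],
                                             nlev[pick])
      }
    }
  }
  selected
}
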