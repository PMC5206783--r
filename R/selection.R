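# Feature selection with fold aggregation.  Each selector is run once per
# cross-validation training fold; the final subset keeps the features chosen
# in at least `min_occurrence` of the folds (CFS, SVR-weight) or whose mean
# rank across folds is within the top `top_k` positions (RReliefF, which
# ranks all features rather than choosing a subset).

#' Deterministic cross-validation folds
#'
#' Seeded shuffle followed by contiguous blocks.
#'
#' @param n number of rows.
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of `k` integer vectors (test indices).
#' @export
make_folds <- function(n, k = 10L, seed = 1L) {
  if (n < k) abort_input("fewer rows than folds", "redeye_bad_protocol")
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  split(perm, rep(seq_len(k), sizes))
}

selection_result <- function(method, per_fold, final_subset, extra = list()) {
  structure(c(list(method = method, per_fold = per_fold,
                   final_subset = final_subset), extra),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result %s> %d folds; final subset (%d): %s\n",
              x$method, length(x$per_fold), length(x$final_subset),
              paste(x$final_subset, collapse = ", ")))
  invisible(x)
}

# Hall's CFS merit of a subset: k * mean|r_cf| / sqrt(k + k (k-1) mean|r_ff|).
cfs_merit <- function(subset, r_cf, r_ff) {
  k <- length(subset)
  if (k == 0L) return(0)
  rcf <- mean(r_cf[subset])
  if (k == 1L) return(rcf)
  rff <- mean(r_ff[subset, subset][upper.tri(matrix(0, k, k))])
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

# Best-first forward search over feature subsets, stopping after `stale`
# consecutive non-improving expansions (Weka-style).
cfs_search <- function(X, y, stale = 5L) {
  p <- ncol(X)
  r_cf <- abs(suppressWarnings(stats::cor(X, y)))[, 1]
  r_cf[is.na(r_cf)] <- 0
  r_ff <- abs(suppressWarnings(stats::cor(X)))
  r_ff[is.na(r_ff)] <- 0
  best <- integer(0)
  best_merit <- 0
  current <- integer(0)
  n_stale <- 0L
  repeat {
    cand <- setdiff(seq_len(p), current)
    if (!length(cand)) break
    merits <- vapply(cand, function(f) cfs_merit(c(current, f), r_cf, r_ff),
                     numeric(1))
    j <- which.max(merits)
    current <- c(current, cand[j])
    if (merits[j] > best_merit + 1e-12) {
      best_merit <- merits[j]
      best <- current
      n_stale <- 0L
    } else {
      n_stale <- n_stale + 1L
      if (n_stale >= stale) break
    }
  }
  colnames(X)[best]
}

#' Correlation-based feature selection (CFS) with fold aggregation
#'
#' Per training fold, a best-first forward search maximises Hall's merit
#' `k r_cf / sqrt(k + k (k-1) r_ff)` (mean absolute Pearson correlations of
#' subset features with the target and among themselves); the final subset
#' keeps features selected in at least `min_occurrence` folds.
#'
#' @param X data frame or matrix of (normalised) feature columns.
#' @param y numeric target (continuous grade).
#' @param folds number of folds (default 10).
#' @param min_occurrence minimum fold count for the final subset (default 7).
#' @param seed fold seed.
#' @return a `selection_result`.
#' @export
cfs_select <- function(X, y, folds = 10L, min_occurrence = 7L, seed = 1L) {
  X <- as.data.frame(X)
  if (stats::sd(y) == 0) abort_input("constant target: nothing to select",
                                     "redeye_selection_error")
  fold_idx <- make_folds(nrow(X), folds, seed)
  per_fold <- lapply(fold_idx, function(test) {
    tr <- setdiff(seq_len(nrow(X)), test)
    cfs_search(as.matrix(X[tr, , drop = FALSE]), y[tr])
  })
  counts <- table(unlist(per_fold))
  final <- names(counts)[counts >= min_occurrence]
  selection_result("CFS", per_fold, intersect(colnames(X), final))
}

# RReliefF weights (regression Relief) on one training set.  Features and
# target are range-normalised; each instance contributes its k nearest
# neighbours (Manhattan distance) with uniform weight.
rrelieff_weights <- function(X, y, neighbors = 10L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  rng <- apply(X, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  Xn <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rng, "/")
  yr <- diff(range(y))
  yn <- if (yr == 0) rep(0, n) else (y - min(y)) / yr
  k <- min(neighbors, n - 1L)
  ndc <- 0
  nda <- numeric(p)
  ndcda <- numeric(p)
  for (i in seq_len(n)) {
    dx <- abs(sweep(Xn[-i, , drop = FALSE], 2, Xn[i, ]))
    dist <- rowSums(dx)
    nn <- order(dist)[seq_len(k)]
    dy <- abs(yn[-i][nn] - yn[i])
    w <- rep(1 / k, k)
    ndc <- ndc + sum(w * dy)
    nda <- nda + colSums(dx[nn, , drop = FALSE] * w)
    ndcda <- ndcda + colSums(dx[nn, , drop = FALSE] * (w * dy))
  }
  m <- n
  if (ndc == 0 || m - ndc == 0) return(stats::setNames(numeric(p), colnames(X)))
  stats::setNames(ndcda / ndc - (nda - ndcda) / (m - ndc), colnames(X))
}

#' RReliefF ranking with fold aggregation
#'
#' Per training fold, RReliefF (the regression variant of Relief) weights
#' every feature; features are ranked by descending weight and the final
#' subset keeps those whose mean rank across folds is within the first
#' `top_k` positions.
#'
#' @inheritParams cfs_select
#' @param top_k rank cut-off for the final subset (default 10).
#' @param neighbors number of nearest neighbours per instance (default 10).
#' @return a `selection_result`; `per_fold` holds full rankings (character
#'   vectors of all feature names, most important first) and `mean_rank` the
#'   aggregated ranks.
#' @export
relieff_rank <- function(X, y, folds = 10L, top_k = 10L, neighbors = 10L,
                         seed = 1L) {
  X <- as.data.frame(X)
  p <- ncol(X)
  fold_idx <- make_folds(nrow(X), folds, seed)
  per_fold <- lapply(fold_idx, function(test) {
    tr <- setdiff(seq_len(nrow(X)), test)
    w <- rrelieff_weights(X[tr, , drop = FALSE], y[tr], neighbors)
    names(sort(w, decreasing = TRUE))
  })
  rank_mat <- vapply(per_fold, function(rk) match(colnames(X), rk),
                     numeric(p))
  mean_rank <- rowMeans(rank_mat)
  names(mean_rank) <- colnames(X)
  final <- if (p <= top_k) colnames(X) else
    colnames(X)[rank(mean_rank, ties.method = "first") <= top_k]
  selection_result("Relief", per_fold, final,
                   list(mean_rank = mean_rank, top_k = top_k))
}

#' Linear support-vector-regression weight selection with fold aggregation
#'
#' Per training fold, fits a linear epsilon-insensitive support-vector
#' regressor (SMO-family solver from e1071) and keeps the features whose
#' absolute weight is at least one standard deviation above the mean
#' absolute weight; the final subset keeps features selected in at least
#' `min_occurrence` folds.
#'
#' @inheritParams cfs_select
#' @param cost SVR cost parameter C.
#' @param epsilon epsilon-insensitive tube width.
#' @return a `selection_result`.
#' @export
smoreg_select <- function(X, y, folds = 10L, min_occurrence = 7L, seed = 1L,
                          cost = 1, epsilon = 0.1) {
  X <- as.data.frame(X)
  fold_idx <- make_folds(nrow(X), folds, seed)
  per_fold <- lapply(fold_idx, function(test) {
    tr <- setdiff(seq_len(nrow(X)), test)
    fit <- tryCatch(
      e1071::svm(as.matrix(X[tr, , drop = FALSE]), y[tr], kernel = "linear",
                 type = "eps-regression", cost = cost, epsilon = epsilon,
                 scale = FALSE),
      error = function(e) {
        abort_input(paste("degenerate SVR fit:", conditionMessage(e)),
                    "redeye_selection_error")
      }
    )
    w <- abs(drop(t(fit$coefs) %*% fit$SV))
    names(w) <- colnames(X)
    thr <- if (length(w) > 1L) mean(w) + stats::sd(w) else mean(w)
    names(w)[w >= thr]
  })
  counts <- table(unlist(per_fold))
  final <- names(counts)[counts >= min_occurrence]
  selection_result("SMOReg", per_fold, intersect(colnames(X), final))
}

#' Run a selector by name
#'
#' @param method `"none"`, `"cfs"`, `"relief"` or `"smoreg"`.
#' @inheritParams cfs_select
#' @return a `selection_result` (for `"none"`, a result whose final subset is
#'   every column).
#' @export
select_features <- function(method, X, y, folds = 10L, seed = 1L) {
  method <- match.arg(tolower(method), c("none", "cfs", "relief", "smoreg"))
  switch(method,
    none = selection_result("none", list(), colnames(as.data.frame(X))),
    cfs = cfs_select(X, y, folds = folds, seed = seed),
    relief = relieff_rank(X, y, folds = folds, seed = seed),
    smoreg = smoreg_select(X, y, folds = folds, seed = seed)
  )
}
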