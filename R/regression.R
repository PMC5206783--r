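# Regression of feature vectors onto the grading scale.  Three model
# families, all behind one fit/predict surface with predictions clipped to
# the grade range [0, 4]:
#   * MLP  — single-hidden-layer perceptron (nnet), logistic hidden units,
#            linear output plus skip-layer (direct linear) connections,
#            trained in warm-restarted bursts with validation-based early
#            stopping and averaged over seeded random restarts.
#   * PLS  — univariate partial least squares (NIPALS, mean-centred,
#            unscaled), max(1, min(10, p, n - 2)) components; deterministic
#            and robust to rank-deficient inputs.
#   * RF   — random forest (randomForest), 100 trees; seeded.

#' Fit a grading regressor
#'
#' @param kind `"mlp"`, `"pls"` or `"rf"`.
#' @param X data frame or matrix of (normalised) features.
#' @param y numeric grades in \[0, 4\].
#' @param seed integer seed (MLP initial weights, RF bootstrap).
#' @param clip prediction range (default `c(0, 4)`).
#' @param ... tuning overrides: `size`, `decay`, `skip`, `restarts`,
#'   `chunk`, `max_chunks`, `patience`, `val_frac` (MLP); `ncomp` (PLS);
#'   `ntree` (RF).
#' @return object of class `redeye_model`.
#' @export
fit_regressor <- function(kind, X, y, seed = 1L, clip = c(0, 4), ...) {
  kind <- match.arg(tolower(kind), c("mlp", "pls", "rf"))
  X <- as.matrix(as.data.frame(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  p <- ncol(X)
  dots <- list(...)
  fit <- switch(kind,
    mlp = {
      # one logistic hidden layer; the (p+1)/2 sizing rule is capped because
      # the full-batch BFGS optimiser scales quadratically in weight count
      size <- dots$size %||% min(8L, ceiling((p + 1) / 2))
      with_seed(seed, lapply(seq_len(dots$restarts %||% 3L), function(r) {
        mlp_train_early_stop(
          X, y, size = size, decay = dots$decay %||% 0.1,
          skip = dots$skip %||% TRUE, chunk = dots$chunk %||% 25L,
          max_chunks = dots$max_chunks %||% 20L,
          patience = dots$patience %||% 4L,
          val_frac = dots$val_frac %||% 0.2)
      }))
    },
    pls = {
      ncomp <- dots$ncomp %||% max(1L, min(10L, p, n - 2L))
      if (n < ncomp + 1L) {
        abort_input("too few samples for the requested PLS components",
                    "redeye_bad_config")
      }
      pls1_fit(X, y, ncomp)
    },
    rf = with_seed(seed, randomForest::randomForest(
      X, y, ntree = dots$ntree %||% 100L))
  )
  structure(list(kind = kind, fit = fit, clip = clip, columns = colnames(X),
                 seed = seed),
            class = "redeye_model")
}

#' Predict grades from a fitted regressor
#'
#' @param object a [fit_regressor()] model.
#' @param newdata data frame or matrix with the training columns.
#' @param ... unused.
#' @return numeric predictions clipped to the model's grade range.
#' @export
predict.redeye_model <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata))[, object$columns, drop = FALSE]
  raw <- switch(object$kind,
    mlp = rowMeans(matrix(vapply(object$fit, function(net) {
      as.numeric(stats::predict(net, X))
    }, numeric(nrow(X))), nrow = nrow(X))),
    pls = pls1_predict(object$fit, X),
    rf = drop(stats::predict(object$fit, X))
  )
  unname(clamp(raw, object$clip[1], object$clip[2]))
}

#' @export
print.redeye_model <- function(x, ...) {
  cat(sprintf("<redeye_model %s> %d features, clip [%g, %g]\n",
              toupper(x$kind), length(x$columns), x$clip[1], x$clip[2]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One early-stopped MLP: a validation split is held out of the training
# rows, the network is trained in short warm-restarted BFGS bursts, and the
# weights with the best validation error are kept.  Uses the current RNG
# stream (callers seed it).
mlp_train_early_stop <- function(X, y, size, decay, skip, chunk, max_chunks,
                                 patience, val_frac) {
  n <- nrow(X)
  max_wts <- (ncol(X) + 1L) * size + size + 1L + ncol(X) + 10L
  run <- function(x, yy, wts = NULL, maxit = chunk) {
    args <- list(x = x, y = yy, size = size, linout = TRUE, skip = skip,
                 trace = FALSE, decay = decay, maxit = maxit,
                 MaxNWts = max_wts)
    if (!is.null(wts)) args$Wts <- wts
    do.call(nnet::nnet, args)
  }
  n_val <- max(2L, round(val_frac * n))
  if (n - n_val < 3L) {
    return(run(X, y, maxit = chunk * max_chunks))  # too few rows to split
  }
  va <- sample(n, n_val)
  tr <- setdiff(seq_len(n), va)
  fit <- run(X[tr, , drop = FALSE], y[tr])
  val_mse <- function(f) {
    mean((drop(stats::predict(f, X[va, , drop = FALSE])) - y[va])^2)
  }
  best_wts <- fit$wts
  best_v <- val_mse(fit)
  stale <- 0L
  for (step in seq_len(max_chunks - 1L)) {
    fit <- run(X[tr, , drop = FALSE], y[tr], wts = fit$wts)
    v <- val_mse(fit)
    if (v < best_v - 1e-6) {
      best_v <- v
      best_wts <- fit$wts
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  run(X, y, wts = best_wts, maxit = 0L)
}

# Univariate-response partial least squares (PLS1) by NIPALS with
# mean-centring, no scaling.  Deflation stops early when the remaining
# covariance or score norm underflows, so rank-deficient inputs (constant
# targets, duplicated or single features) degrade gracefully to fewer
# components instead of failing.
pls1_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  p <- ncol(X)
  W <- P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  scale0 <- max(sum(Xc^2), .Machine$double.eps)
  a <- 0L
  for (k in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * sqrt(scale0) || !is.finite(nw)) break
    w <- w / nw
    tt <- drop(Xc %*% w)
    t2 <- sum(tt^2)
    if (t2 < 1e-12 * scale0) break
    pk <- drop(crossprod(Xc, tt)) / t2
    qk <- sum(yc * tt) / t2
    Xc <- Xc - tcrossprod(tt, pk)
    yc <- yc - tt * qk
    a <- k
    W[, k] <- w
    P[, k] <- pk
    Q[k] <- qk
  }
  beta <- if (a == 0L) {
    numeric(p)
  } else {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    drop(Wa %*% solve(crossprod(Pa, Wa), Q[seq_len(a)]))
  }
  list(beta = beta, x_means = xm, y_mean = ym, ncomp_used = a,
       ncomp_requested = ncomp)
}

pls1_predict <- function(fit, X) {
  drop(sweep(as.matrix(X), 2, fit$x_means) %*% fit$beta) + fit$y_mean
}

# Column-scope filters matching the two experimental protocols: "all" uses
# every region (o, t and cells); "cells_only" drops the o and t blocks.
scope_columns <- function(columns, scope = c("all", "cells_only")) {
  scope <- match.arg(scope)
  if (scope == "all") return(columns)
  columns[!grepl("_(o|t)$", columns)]
}

# Per-fold feature selection for a CV protocol: normaliser and selector are
# fitted on the training rows of each fold only.  Regressor-independent, so
# the experiment matrix computes these once per (grid, selector) and shares
# them across regressors.
cv_fold_selections <- function(X, y, selector, fold_idx, seed) {
  lapply(seq_along(fold_idx), function(f) {
    tr <- setdiff(seq_len(nrow(X)), fold_idx[[f]])
    norm <- feature_normalizer(X[tr, , drop = FALSE])
    Xtr <- predict(norm, X[tr, , drop = FALSE])
    sel <- select_features(selector, Xtr, y[tr],
                           folds = min(length(fold_idx), length(tr)),
                           seed = seed + f)
    sel$final_subset
  })
}

#' Cross-validated mean squared error of a (selector, regressor) pipeline
#'
#' Deterministic seeded 10-fold protocol.  Within each fold: the feature
#' normaliser is fitted on the training rows only, the selector (if any) is
#' re-run on the training rows only (itself aggregating over internal
#' folds), the regressor is fitted on the selected columns and scored on the
#' held-out rows.  No information from a test fold ever reaches selection or
#' normalisation.
#'
#' @param X data frame of raw (unnormalised) feature columns.
#' @param y numeric grades in \[0, 4\].
#' @param regressor `"mlp"`, `"pls"` or `"rf"`.
#' @param selector `NULL`/`"none"`, `"cfs"`, `"relief"` or `"smoreg"`.
#' @param folds number of folds (default 10).
#' @param seed integer seed driving folds and seeded regressors.
#' @param scope `"all"` or `"cells_only"` column scope.
#' @param grid optional grid tag recorded in the result.
#' @return object of class `experiment_result` with per-fold and mean MSE,
#'   per-fold selected subsets, the out-of-fold predictions (`predictions`,
#'   aligned to the input rows), and the protocol configuration.
#' @export
cross_validate_mse <- function(X, y, regressor, selector = NULL, folds = 10L,
                               seed = 1L, scope = "all", grid = NA_character_,
                               fold_selections = NULL) {
  X <- as.data.frame(X)
  if (nrow(X) < folds) abort_input("fewer rows than folds", "redeye_bad_protocol")
  selector <- if (is.null(selector)) "none" else tolower(selector)
  keep <- scope_columns(colnames(X), scope)
  X <- X[, keep, drop = FALSE]
  fold_idx <- make_folds(nrow(X), folds, seed)
  if (is.null(fold_selections)) {
    fold_selections <- cv_fold_selections(X, y, selector, fold_idx, seed)
  }
  per_fold_mse <- numeric(folds)
  per_fold_sel <- vector("list", folds)
  oof <- numeric(nrow(X))
  for (f in seq_along(fold_idx)) {
    test <- fold_idx[[f]]
    if (length(test) < 1L || nrow(X) - length(test) < 2L) {
      abort_input("a fold has too few samples", "redeye_bad_protocol")
    }
    tr <- setdiff(seq_len(nrow(X)), test)
    norm <- feature_normalizer(X[tr, , drop = FALSE])
    Xtr <- predict(norm, X[tr, , drop = FALSE])
    Xte <- predict(norm, X[test, , drop = FALSE])
    cols <- fold_selections[[f]]
    per_fold_sel[[f]] <- cols
    if (!length(cols)) {
      pred <- rep(mean(y[tr]), length(test))  # empty subset: grand-mean model
    } else {
      model <- fit_regressor(regressor, Xtr[, cols, drop = FALSE], y[tr],
                             seed = seed + f)
      pred <- predict(model, Xte[, cols, drop = FALSE])
    }
    per_fold_mse[f] <- mean((pred - y[test])^2)
    oof[test] <- pred
  }
  structure(list(
    grid = grid, selector = selector, regressor = regressor, scope = scope,
    per_fold_mse = per_fold_mse, mean_mse = mean(per_fold_mse),
    per_fold_selected = per_fold_sel, folds = folds, seed = seed,
    n = nrow(X), predictions = oof
  ), class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "<experiment_result> grid %s | selector %s | %s | scope %s: mean MSE %.5f (%d folds, n = %d)\n",
    x$grid, x$selector, toupper(x$regressor), x$scope, x$mean_mse, x$folds, x$n))
  invisible(x)
}
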