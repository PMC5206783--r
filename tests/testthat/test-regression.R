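test_that("PLS recovers an exactly linear target", {
  set.seed(3)
  X <- matrix(runif(120), 30, 4)
  colnames(X) <- paste0("x", 1:4)
  y <- drop(X %*% c(1, -2, 0.5, 3)) / 2
  fit <- fit_regressor("pls", X, y, clip = c(-10, 10))
  expect_lt(mean((predict(fit, X) - y)^2), 1e-6)
  # a single-feature subset still fits (univariate PLS)
  f1 <- fit_regressor("pls", X[, 1, drop = FALSE], X[, 1] * 2,
                      clip = c(-10, 10))
  expect_lt(mean((predict(f1, X[, 1, drop = FALSE]) - X[, 1] * 2)^2), 1e-6)
})

test_that("PLS agrees with an independent reference implementation", {
  set.seed(27)
  X <- matrix(rnorm(50 * 8), 50, 8)
  colnames(X) <- paste0("x", 1:8)
  y <- drop(X %*% rnorm(8)) + rnorm(50, sd = 0.3)
  for (nc in c(2, 5)) {
    fit <- fit_regressor("pls", X, y, clip = c(-100, 100), ncomp = nc)
    ref <- mixOmics::pls(X, y, ncomp = nc, mode = "regression", scale = FALSE)
    pref <- stats::predict(ref, X)$predict[, 1, nc]
    expect_equal(unname(predict(fit, X)), unname(pref), tolerance = 1e-8)
  }
})

test_that("a constant target is reproduced by every model family", {
  set.seed(5)
  X <- matrix(runif(200), 40, 5)
  colnames(X) <- paste0("x", 1:5)
  y <- rep(2.5, 40)
  for (kind in c("mlp", "pls", "rf")) {
    fit <- suppressWarnings(fit_regressor(kind, X, y, seed = 7))
    expect_lt(max(abs(predict(fit, X) - 2.5)), 0.05, label = kind)
  }
})

test_that("seeded fits are exactly reproducible", {
  set.seed(9)
  X <- matrix(runif(300), 60, 5)
  colnames(X) <- paste0("x", 1:5)
  y <- pmin(pmax(2 + X[, 1] - X[, 2] + rnorm(60, sd = 0.1), 0), 4)
  for (kind in c("mlp", "pls", "rf")) {
    p1 <- predict(fit_regressor(kind, X, y, seed = 31), X)
    p2 <- predict(fit_regressor(kind, X, y, seed = 31), X)
    expect_identical(p1, p2, info = kind)
  }
})

test_that("predictions are clipped to the grade range", {
  set.seed(2)
  X <- matrix(runif(100), 50, 2)
  colnames(X) <- c("x1", "x2")
  y <- pmin(4, 8 * X[, 1])            # saturating target
  fit <- fit_regressor("pls", X, y)
  preds <- predict(fit, matrix(c(2, 0.5), 1, 2,
                               dimnames = list(NULL, c("x1", "x2"))))
  expect_true(all(preds >= 0 & preds <= 4))
})

test_that("forests reduce variance relative to a single tree", {
  better <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(runif(60 * 5), 60, 5)
    colnames(X) <- paste0("x", 1:5)
    y <- pmin(pmax(4 * X[, 1] + rnorm(60, sd = 0.4), 0), 4)
    r100 <- cross_validate_mse(as.data.frame(X), y, regressor = "rf",
                               folds = 10, seed = seed)
    fold_idx <- make_folds(60, 10, seed)
    mse1 <- mean(vapply(fold_idx, function(te) {
      tr <- setdiff(1:60, te)
      fit <- fit_regressor("rf", X[tr, ], y[tr], seed = seed, ntree = 1L)
      mean((predict(fit, X[te, , drop = FALSE]) - y[te])^2)
    }, numeric(1)))
    better <- better + (r100$mean_mse <= mse1)
  }
  expect_gte(better, 8L)
})

test_that("cross-validation honours its protocol contract", {
  set.seed(20)
  X <- data.frame(a = runif(40), b = runif(40))
  y <- pmin(pmax(X$a * 4, 0), 4)
  res <- cross_validate_mse(cbind(X, y_dup = y), y, regressor = "pls",
                            folds = 10, seed = 3)
  expect_length(res$per_fold_mse, 10)
  expect_true(all(res$per_fold_mse >= 0))
  expect_equal(res$mean_mse, mean(res$per_fold_mse))
  expect_lt(res$mean_mse, 1e-6)       # target leaked as a feature: perfect
  expect_error(cross_validate_mse(X[1:5, ], y[1:5], "pls", folds = 10),
               class = "redeye_bad_protocol")
})

test_that("selection and normalisation never see test-fold labels", {
  set.seed(30)
  X <- data.frame(matrix(runif(50 * 8), 50, 8))
  names(X) <- paste0("f", 1:8)
  y <- pmin(pmax(4 * X$f1 + rnorm(50, sd = 0.2), 0), 4)
  fold_idx <- make_folds(50, 10, seed = 1)
  sels <- redeye:::cv_fold_selections(X, y, "smoreg", fold_idx, seed = 1)
  y2 <- y
  y2[fold_idx[[3]]] <- sample(y2[fold_idx[[3]]])   # shuffle one test fold
  sels2 <- redeye:::cv_fold_selections(X, y2, "smoreg", fold_idx, seed = 1)
  expect_identical(sels[[3]], sels2[[3]])
})

test_that("column scopes drop the global blocks", {
  cols <- c("F1_o", "F2_t", "F3_g1", "F4_g22", "F5_o")
  expect_identical(redeye:::scope_columns(cols, "all"), cols)
  expect_identical(redeye:::scope_columns(cols, "cells_only"),
                   c("F3_g1", "F4_g22"))
})
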