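test_that("mean-threshold masks select the conjunctiva side of each plane", {
  # constant image: threshold equals the constant, inclusive comparison
  # keeps every pixel for every method
  flat <- array(100, dim = c(12, 12, 3))
  for (id in threshold_methods()$id) {
    expect_true(all(channel_threshold_mask(flat, id)), info = id)
  }
  # two-level green image: mean splits the levels exactly
  img <- array(0, dim = c(10, 8, 3))
  img[, , 2] <- rbind(matrix(200, 5, 8), matrix(50, 5, 8))
  m <- channel_threshold_mask(img, "tg")
  expect_identical(m, rbind(matrix(TRUE, 5, 8), matrix(FALSE, 5, 8)))
})

test_that("the primed green method thresholds at the central-stripe mean", {
  # 9 rows: stripe = rows 4-6; G = 30 except stripe rows at 90
  img <- array(0, dim = c(9, 6, 3))
  img[, , 2] <- 30
  img[4:6, , 2] <- 90
  m <- channel_threshold_mask(img, "tgp")
  # threshold = 90 (stripe mean): only stripe rows pass
  expect_identical(m, img[, , 2] >= 90)
  expect_equal(sum(m), 18L)
})

test_that("red suppression changes only the saturated red pixels", {
  img <- array(0, dim = c(4, 4, 3))
  img[, , 1] <- 200; img[, , 2] <- 180; img[, , 3] <- 170
  img[1, 1, ] <- c(250, 60, 60)  # a vessel-like pixel
  m_raw <- channel_threshold_mask(img, "ts")
  m_cor <- channel_threshold_mask(img, "tsp")
  # raw TSL saturation excludes the saturated vessel pixel; after clamping
  # R to G the pixel is desaturated and classed as conjunctiva
  expect_false(m_raw[1, 1])
  expect_true(m_cor[1, 1])
  expect_identical(dim(m_cor), dim(m_raw))
})

test_that("the vote ensemble matches AND, OR and a popcount oracle", {
  set.seed(2)
  masks <- lapply(1:6, function(i) matrix(runif(64) > 0.5, 8, 8))
  expect_identical(ensemble_combine(masks, 6L), Reduce(`&`, masks))
  expect_identical(ensemble_combine(masks, 1L), Reduce(`|`, masks))
  # all 64 per-pixel vote patterns, every t_n
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  pmasks <- lapply(1:6, function(i) matrix(patterns[[i]], 8, 8))
  votes <- rowSums(patterns)
  for (tn in 1:6) {
    got <- ensemble_combine(pmasks, tn)
    expect_identical(as.vector(got), votes >= tn, info = paste("t_n", tn))
  }
})

test_that("ensemble input contracts are enforced", {
  masks <- lapply(1:6, function(i) matrix(TRUE, 4, 4))
  expect_error(ensemble_combine(masks[1:5], 3L), class = "redeye_bad_input")
  bad <- masks; bad[[6]] <- matrix(TRUE, 5, 4)
  expect_error(ensemble_combine(bad, 3L), class = "redeye_bad_input")
  expect_error(ensemble_combine(masks, 7L), class = "redeye_bad_config")
})

test_that("ensemble output shrinks as the vote threshold rises", {
  set.seed(4)
  masks <- lapply(1:6, function(i) matrix(runif(400) > 0.4, 20, 20))
  prev <- ensemble_combine(masks, 1L)
  for (tn in 2:6) {
    cur <- ensemble_combine(masks, tn)
    expect_true(all(!cur | prev))  # cur is a subset of prev
    prev <- cur
  }
  expect_true(all(!Reduce(`&`, masks) | ensemble_combine(masks, 4L)))
})

test_that("confusion counts tally pixels and are conserved", {
  truth <- matrix(c(TRUE, TRUE, FALSE, FALSE), 4, 4)
  expect_equal(unname(confusion_counts(truth, truth)[c("FP", "FN")]), c(0L, 0L))
  inv <- confusion_counts(!truth, truth)
  expect_equal(unname(inv[c("TP", "TN")]), c(0L, 0L))
  # hand-drawn 4x4 overlap
  pred <- matrix(FALSE, 4, 4); pred[1:2, 1:3] <- TRUE
  tr <- matrix(FALSE, 4, 4); tr[2:3, 2:4] <- TRUE
  cc <- confusion_counts(pred, tr)
  expect_equal(unname(cc), c(2L, 4L, 6L, 4L))  # TP FP TN FN by hand
  expect_equal(sum(cc), 16L)
  expect_error(confusion_counts(pred, matrix(TRUE, 2, 2)),
               class = "redeye_bad_input")
})

test_that("segmentation metrics follow the confusion definitions", {
  perfect <- segmentation_metrics(c(TP = 10, FP = 0, TN = 20, FN = 0))
  expect_equal(unlist(perfect), c(sensitivity = 1, specificity = 1,
                                  accuracy = 1, precision = 1))
  m <- segmentation_metrics(c(TP = 9, FP = 1, TN = 89, FN = 1))
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 89 / 90)
  expect_equal(m$accuracy, 0.98)
  expect_equal(m$precision, 0.9)
  # empty positive class: sensitivity undefined, not a number
  und <- segmentation_metrics(c(TP = 0, FP = 3, TN = 97, FN = 0))
  expect_true(is.na(und$sensitivity))
  expect_error(segmentation_metrics(c(TP = 0, FP = 0, TN = 0, FN = 0)),
               class = "redeye_bad_input")
})

test_that("watershed baseline recovers a bright blob on dark ground", {
  img <- array(30, dim = c(120, 120, 3))
  blob <- matrix(FALSE, 120, 120)
  blob[(row(blob) - 60)^2 + (col(blob) - 60)^2 <= 30^2] <- TRUE
  for (ch in 1:3) {
    pl <- img[, , ch]; pl[blob] <- 220; img[, , ch] <- pl
  }
  m <- baseline_watershed(img)
  expect_identical(dim(m), dim(blob))
  expect_gt(sum(m & blob) / sum(blob), 0.9)
  flat <- array(80, dim = c(40, 40, 3))
  d <- baseline_watershed(flat)
  expect_true(isTRUE(attr(d, "degenerate")))
})

test_that("split-and-merge respects variance structure", {
  flat <- array(120, dim = c(64, 64, 3))
  m <- baseline_split_merge(flat)
  expect_identical(dim(m), c(64L, 64L))
  expect_true(all(m == m[1, 1]))  # single segment, uniform decision
  # 2-level checkerboard of 64-px blocks: leaves align with the blocks
  img <- array(0, dim = c(256, 256, 3))
  g <- 50 + 150 * ((floor((row(matrix(0, 256, 256)) - 1) / 64) +
                    floor((col(matrix(0, 256, 256)) - 1) / 64)) %% 2)
  img[, , 2] <- g
  m2 <- baseline_split_merge(img)
  expect_identical(m2, g > mean(g))
})
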