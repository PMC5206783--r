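# Automatic conjunctiva segmentation.
#
# Six threshold methods, each thresholding one colour plane at the
# arithmetic mean of that plane over its scope (whole image or the central
# horizontal stripe, i.e. the middle third of rows).  The side of the
# threshold that is conjunctiva follows sclera optics: the sclera is bright
# in green (T_G, T_G'), bright in HSV value (T_V), desaturated in TSL
# saturation (T_S, T_S') and low on the green-red opponent axis (T_a).  For
# T_S' the red channel is first suppressed (R <- min(R, G)) so engorged
# vessels in severe hyperemia do not drag the saturation statistics.
#
# The ensemble keeps the pixels classed as conjunctiva by at least t_n of
# the six masks.  Watershed and split-and-merge are scored baselines only
# and never enter the vote.

#' Registry of threshold segmentation methods
#'
#' @return tibble with columns `id`, `plane`, `scope`
#'   (`whole`/`central_stripe`) and `polarity` (`above`/`below`: which side
#'   of the mean-threshold is conjunctiva).
#' @export
threshold_methods <- function() {
  tibble::tibble(
    id       = c("tg", "tgp", "ts", "tsp", "tv", "ta"),
    plane    = c("G", "G", "S_tsl", "S_tsl_red_suppressed", "V", "a"),
    scope    = c("whole", "central_stripe", "whole", "whole", "whole", "whole"),
    polarity = c("above", "above", "below", "below", "above", "below")
  )
}

threshold_plane <- function(img, method_row, planes = NULL) {
  switch(method_row$plane,
    G = img[, , 2],
    V = if (!is.null(planes)) planes$V else rgb_to_hsv_planes(img)$V,
    S_tsl = if (!is.null(planes)) planes$S_tsl else rgb_to_tsl(img)$S,
    a = if (!is.null(planes)) planes$a else rgb_to_lab(img)$a,
    S_tsl_red_suppressed = {
      imr <- img
      imr[, , 1] <- pmin(img[, , 1], img[, , 2])
      rgb_to_tsl(imr)$S
    },
    abort_input(paste("unknown plane", method_row$plane), "redeye_bad_config")
  )
}

#' Mask an image with one mean-threshold segmentation method
#'
#' The threshold is the arithmetic mean of the method's colour plane over its
#' scope; the mask keeps the pixels on the conjunctiva side of the threshold
#' (`above`: plane >= mean; `below`: plane <= mean).
#'
#' @param img RGB image array.
#' @param method one of `"tg"`, `"tgp"`, `"ts"`, `"tsp"`, `"tv"`, `"ta"`.
#' @param planes optional precomputed [color_planes()] (reused for speed).
#' @return logical matrix mask.
#' @export
channel_threshold_mask <- function(img, method, planes = NULL) {
  reg <- threshold_methods()
  row <- reg[reg$id == method, ]
  if (nrow(row) != 1L) {
    abort_input(sprintf("unknown threshold method '%s'", method),
                "redeye_bad_config")
  }
  p <- threshold_plane(img, row, planes)
  thr <- if (row$scope == "central_stripe") {
    h <- nrow(p)
    mean(p[(floor(h / 3) + 1L):ceiling(2 * h / 3), ])
  } else {
    mean(p)
  }
  if (row$polarity == "above") p >= thr else p <= thr
}

#' Combine six threshold masks by pixel vote
#'
#' A pixel is conjunctiva iff at least `t_n` of the six masks mark it.
#' `t_n = 6` is the logical AND of the masks, `t_n = 1` the logical OR.
#'
#' @param masks list of exactly six logical matrices of identical dimensions.
#' @param t_n vote threshold, integer in 1..6.
#' @return logical matrix mask.
#' @export
ensemble_combine <- function(masks, t_n) {
  if (length(masks) != 6L) {
    abort_input("the vote ensemble needs exactly six masks", "redeye_bad_input")
  }
  d <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), d), logical(1)))) {
    abort_input("ensemble masks must share dimensions", "redeye_bad_input")
  }
  if (t_n < 1L || t_n > 6L) abort_input("t_n must be in 1..6", "redeye_bad_config")
  votes <- Reduce(`+`, lapply(masks, function(m) m + 0L))
  votes >= t_n
}

#' Run all six threshold methods on one image
#'
#' @inheritParams channel_threshold_mask
#' @return named list of six logical masks, in registry order.
#' @export
threshold_masks <- function(img, planes = NULL) {
  ids <- threshold_methods()$id
  stats::setNames(lapply(ids, function(id) {
    channel_threshold_mask(img, id, planes)
  }), ids)
}

#' Watershed segmentation baseline
#'
#' Intensity watershed (EBImage) on the Gaussian-smoothed green plane; among
#' the basins whose mean green intensity exceeds the image mean, the largest
#' is returned as conjunctiva.  Scored baseline only — never part of the
#' vote ensemble.  A single-basin (degenerate) result is flagged in the
#' `degenerate` attribute.
#'
#' @param img RGB image array.
#' @param blur_sigma Gaussian smoothing sigma in pixels.
#' @param tolerance basin-merging tolerance on the 0-255 intensity scale.
#' @return logical matrix mask with attribute `degenerate`.
#' @export
baseline_watershed <- function(img, blur_sigma = 4, tolerance = 10) {
  validate_rgb_image(img)
  g <- img[, , 2] / 255
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(g), sigma = blur_sigma))
  labs <- EBImage::imageData(EBImage::watershed(EBImage::Image(sm),
                                                tolerance = tolerance / 255))
  n_basin <- max(labs)
  if (n_basin <= 1L) {
    out <- matrix(n_basin == 1L, nrow(g), ncol(g))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  means <- tapply(g[labs > 0], labs[labs > 0], mean)
  sizes <- tabulate(labs[labs > 0], nbins = n_basin)
  bright <- as.integer(names(means))[means > mean(g)]
  pick <- if (length(bright)) bright[which.max(sizes[bright])] else which.max(sizes)
  out <- labs == pick
  attr(out, "degenerate") <- FALSE
  out
}

#' Split-and-merge segmentation baseline
#'
#' Quadtree split of the green plane (split while block variance > `tau` and
#' block side > `min_block`), merge of adjacent leaves whose mean intensities
#' differ by less than `delta` (static leaf means over the leaf adjacency
#' graph), then selection of merged segments brighter than the image mean.
#' Scored baseline only.
#'
#' @param img RGB image array.
#' @param tau variance threshold for splitting (intensity^2 units).
#' @param delta mean-difference threshold for merging.
#' @param min_block minimum block side in pixels.
#' @return logical matrix mask.
#' @export
baseline_split_merge <- function(img, tau = 100, delta = 20, min_block = 8L) {
  validate_rgb_image(img)
  g <- img[, , 2]
  h <- nrow(g)
  w <- ncol(g)
  # summed-area tables (zero-padded) for O(1) block mean/variance
  s1 <- rbind(0, cbind(0, t(apply(apply(g, 2, cumsum), 1, cumsum))))
  s2 <- rbind(0, cbind(0, t(apply(apply(g^2, 2, cumsum), 1, cumsum))))
  bsum <- function(S, r0, c0, r1, c1) {
    S[r1 + 1, c1 + 1] - S[r0, c1 + 1] - S[r1 + 1, c0] + S[r0, c0]
  }
  leaves <- list()
  stack <- list(c(1L, 1L, h, w))
  while (length(stack)) {
    b <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    r0 <- b[1]; c0 <- b[2]; r1 <- b[3]; c1 <- b[4]
    np <- (r1 - r0 + 1) * (c1 - c0 + 1)
    mu <- bsum(s1, r0, c0, r1, c1) / np
    v <- bsum(s2, r0, c0, r1, c1) / np - mu^2
    can_split <- (r1 - r0 + 1) > min_block && (c1 - c0 + 1) > min_block
    if (v > tau && can_split) {
      rm_ <- (r0 + r1) %/% 2L
      cm_ <- (c0 + c1) %/% 2L
      stack <- c(stack, list(
        c(r0, c0, rm_, cm_), c(r0, cm_ + 1L, rm_, c1),
        c(rm_ + 1L, c0, r1, cm_), c(rm_ + 1L, cm_ + 1L, r1, c1)))
    } else {
      leaves[[length(leaves) + 1L]] <- c(b, mu)
    }
  }
  nl <- length(leaves)
  lab <- matrix(0L, h, w)
  mu_leaf <- numeric(nl)
  n_leaf <- numeric(nl)
  for (k in seq_len(nl)) {
    b <- leaves[[k]]
    lab[b[1]:b[3], b[2]:b[4]] <- k
    mu_leaf[k] <- b[5]
    n_leaf[k] <- (b[3] - b[1] + 1) * (b[4] - b[2] + 1)
  }
  # adjacency from horizontal/vertical label transitions
  pairs <- rbind(
    cbind(as.vector(lab[, -w]), as.vector(lab[, -1])),
    cbind(as.vector(lab[-h, ]), as.vector(lab[-1, ]))
  )
  pairs <- unique(pairs[pairs[, 1] != pairs[, 2], , drop = FALSE])
  parent <- seq_len(nl)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    keep <- abs(mu_leaf[pairs[, 1]] - mu_leaf[pairs[, 2]]) < delta
    for (k in which(keep)) {
      a <- find(pairs[k, 1])
      b <- find(pairs[k, 2])
      if (a != b) parent[b] <- a
    }
  }
  root <- vapply(seq_len(nl), find, integer(1))
  seg_sum <- tapply(mu_leaf * n_leaf, root, sum)
  seg_n <- tapply(n_leaf, root, sum)
  seg_mean <- seg_sum / seg_n
  bright_roots <- as.integer(names(seg_mean))[seg_mean > mean(g)]
  matrix(root[lab] %in% bright_roots, h, w)
}

#' Pixelwise confusion counts between a predicted and a true mask
#'
#' @param pred,truth logical matrices of identical dimensions.
#' @return named integer vector `c(TP, FP, TN, FN)`; the counts always sum to
#'   the total pixel count.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    abort_input("prediction and truth masks must share dimensions",
                "redeye_bad_input")
  }
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tn <- length(pred) - tp - fp - fn
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

#' Segmentation quality metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy (TP+TN)/total,
#' precision TP/(TP+FP).  A metric whose denominator is empty is returned as
#' `NA` (undefined), never as a number.
#'
#' @param counts named vector from [confusion_counts()].
#' @return tibble with one row: `sensitivity`, `specificity`, `accuracy`,
#'   `precision`.
#' @export
segmentation_metrics <- function(counts) {
  total <- sum(counts)
  if (total == 0) abort_input("all-zero confusion counts", "redeye_bad_input")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    sensitivity = safe(counts[["TP"]], counts[["TP"]] + counts[["FN"]]),
    specificity = safe(counts[["TN"]], counts[["TN"]] + counts[["FP"]]),
    accuracy    = (counts[["TP"]] + counts[["TN"]]) / total,
    precision   = safe(counts[["TP"]], counts[["TP"]] + counts[["FP"]])
  )
}
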