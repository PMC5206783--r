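# End-to-end experimental protocol over a (synthetic or annotated) dataset:
# a segmentation benchmark scoring the six thresholds, the two classical
# baselines and the vote ensemble against ground-truth masks, and a grading
# experiment running every (grid, selector, regressor) combination under
# seeded 10-fold cross-validation.

# Crop image and mask to the window needed for per-region features: the
# mask bounding box (plus a margin for the Canny smoothing support) united
# with the central-square footprint.  Region sums are unchanged; only
# pixels no region can touch are discarded.  The central-square fit is
# checked against the ORIGINAL image bounds first so the discard rule is
# identical with and without cropping.
crop_to_roi <- function(img, mask, side = 512L, margin = 16L) {
  m <- mask$mask
  if (!any(m)) abort_input("empty conjunctiva mask", "redeye_too_small_conjunctiva")
  idx <- which(m, arr.ind = TRUE)
  rr <- range(idx[, 1])
  cc <- range(idx[, 2])
  if (diff(rr) + 1L < side || diff(cc) + 1L < side) {
    abort_input("conjunctiva too small for the central square",
                "redeye_too_small_conjunctiva")
  }
  cr <- round(mean(idx[, 1]))
  ccol <- round(mean(idx[, 2]))
  r0s <- cr - side %/% 2L
  c0s <- ccol - side %/% 2L
  if (r0s < 1L || c0s < 1L || r0s + side - 1L > nrow(m) ||
      c0s + side - 1L > ncol(m)) {
    abort_input("conjunctiva too small: centred square exceeds image bounds",
                "redeye_too_small_conjunctiva")
  }
  r_lo <- max(1L, min(rr[1] - margin, r0s))
  r_hi <- min(nrow(m), max(rr[2] + margin, r0s + side - 1L))
  c_lo <- max(1L, min(cc[1] - margin, c0s))
  c_hi <- min(ncol(m), max(cc[2] + margin, c0s + side - 1L))
  list(img = img[r_lo:r_hi, c_lo:c_hi, , drop = FALSE],
       mask = region(m[r_lo:r_hi, c_lo:c_hi, drop = FALSE], mask$label))
}

#' Per-image feature tables for one or more grids
#'
#' For each image: normalises orientation (pupil to the canonical side),
#' rasterises the polygon ROI, computes colour planes and the Canny edge map
#' once, and assembles the `(m*n + 2) * 24` feature vector for every
#' requested grid.  Images whose conjunctiva cannot hold the central square
#' are dropped with a warning (the "too small" discard rule).
#'
#' @param dataset a `redeye_dataset` tibble (see [generate_dataset()] or
#'   [load_dataset()]).
#' @param grids list of grid pairs (default all of 1x2, 2x1, 2x2).
#' @param side central-square side (default 512).
#' @param sigma,hysteresis Canny configuration.
#' @param canonical canonical pupil side (default `"left"`).
#' @return named list (one element per grid, names like `"1x2"`) of tibbles:
#'   `image_id` plus one column per feature.
#' @export
feature_tables <- function(dataset, grids = list(c(1L, 2L), c(2L, 1L), c(2L, 2L)),
                           side = 512L, sigma = 1.4, hysteresis = NULL,
                           canonical = "left") {
  grid_name <- function(g) paste0(g[1], "x", g[2])
  acc <- stats::setNames(vector("list", length(grids)),
                         vapply(grids, grid_name, character(1)))
  kept_ids <- character(0)
  rows <- vector("list", nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    sc <- dataset_scene(dataset, i)
    img <- sc$image
    mask <- if (!is.null(dataset$roi[[i]])) {
      polygon_to_mask(dataset$roi[[i]], dim(img)[1:2])
    } else {
      sc$conjunctiva_mask
    }
    ori <- orient_image(img, mask, dataset$pupil_side[i], canonical)
    vecs <- tryCatch({
      cr <- crop_to_roi(ori$img, ori$mask, side = side)
      assemble_feature_vectors(cr$img, cr$mask, grids = grids, side = side,
                               sigma = sigma, hysteresis = hysteresis)
    }, redeye_too_small_conjunctiva = function(e) NULL)
    if (is.null(vecs)) {
      warning(sprintf("image %s: conjunctiva too small for the %d px square; dropped",
                      dataset$image_id[i], side), call. = FALSE)
      next
    }
    kept_ids <- c(kept_ids, dataset$image_id[i])
    rows[[i]] <- vecs
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  for (gi in seq_along(grids)) {
    if (!length(rows)) {
      acc[[gi]] <- tibble::tibble(image_id = character(0))
    } else {
      mat <- do.call(rbind, lapply(rows, `[[`, gi))
      acc[[gi]] <- dplyr::bind_cols(tibble::tibble(image_id = kept_ids),
                                    tibble::as_tibble(mat))
    }
  }
  acc
}

#' Benchmark conjunctiva segmentation methods against ground truth
#'
#' Scores the six mean-threshold methods, optionally the watershed and
#' split-and-merge baselines, and the vote ensemble at each `t_n` against
#' the ground-truth conjunctiva masks; sensitivity, specificity, accuracy
#' and precision are averaged over images.
#'
#' @param dataset a `redeye_dataset` with scenes carrying ground-truth masks.
#' @param t_n vote thresholds to evaluate (default 2:6).
#' @param include_baselines score the two classical baselines too (default
#'   `TRUE`).
#' @return tibble of class `redeye_benchmark`: `method`, `t_n`, the four
#'   mean metrics and `n_images`.
#' @export
run_segmentation_benchmark <- function(dataset, t_n = 2:6,
                                       include_baselines = TRUE) {
  ids <- threshold_methods()$id
  methods <- c(ids, if (include_baselines) c("watershed", "splitmerge"),
               paste0("ensemble_t", t_n))
  sums <- list()
  n_img <- 0L
  for (i in seq_len(nrow(dataset))) {
    sc <- dataset_scene(dataset, i)
    truth <- sc$conjunctiva_mask$mask
    if (is.null(truth)) {
      warning(sprintf("image %s has no ground-truth mask; skipped",
                      dataset$image_id[i]), call. = FALSE)
      next
    }
    planes <- color_planes(sc$image)
    masks <- threshold_masks(sc$image, planes)
    preds <- masks
    if (include_baselines) {
      preds$watershed <- baseline_watershed(sc$image)
      preds$splitmerge <- baseline_split_merge(sc$image)
    }
    for (tn in t_n) preds[[paste0("ensemble_t", tn)]] <-
      ensemble_combine(masks, tn)
    n_img <- n_img + 1L
    for (m in names(preds)) {
      met <- segmentation_metrics(confusion_counts(preds[[m]], truth))
      sums[[m]] <- if (is.null(sums[[m]])) met else sums[[m]] + met
    }
  }
  if (n_img == 0L) abort_input("no image with ground truth", "redeye_bad_input")
  out <- purrr::map_dfr(methods, function(m) {
    dplyr::bind_cols(
      tibble::tibble(
        method = m,
        t_n = if (grepl("^ensemble_t", m)) {
          as.integer(sub("^ensemble_t", "", m))
        } else {
          NA_integer_
        }
      ),
      sums[[m]] / n_img
    )
  })
  out$n_images <- n_img
  class(out) <- c("redeye_benchmark", class(out))
  out
}

#' Run the full grading experiment matrix
#'
#' Applies the agreement filter and ground-truth averaging to the grading
#' table, assembles feature vectors per grid, and evaluates every (grid,
#' selector, regressor) combination with seeded 10-fold cross-validation
#' under the chosen column scope.  Also reports, per grid and selector, the
#' subset selected on the full filtered dataset.  With `out_dir` set, writes
#' one MSE CSV per regressor (rows = grids, columns = selectors) and a
#' selected-features CSV.
#'
#' @param dataset a `redeye_dataset`.
#' @param grids list of grid pairs.
#' @param selectors subset of `c("none", "cfs", "relief", "smoreg")`.
#' @param regressors subset of `c("mlp", "pls", "rf")`.
#' @param scope `"all"` or `"cells_only"`.
#' @param agreement_threshold agreement filter threshold (default 0.5).
#' @param folds,seed cross-validation protocol.
#' @param side central-square side.
#' @param out_dir optional directory for result CSVs.
#' @return tibble of class `redeye_experiment`: one row per matrix cell with
#'   `grid`, `selector`, `regressor`, `scope`, `mean_mse` and a `result`
#'   list-column of [cross_validate_mse()] objects; attribute
#'   `"selected_features"` holds the full-data selection report.
#' @export
run_grading_experiment <- function(dataset,
                                   grids = list(c(1L, 2L), c(2L, 1L), c(2L, 2L)),
                                   selectors = c("none", "cfs", "relief", "smoreg"),
                                   regressors = c("mlp", "pls", "rf"),
                                   scope = "all",
                                   agreement_threshold = 0.5,
                                   folds = 10L, seed = 1L, side = 512L,
                                   out_dir = NULL) {
  records <- filter_by_agreement(dataset, agreement_threshold)
  if (nrow(records) < folds) {
    abort_input(sprintf(
      "only %d images pass the %.2f-point agreement filter; %d needed for %d-fold CV",
      nrow(records), agreement_threshold, folds, folds), "redeye_bad_protocol")
  }
  records <- make_ground_truth(records)
  tables <- feature_tables(records, grids = grids, side = side)
  grid_names <- names(tables)
  cells <- list()
  sel_report <- list()
  for (g in grid_names) {
    tab <- tables[[g]]
    keep <- match(tab$image_id, records$image_id)
    y <- records$ground_truth[keep]
    X <- dplyr::select(tab, -"image_id")
    Xs <- X[, scope_columns(colnames(X), scope), drop = FALSE]
    fold_idx <- make_folds(nrow(Xs), folds, seed)
    for (sel in selectors) {
      if (sel != "none") {
        full_sel <- select_features(sel, normalize_features(Xs), y,
                                    folds = folds, seed = seed)
        sel_report[[paste(g, sel)]] <- tibble::tibble(
          grid = g, selector = sel,
          features = paste(full_sel$final_subset, collapse = " "))
      }
      sels <- cv_fold_selections(Xs, y, sel, fold_idx, seed)
      for (reg in regressors) {
        res <- cross_validate_mse(X, y, regressor = reg, selector = sel,
                                  folds = folds, seed = seed, scope = scope,
                                  grid = g, fold_selections = sels)
        cells[[paste(g, sel, reg)]] <- tibble::tibble(
          grid = g, selector = sel, regressor = reg, scope = scope,
          mean_mse = res$mean_mse, result = list(res))
      }
    }
  }
  out <- dplyr::bind_rows(cells)
  attr(out, "selected_features") <- dplyr::bind_rows(sel_report)
  class(out) <- c("redeye_experiment", class(out))
  if (!is.null(out_dir)) write_experiment_csvs(out, out_dir)
  out
}

#' Write experiment results as CSV files
#'
#' One `mse_<regressor>.csv` per regressor (rows = grids, columns =
#' selectors) plus `selected_features.csv`.
#'
#' @param experiment a `redeye_experiment` tibble.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_experiment_csvs <- function(experiment, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (reg in unique(experiment$regressor)) {
    wide <- tidyr::pivot_wider(
      dplyr::select(
        dplyr::filter(tibble::as_tibble(experiment), .data$regressor == reg),
        "grid", "selector", "mean_mse"),
      names_from = "selector", values_from = "mean_mse")
    readr::write_csv(wide, file.path(out_dir, paste0("mse_", reg, ".csv")))
  }
  sel <- attr(experiment, "selected_features")
  if (!is.null(sel) && nrow(sel)) {
    readr::write_csv(sel, file.path(out_dir, "selected_features.csv"))
  }
  invisible(out_dir)
}
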