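# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation result into per-fold rows
#'
#' @param x an `experiment_result` from [cross_validate_mse()].
#' @param ... unused.
#' @return tibble with `fold`, `mse` and the selected features per fold.
#' @export
tidy.experiment_result <- function(x, ...) {
  tibble::tibble(
    grid = x$grid, selector = x$selector, regressor = x$regressor,
    fold = seq_along(x$per_fold_mse), mse = x$per_fold_mse,
    n_selected = vapply(x$per_fold_selected, length, integer(1)),
    selected = vapply(x$per_fold_selected, paste, character(1), collapse = " ")
  )
}

#' One-row summary of a cross-validation result
#'
#' @inheritParams tidy.experiment_result
#' @return one-row tibble with the protocol cell and its mean MSE.
#' @export
glance.experiment_result <- function(x, ...) {
  tibble::tibble(
    grid = x$grid, selector = x$selector, regressor = x$regressor,
    scope = x$scope, folds = x$folds, n = x$n, mean_mse = x$mean_mse,
    sd_mse = stats::sd(x$per_fold_mse), seed = x$seed
  )
}

#' Tidy a feature-selection result
#'
#' @param x a `selection_result`.
#' @param ... unused.
#' @return tibble with one row per (fold, feature) choice; for rankers the
#'   per-fold rank is included.
#' @export
tidy.selection_result <- function(x, ...) {
  if (!length(x$per_fold)) {
    return(tibble::tibble(method = x$method, fold = integer(),
                          feature = character(), rank = integer()))
  }
  purrr::map_dfr(seq_along(x$per_fold), function(f) {
    feats <- x$per_fold[[f]]
    tibble::tibble(method = x$method, fold = f, feature = feats,
                   rank = seq_along(feats))
  })
}

#' One-row summary of a feature-selection result
#'
#' @inheritParams tidy.selection_result
#' @return one-row tibble with the final subset.
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(method = x$method, folds = length(x$per_fold),
                 n_selected = length(x$final_subset),
                 final_subset = paste(x$final_subset, collapse = " "))
}

#' Plot a segmentation benchmark
#'
#' Dot-line chart of the four mean metrics per method; ensemble rows are
#' ordered by their vote threshold.
#'
#' @param object a `redeye_benchmark` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.redeye_benchmark <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("sensitivity", "specificity", "accuracy", "precision"),
    names_to = "metric", values_to = "value")
  long$method <- factor(long$method, levels = unique(object$method))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value,
                                     colour = .data$metric,
                                     group = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "mean metric over images", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a grading experiment matrix
#'
#' MSE heatmap, grids by selectors, faceted by regressor.
#'
#' @param object a `redeye_experiment` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.redeye_experiment <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$selector, y = .data$grid,
                               fill = .data$mean_mse)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$mean_mse)),
                       size = 3) +
    ggplot2::facet_wrap(~regressor) +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "feature selector", y = "grid", fill = "CV MSE") +
    ggplot2::theme_minimal()
}

#' Display a synthetic scene
#'
#' @param object a `synthetic_scene`.
#' @param ... unused.
#' @return a ggplot showing the RGB image.
#' @export
autoplot.synthetic_scene <- function(object, ...) {
  img <- object$image / 255
  ggplot2::ggplot() +
    ggplot2::annotation_raster(img, xmin = 0, xmax = ncol(img),
                               ymin = 0, ymax = nrow(img)) +
    ggplot2::xlim(0, ncol(img)) +
    ggplot2::ylim(0, nrow(img)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("synthetic scene, grade %.2f",
                                  object$true_grade)) +
    ggplot2::theme_void()
}
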