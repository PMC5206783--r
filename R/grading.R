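# Preparation of expert grading tables.  Two graders score each image on
# the 0-4 scale with decimal precision; images where they disagree too much
# are discarded, and the mean of the two scores on the kept images is the
# regression ground truth.

#' Filter a grading table by inter-grader agreement
#'
#' Keeps the records where the two experts' grades differ strictly less than
#' `threshold` points and reports the Pearson correlation of the two graders
#' on the kept set.
#'
#' @param records data frame with numeric columns `grade1`, `grade2` in
#'   \[0, 4\].
#' @param threshold agreement threshold in grade points (default 0.5).
#' @return the kept rows (tibble) with attribute `"correlation"` — the
#'   Pearson correlation of `grade1` and `grade2` on the kept set (`NA` if
#'   fewer than 2 rows survive or a grader is constant).
#' @export
filter_by_agreement <- function(records, threshold = 0.5) {
  if (nrow(records) < 2L) {
    abort_input("need at least 2 graded records", "redeye_bad_input")
  }
  kept <- dplyr::filter(tibble::as_tibble(records),
                        abs(.data$grade1 - .data$grade2) < threshold)
  r <- if (nrow(kept) < 2L || stats::sd(kept$grade1) == 0 ||
           stats::sd(kept$grade2) == 0) {
    NA_real_
  } else {
    stats::cor(kept$grade1, kept$grade2)
  }
  attr(kept, "correlation") <- r
  kept
}

#' Agreement summary over several thresholds
#'
#' @param records data frame with `grade1`, `grade2`.
#' @param thresholds numeric vector of agreement thresholds.
#' @return tibble with `threshold`, `n_images`, `correlation`.
#' @export
grader_agreement <- function(records, thresholds = c(0.5, 1, 1.5)) {
  purrr::map_dfr(thresholds, function(th) {
    kept <- filter_by_agreement(records, th)
    tibble::tibble(threshold = th, n_images = nrow(kept),
                   correlation = attr(kept, "correlation"))
  })
}

#' Attach the ground-truth grade to a grading table
#'
#' The ground truth of an image is the arithmetic mean of the two experts'
#' grades.
#'
#' @param records data frame with numeric `grade1`, `grade2` (no missing
#'   values).
#' @return `records` with a `ground_truth` column.
#' @export
make_ground_truth <- function(records) {
  if (anyNA(records$grade1) || anyNA(records$grade2)) {
    abort_input("both grades must be present to form the ground truth",
                "redeye_bad_input")
  }
  dplyr::mutate(tibble::as_tibble(records),
                ground_truth = (.data$grade1 + .data$grade2) / 2)
}
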