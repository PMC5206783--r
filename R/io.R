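# Reading and writing the interchange formats: 8-bit RGB images (PNG/TIFF/
# JPEG), 0/255 mask PNGs, polygon ROI annotations (JSON) and grading CSVs.

#' Read an RGB image
#'
#' @param path PNG, TIFF or JPEG file (8-bit per channel).
#' @return RGB image array, `height x width x 3`, values in \[0, 255\].
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort_input("the 'tiff' package is needed to read TIFF images",
                    "redeye_bad_input")
      }
      tiff::readTIFF(path)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        abort_input("the 'jpeg' package is needed to read JPEG images",
                    "redeye_bad_input")
      }
      jpeg::readJPEG(path)
    },
    abort_input(sprintf("unsupported image format '%s'", ext),
                "redeye_bad_input")
  )
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  round(raw[, , 1:3, drop = FALSE] * 255)
}

#' Write a binary mask as a 0/255 single-channel PNG
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Read a binary mask from a PNG
#'
#' @param path PNG file; any nonzero pixel is foreground.
#' @return logical matrix.
#' @export
read_mask_png <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  raw > 0.5
}

#' Read a polygon ROI annotation
#'
#' @param path JSON file with fields `image`, `vertices` (list of
#'   `[row, col]` pairs in the 0-based pixel frame) and `pupil_side`.
#' @return list with `image`, `vertices` (matrix) and `pupil_side`.
#' @export
read_roi_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$vertices <- matrix(as.numeric(t(x$vertices)), ncol = 2, byrow = TRUE)
  x
}

#' Load a dataset directory
#'
#' Expects the layout written by [write_dataset()]: `<id>.png` images,
#' optional `<id>_mask.png` ground-truth masks, `<id>_roi.json` polygon
#' annotations and a `grading.csv` with columns
#' `image_id,grade1,grade2,pupil_side`.
#'
#' @param dir dataset directory.
#' @return a `redeye_dataset` tibble compatible with [feature_tables()],
#'   [run_segmentation_benchmark()] and [run_grading_experiment()].
#' @export
load_dataset <- function(dir) {
  grading <- readr::read_csv(file.path(dir, "grading.csv"),
                             show_col_types = FALSE)
  rows <- purrr::map(seq_len(nrow(grading)), function(i) {
    id <- grading$image_id[i]
    img <- read_rgb_image(file.path(dir, paste0(id, ".png")))
    mask_path <- file.path(dir, paste0(id, "_mask.png"))
    truth <- if (file.exists(mask_path)) read_mask_png(mask_path) else NULL
    roi <- read_roi_json(file.path(dir, paste0(id, "_roi.json")))
    scene <- structure(list(
      image = img,
      conjunctiva_mask = if (!is.null(truth)) region(truth, "o") else NULL,
      vessel_mask = NULL, true_grade = NA_real_, params = NULL
    ), class = "synthetic_scene")
    tibble::tibble(image_id = id, scene = list(scene),
                   roi = list(roi$vertices),
                   pupil_side = grading$pupil_side[i],
                   grade1 = grading$grade1[i], grade2 = grading$grade2[i],
                   true_grade = NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("redeye_dataset", class(out))
  out
}

#' Export a colour plane as a single-channel PNG (debug aid)
#'
#' @param plane numeric matrix in \[0, 255\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plane_png <- function(plane, path) {
  png::writePNG(clamp(plane, 0, 255) / 255, path)
  invisible(path)
}
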