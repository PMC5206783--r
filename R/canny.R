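# Canny edge detection on the green plane, used to split a region into
# vessel-edge pixels (VE) and background pixels (VE-bar).  The green plane
# gives the best vessel/sclera contrast in ocular imaging.  Stages:
# separable Gaussian smoothing, Sobel gradients, non-maximum suppression
# along the quantised gradient direction, and two-level hysteresis
# implemented as connected-component retention (weak components that touch a
# strong pixel survive).  Hysteresis thresholds default to Otsu's threshold
# on the gradient magnitude for the high level and half of it for the low
# level, since clinical image contrast varies widely.

#' Canny edge map of a single plane
#'
#' @param plane numeric matrix (any scale).
#' @param sigma Gaussian smoothing sigma in pixels (default 1.4).
#' @param hysteresis optional `c(low, high)` thresholds on gradient
#'   magnitude; by default `high` is Otsu's threshold on the magnitude
#'   histogram and `low = 0.5 * high`.
#' @return logical matrix of edge pixels.
#' @export
canny_edges <- function(plane, sigma = 1.4, hysteresis = NULL) {
  stopifnot(is.matrix(plane))
  sm <- sep_conv(plane, gaussian_kernel1d(sigma))
  # Sobel gradients via shifted sums (replicate padding)
  gx <- (mat_shift(sm, -1L, 1L) + 2 * mat_shift(sm, 0L, 1L) + mat_shift(sm, 1L, 1L)) -
        (mat_shift(sm, -1L, -1L) + 2 * mat_shift(sm, 0L, -1L) + mat_shift(sm, 1L, -1L))
  gy <- (mat_shift(sm, 1L, -1L) + 2 * mat_shift(sm, 1L, 0L) + mat_shift(sm, 1L, 1L)) -
        (mat_shift(sm, -1L, -1L) + 2 * mat_shift(sm, -1L, 0L) + mat_shift(sm, -1L, 1L))
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  if (mx == 0) return(matrix(FALSE, nrow(plane), ncol(plane)))
  # non-maximum suppression in 4 quantised directions (tan(22.5 deg) split,
  # avoiding atan2): the gradient points along (gy, gx) in (row, col) terms
  adx <- abs(gx)
  ady <- abs(gy)
  t225 <- tan(pi / 8)
  horiz <- ady <= t225 * adx            # gradient ~ along columns
  vert <- adx <= t225 * ady             # gradient ~ along rows
  diag1 <- !horiz & !vert & (gx * gy > 0)   # toward (+1, +1) / (-1, -1)
  diag2 <- !horiz & !vert & !diag1
  n1 <- horiz * mat_shift(mag, 0L, 1L) + vert * mat_shift(mag, 1L, 0L) +
    diag1 * mat_shift(mag, 1L, 1L) + diag2 * mat_shift(mag, 1L, -1L)
  n2 <- horiz * mat_shift(mag, 0L, -1L) + vert * mat_shift(mag, -1L, 0L) +
    diag1 * mat_shift(mag, -1L, -1L) + diag2 * mat_shift(mag, -1L, 1L)
  ridge <- mag >= n1 & mag >= n2 & mag > 0
  if (is.null(hysteresis)) {
    high <- as.numeric(EBImage::otsu(EBImage::Image(mag / mx), range = c(0, 1))) * mx
    low <- 0.5 * high
  } else {
    low <- hysteresis[1]
    high <- hysteresis[2]
  }
  strong <- ridge & mag >= high
  weak <- ridge & mag >= low
  if (!any(strong)) return(matrix(FALSE, nrow(plane), ncol(plane)))
  labs <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(weak * 1)))
  keep <- logical(max(labs) + 1L)
  keep[unique(labs[strong]) + 1L] <- TRUE
  keep[1L] <- FALSE  # background label 0
  matrix(keep[labs + 1L], nrow(plane), ncol(plane))
}

#' Split a region into vessel-edge and background pixels
#'
#' Runs [canny_edges()] on the image's green plane; region pixels on an edge
#' form the vessel-edge set VE, the rest the background set VE-bar.
#'
#' @param img RGB image array.
#' @param region a [region()]; must be nonempty.
#' @param sigma,hysteresis passed to [canny_edges()].
#' @param edges optional precomputed full-image edge map (logical matrix),
#'   reused across the regions of one image.
#' @return object of class `vessel_partition`: list with `E` (full edge
#'   map), `ve` (logical matrix, VE) and `ve_bar` (logical matrix), where
#'   `ve | ve_bar` equals the region mask and the two are disjoint.
#' @export
detect_vessel_edges <- function(img, region, sigma = 1.4, hysteresis = NULL,
                                edges = NULL) {
  stopifnot(inherits(region, "region"))
  if (pixel_count(region) == 0L) {
    abort_input("cannot partition an empty region", "redeye_bad_input")
  }
  if (is.null(edges)) edges <- canny_edges(img[, , 2], sigma, hysteresis)
  ve <- edges & region$mask
  structure(list(E = edges, ve = ve, ve_bar = region$mask & !edges),
            class = "vessel_partition")
}
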