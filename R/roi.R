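# Regions of interest.  A Region is a logical mask over the image plus a
# label: "o" (whole conjunctiva polygon), "t" (central 512-px square
# intersected with the conjunctiva) or a grid-cell tag such as "g21".
#
# Pixel geometry: pixels are unit squares on a 0-based (row, column) grid,
# origin top-left; pixel (i, j) has centre (i + 0.5, j + 0.5).  Matrix entry
# [i + 1, j + 1] stores pixel (i, j).

#' Create a region
#'
#' @param mask logical matrix; `TRUE` marks region pixels.
#' @param label region tag: `"o"`, `"t"`, or a grid cell such as `"g21"`.
#' @return object of class `region`.
#' @export
region <- function(mask, label = "o") {
  stopifnot(is.matrix(mask), is.logical(mask))
  structure(list(mask = mask, label = label), class = "region")
}

#' Number of pixels in a region
#' @param x a [region()].
#' @return integer count of `TRUE` mask entries.
#' @export
pixel_count <- function(x) {
  stopifnot(inherits(x, "region"))
  sum(x$mask)
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region '%s'> %d x %d mask, %d pixels\n",
              x$label, nrow(x$mask), ncol(x$mask), pixel_count(x)))
  invisible(x)
}

#' Rasterise a polygon annotation into a conjunctiva region
#'
#' A pixel belongs to the region iff its centre lies inside the polygon under
#' the even-odd (crossing-number) rule.  Centres falling exactly on an edge
#' are resolved by the half-open crossing convention (a measure-zero case for
#' hand-drawn annotations).
#'
#' @param vertices numeric matrix (or list of pairs) of polygon vertices as
#'   `(row, column)` coordinates in the 0-based pixel coordinate frame; at
#'   least 3 vertices, all within `[0, height] x [0, width]`.
#' @param dim image dimensions `c(height, width)` in pixels.
#' @return a [region()] labelled `"o"`.
#' @export
#' @examples
#' r <- polygon_to_mask(rbind(c(0, 0), c(0, 20), c(10, 20), c(10, 0)), c(32, 32))
#' pixel_count(r)  # 10 x 20 rectangle covers 200 pixel centres
polygon_to_mask <- function(vertices, dim) {
  if (is.list(vertices)) vertices <- do.call(rbind, lapply(vertices, as.numeric))
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) {
    abort_input("a polygon annotation needs at least 3 vertices",
                "redeye_invalid_annotation")
  }
  h <- dim[1]
  w <- dim[2]
  if (any(vertices[, 1] < 0) || any(vertices[, 1] > h) ||
      any(vertices[, 2] < 0) || any(vertices[, 2] > w)) {
    abort_input("polygon vertices fall outside the image bounds",
                "redeye_invalid_annotation")
  }
  yc <- seq_len(h) - 0.5   # pixel-centre row coordinates
  vy <- vertices[, 1]
  vx <- vertices[, 2]
  n <- length(vy)
  nxt <- c(seq_len(n)[-1], 1L)
  # scanline even-odd fill: per image row, collect the x-coordinates where
  # edges cross the row's centre line, sort them, and fill alternate runs.
  cross_x <- vector("list", h)
  for (e in seq_len(n)) {
    y1 <- vy[e]; y2 <- vy[nxt[e]]
    x1 <- vx[e]; x2 <- vx[nxt[e]]
    if (y1 == y2) next
    rows <- which((y1 > yc) != (y2 > yc))
    if (!length(rows)) next
    xint <- x1 + (yc[rows] - y1) / (y2 - y1) * (x2 - x1)
    for (k in seq_along(rows)) {
      r <- rows[k]
      cross_x[[r]] <- c(cross_x[[r]], xint[k])
    }
  }
  mask <- matrix(FALSE, h, w)
  for (r in seq_len(h)) {
    xs <- cross_x[[r]]
    if (length(xs) < 2L) next
    xs <- sort(xs)
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      # centres xc = c - 0.5 with xs[k] <= xc < xs[k + 1]
      c0 <- ceiling(xs[k] + 0.5)
      c1 <- clamp(ceiling(xs[k + 1] - 0.5), 0, w)
      if (c0 <= c1) mask[r, c0:c1] <- TRUE
    }
  }
  region(mask, "o")
}

#' Normalise lateral orientation so the pupil sits on the canonical side
#'
#' Images in a grading set show the pupil on either lateral side; features
#' computed per grid cell are only comparable if the same cell shows the same
#' anatomy, so images whose pupil side differs from the canonical side are
#' mirrored about the vertical axis (left-right), together with their masks.
#' The operation is an involution: flipping twice restores the input.
#'
#' @param img RGB image array.
#' @param mask a [region()] (the conjunctiva mask).
#' @param pupil_side `"left"` or `"right"`: where the pupil is in `img`.
#' @param canonical the side every output should have (default `"left"`).
#' @return list with elements `img` and `mask`, mirrored if needed.
#' @export
orient_image <- function(img, mask, pupil_side, canonical = "left") {
  pupil_side <- match.arg(pupil_side, c("left", "right"))
  canonical <- match.arg(canonical, c("left", "right"))
  if (pupil_side == canonical) return(list(img = img, mask = mask))
  w <- dim(img)[2]
  list(img = img[, w:1, , drop = FALSE],
       mask = region(mask$mask[, w:1, drop = FALSE], mask$label))
}

#' Central square of the conjunctiva mask
#'
#' Places a `side x side` square centred on the integer-rounded centroid of
#' the mask and intersects it with the mask, so occluders excluded by the
#' polygon stay excluded.  Errors if the mask's bounding box is smaller than
#' `side` in either dimension or the square does not fit inside the image —
#' the "conjunctiva too small" case in which an image must be discarded.
#'
#' @param mask a [region()] (whole conjunctiva).
#' @param side square side in pixels (default 512).
#' @return a [region()] labelled `"t"`, with attribute `footprint` holding the
#'   square's row/column ranges (used by [subdivide_grid()]).
#' @export
central_square <- function(mask, side = 512L) {
  stopifnot(inherits(mask, "region"))
  m <- mask$mask
  if (!any(m)) abort_input("empty conjunctiva mask", "redeye_too_small_conjunctiva")
  idx <- which(m, arr.ind = TRUE)
  bb_h <- diff(range(idx[, 1])) + 1L
  bb_w <- diff(range(idx[, 2])) + 1L
  if (bb_h < side || bb_w < side) {
    abort_input(sprintf(
      "conjunctiva too small: mask bounding box %d x %d cannot hold a %d x %d square",
      bb_h, bb_w, side, side), "redeye_too_small_conjunctiva")
  }
  cr <- round(mean(idx[, 1]))
  cc <- round(mean(idx[, 2]))
  r0 <- cr - side %/% 2L
  c0 <- cc - side %/% 2L
  if (r0 < 1L || c0 < 1L || r0 + side - 1L > nrow(m) || c0 + side - 1L > ncol(m)) {
    abort_input("conjunctiva too small: centred square exceeds image bounds",
                "redeye_too_small_conjunctiva")
  }
  sq <- matrix(FALSE, nrow(m), ncol(m))
  sq[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- TRUE
  out <- region(sq & m, "t")
  attr(out, "footprint") <- list(rows = c(r0, r0 + side - 1L),
                                 cols = c(c0, c0 + side - 1L))
  out
}

#' Subdivide the central square into grid cells
#'
#' Partitions the square footprint into `m x n` equal rectangles (allowed
#' grids: 1x2, 2x1, 2x2) and intersects each with the square's mask.  Cells
#' are numbered `(row, column)` from the top-left; for one-dimensional grids
#' the tag is a single index (`g1`, `g2`), for 2x2 it is `g{r}{c}`.
#'
#' @param square the [region()] returned by [central_square()].
#' @param grid integer pair `c(m, n)`; one of `c(1, 2)`, `c(2, 1)`, `c(2, 2)`.
#' @return list of [region()]s in row-major order.
#' @export
subdivide_grid <- function(square, grid = c(2L, 2L)) {
  stopifnot(inherits(square, "region"))
  grid <- as.integer(grid)
  allowed <- list(c(1L, 2L), c(2L, 1L), c(2L, 2L))
  if (!any(vapply(allowed, identical, logical(1), grid))) {
    abort_input("grid must be one of 1x2, 2x1, 2x2", "redeye_bad_config")
  }
  fp <- attr(square, "footprint")
  if (is.null(fp)) abort_input("square must come from central_square()",
                               "redeye_bad_config")
  m <- grid[1]
  n <- grid[2]
  side_r <- (fp$rows[2] - fp$rows[1] + 1L) %/% m
  side_c <- (fp$cols[2] - fp$cols[1] + 1L) %/% n
  cells <- list()
  for (r in seq_len(m)) {
    for (cc in seq_len(n)) {
      rr <- fp$rows[1] + (r - 1L) * side_r
      c0 <- fp$cols[1] + (cc - 1L) * side_c
      cell <- matrix(FALSE, nrow(square$mask), ncol(square$mask))
      cell[rr:(rr + side_r - 1L), c0:(c0 + side_c - 1L)] <- TRUE
      lab <- if (m == 1L || n == 1L) {
        sprintf("g%d", (r - 1L) * n + cc)
      } else {
        sprintf("g%d%d", r, cc)
      }
      cells[[lab]] <- region(cell & square$mask, lab)
    }
  }
  cells
}
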