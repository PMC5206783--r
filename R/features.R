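# The 24 hyperemia features.  Every feature is an accumulation over the
# pixels of one region; nm denotes the region pixel count, n_r the number of
# distinct image rows the region intersects, VE/VE-bar the vessel-edge
# partition of the region.  Conventions (applied uniformly):
#   * per-pixel chromaticity terms R/(R+G+B) contribute 0 for black pixels;
#   * ratio features over VE (F11, F12) return 0 when VE is empty;
#   * F3, F4 and F13 are raw sums with no nm normaliser — they scale with
#     region size by design and are rescaled downstream;
#   * H is the 0-255 hue wheel (red at 0/128-offset terms), a/b/L the 8-bit
#     offset L*a*b* planes, S/V the 0-255 HSV planes;
#   * mu_ij (F13) is the mean of H over the 3x3 neighbourhood of (i, j)
#     clipped to the region.

#' Registry of the 24 hyperemia features
#'
#' @return tibble with columns `index` (1..24), `name`, and `uses_partition`
#'   (whether the formula involves the vessel-edge partition).
#' @export
feature_registry <- function() {
  tibble::tibble(
    index = 1:24,
    name = c(
      "vessel count", "vessel occupied area", "relative vessel redness",
      "relative image redness", "difference red-green in vessels",
      "difference red-green of the image", "difference red-blue in vessels",
      "difference red-blue of the image", "red hue value",
      "percentage of vessels", "percentage of red (RGB)",
      "percentage of red (HSV)", "redness with neighbourhood",
      "Lab a-channel of the image", "Lab a-channel in vessels",
      "yellow in background (RGB)", "yellow in background (HSV)",
      "yellow in background (Lab)", "red in background (RGB)",
      "red in background (HSV)", "red in background (Lab)",
      "white in background (RGB)", "white in background (HSV)",
      "white in background (Lab)"
    ),
    uses_partition = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                       FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE,
                       TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  )
}

# Reduce a region to the per-class accumulations the 24 formulas need.
# Work is confined to the region's bounding box; every formula is linear in
# sums over the region ("tot") and over its vessel-edge pixels ("ve"), with
# background sums obtained as tot - ve, so only two passes over the pixels
# are needed.  mu (the 3x3 region-clipped neighbourhood mean of H, used by
# F13) is evaluated at vessel-edge pixels only.
region_pixel_data <- function(img, planes, part, reg) {
  m <- reg$mask
  if (!any(m)) abort_input("empty region", "redeye_bad_input")
  hh <- nrow(m)
  rr <- range(which(rowSums(m) > 0))
  cr <- range(which(colSums(m) > 0))
  hc <- rr[2] - rr[1] + 1L
  idx_c <- which(m[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE])
  rc <- ((idx_c - 1L) %% hc) + 1L
  cc <- ((idx_c - 1L) %/% hc) + 1L
  # full-image linear indices of the region pixels
  fidx <- (cr[1] - 1L + cc - 1L) * hh + (rr[1] - 1L + rc)
  ve_all <- part$ve[fidx]
  iv <- fidx[ve_all]
  Rr <- img[, , 1][fidx]
  Gr <- img[, , 2][fidx]
  Br <- img[, , 3][fidx]
  tot_rgb <- Rr + Gr + Br
  chroma <- numeric(length(fidx))
  nz <- tot_rgb > 0
  chroma[nz] <- Rr[nz] / tot_rgb[nz]
  Hr <- planes$H[fidx]
  # mu at vessel-edge pixels: 3x3 neighbour sums of H and of the mask,
  # clipped to the image bounds and to the region
  Hve <- planes$H[iv]
  mu_sum <- 0
  if (length(iv)) {
    rv <- ((iv - 1L) %% hh) + 1L
    cv <- ((iv - 1L) %/% hh) + 1L
    num <- numeric(length(iv))
    den <- numeric(length(iv))
    ww <- ncol(m)
    for (dr in -1:1) {
      for (dc in -1:1) {
        r2 <- rv + dr
        c2 <- cv + dc
        j <- (c2 - 1L) * hh + r2
        ok <- r2 >= 1L & r2 <= hh & c2 >= 1L & c2 <= ww
        j[!ok] <- 1L
        use <- ok & m[j]           # neighbour inside image and region
        sel <- which(use)
        num[sel] <- num[sel] + planes$H[j[sel]]
        den <- den + use
      }
    }
    mu_sum <- sum(Hve * num / den)
  }
  sums_at <- function(v, sel) sum(v[sel])
  d <- list(
    nm = length(fidx),
    nr = length(unique(rc)),
    n_ve = length(iv),
    mu_ve = mu_sum,
    tot = list(
      R = sum(Rr), G = sum(Gr), B = sum(Br), H = sum(Hr),
      S = sum(planes$S_hsv[fidx]), V = sum(planes$V[fidx]),
      a = sum(planes$a[fidx]), b = sum(planes$b[fidx]),
      L = sum(planes$L_lab[fidx]), chroma = sum(chroma)
    ),
    ve = list(
      R = sums_at(Rr, ve_all), G = sums_at(Gr, ve_all),
      B = sums_at(Br, ve_all), H = sum(Hve),
      S = sum(planes$S_hsv[iv]), V = sum(planes$V[iv]),
      a = sum(planes$a[iv]), b = sum(planes$b[iv]),
      L = sum(planes$L_lab[iv]), chroma = sums_at(chroma, ve_all)
    )
  )
  d
}

feature_value <- function(k, d) {
  nm <- d$nm
  n_ve <- d$n_ve
  n_bg <- nm - n_ve
  tot <- d$tot
  ve <- d$ve
  switch(k,
    n_ve / d$nr,                                            # F1  vessel count
    n_ve / nm,                                              # F2  vessel area
    ve$chroma,                                              # F3  raw sum
    tot$chroma,                                             # F4  raw sum
    (ve$R - ve$G) / nm,                                     # F5
    (tot$R - tot$G) / nm,                                   # F6
    (ve$R - ve$B) / nm,                                     # F7
    (tot$R - tot$B) / nm,                                   # F8
    (128 * nm - tot$H) / nm,                                # F9
    n_ve / nm * 100,                                        # F10 = 100 * F2
    if (n_ve == 0) 0 else ve$R / n_ve * 100,                # F11
    if (n_ve == 0) 0 else ve$H / n_ve * 100,                # F12
    d$mu_ve,                                                # F13 raw sum
    tot$a / nm,                                             # F14
    ve$a / nm,                                              # F15
    ((tot$R - ve$R) + (tot$G - ve$G)) / nm,                 # F16
    (240 * n_bg - (tot$H - ve$H)) / nm,                     # F17
    (tot$b - ve$b) / nm,                                    # F18
    (tot$R - ve$R) / nm,                                    # F19
    (128 * n_bg - (tot$H - ve$H)) / nm,                     # F20
    (tot$a - ve$a) / nm,                                    # F21
    ((tot$R - ve$R) + (tot$G - ve$G) + (tot$B - ve$B)) / nm,  # F22
    ((tot$V - ve$V) + (tot$S - ve$S)) / nm,                 # F23
    (tot$L - ve$L) / nm                                     # F24
  )
}

#' Compute one hyperemia feature on a region
#'
#' @param index feature index, 1..24 (see [feature_registry()]).
#' @param img RGB image array.
#' @param planes [color_planes()] of `img`.
#' @param part [detect_vessel_edges()] partition computed on `region`.
#' @param region a [region()].
#' @return scalar feature value.
#' @export
compute_feature <- function(index, img, planes, part, region) {
  if (!(index %in% 1:24)) abort_input("feature index must be 1..24",
                                      "redeye_bad_config")
  d <- region_pixel_data(img, planes, part, region)
  feature_value(index, d)
}

#' Compute all 24 features on a region
#'
#' @inheritParams compute_feature
#' @return named numeric vector `F1..F24`.
#' @export
compute_region_features <- function(img, planes, part, region) {
  d <- region_pixel_data(img, planes, part, region)
  stats::setNames(vapply(1:24, feature_value, numeric(1), d = d),
                  paste0("F", 1:24))
}

#' Assemble the full feature vector of an image
#'
#' Computes the 24 features on the whole conjunctiva (`o`), the central
#' 512-px square (`t`) and each grid cell, and concatenates them as
#' `F{k}_{region}` in canonical order (o block, t block, cells row-major).
#' For an `m x n` grid this yields `(m*n + 2) * 24` values.
#'
#' @param img RGB image array.
#' @param mask conjunctiva [region()] (label `o`).
#' @param grid integer pair, one of `c(1,2)`, `c(2,1)`, `c(2,2)`.
#' @param side central-square side in pixels (default 512).
#' @param sigma,hysteresis Canny configuration (see [canny_edges()]).
#' @param planes,edges optional precomputed planes/edge map for `img`.
#' @return named numeric vector of length `(prod(grid) + 2) * 24`.
#' @export
assemble_feature_vector <- function(img, mask, grid = c(2L, 2L), side = 512L,
                                    sigma = 1.4, hysteresis = NULL,
                                    planes = NULL, edges = NULL) {
  assemble_feature_vectors(img, mask, grids = list(grid), side = side,
                           sigma = sigma, hysteresis = hysteresis,
                           planes = planes, edges = edges)[[1]]
}

#' Assemble feature vectors for several grids at once
#'
#' Like [assemble_feature_vector()], but the whole-conjunctiva and
#' central-square blocks (shared by every grid) are computed once.
#'
#' @inheritParams assemble_feature_vector
#' @param grids list of grid pairs.
#' @return named list (names like `"2x2"`) of named numeric vectors.
#' @export
assemble_feature_vectors <- function(img, mask, grids = list(c(2L, 2L)),
                                     side = 512L, sigma = 1.4,
                                     hysteresis = NULL, planes = NULL,
                                     edges = NULL) {
  if (is.null(planes)) planes <- color_planes(img)
  if (is.null(edges)) edges <- canny_edges(img[, , 2], sigma, hysteresis)
  sq <- central_square(mask, side)
  region_block <- function(reg) {
    part <- detect_vessel_edges(img, reg, edges = edges)
    v <- compute_region_features(img, planes, part, reg)
    stats::setNames(v, paste0(names(v), "_", reg$label))
  }
  shared <- c(region_block(mask), region_block(sq))
  out <- lapply(grids, function(g) {
    cells <- subdivide_grid(sq, g)
    c(shared, unlist(unname(lapply(cells, region_block))))
  })
  names(out) <- vapply(grids, function(g) paste0(g[1], "x", g[2]), character(1))
  out
}

#' Fit a min-max feature normaliser
#'
#' Rescales every feature column to \[0, 1\] using the column ranges of the
#' fitting (training) table; constant columns map to 0.  The fitted ranges
#' are stored so held-out rows are rescaled with training-fold parameters.
#'
#' @param table data frame of feature columns (numeric).
#' @return object of class `feature_normalizer`.
#' @export
feature_normalizer <- function(table) {
  if (!nrow(table)) abort_input("cannot fit a normaliser on an empty table",
                                "redeye_bad_input")
  num <- vapply(table, is.numeric, logical(1))
  mins <- vapply(table[num], min, numeric(1))
  maxs <- vapply(table[num], max, numeric(1))
  structure(list(columns = names(table)[num], min = mins, max = maxs),
            class = "feature_normalizer")
}

#' Apply a fitted min-max normaliser
#'
#' @param object a [feature_normalizer()].
#' @param table data frame containing the fitted columns.
#' @param ... unused.
#' @return `table` with fitted columns affinely rescaled by the stored
#'   training ranges (training rows land in \[0, 1\]; held-out rows may fall
#'   outside; constant training columns map to 0).
#' @export
predict.feature_normalizer <- function(object, table, ...) {
  for (cn in object$columns) {
    rng <- object$max[[cn]] - object$min[[cn]]
    table[[cn]] <- if (rng == 0) {
      rep(0, nrow(table))
    } else {
      (table[[cn]] - object$min[[cn]]) / rng
    }
  }
  table
}

#' Min-max normalise a feature table
#'
#' Convenience wrapper: fits a [feature_normalizer()] on `table` and applies
#' it; the fitted normaliser is attached as attribute `"normalizer"`.
#'
#' @param table data frame of numeric feature columns (>= 2 rows).
#' @return normalised table.
#' @export
normalize_features <- function(table) {
  if (nrow(table) < 2L) {
    abort_input("normalisation needs at least 2 rows", "redeye_bad_input")
  }
  fit <- feature_normalizer(table)
  out <- predict(fit, table)
  attr(out, "normalizer") <- fit
  out
}
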