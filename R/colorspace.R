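# Colour-space conversions used by the threshold segmentations and the
# hyperemia features.  All planes are kept on a common 0-255 scale:
#
# * H is the HSV hue rescaled from [0, 360) degrees to [0, 255], so the
#   red-hue constant 128 and the yellow constant 240 used by the features
#   live on the same wheel; achromatic pixels have H = 0 by convention.
# * The TSL saturation S = sqrt(9/5 * (r'^2 + g'^2)) is 1 at pure red and is
#   multiplied by 255; black pixels (R+G+B = 0) have S = T = 0 by convention.
# * L*a*b* uses sRGB primaries with D65 white and is stored in the 8-bit
#   offset convention L = L* * 255/100, a = a* + 128, b = b* + 128, so the
#   neutral axis sits exactly at 128 and sums over a/b/L stay positive and
#   commensurate with RGB sums.

#' Validate an RGB image array
#'
#' An RGB image is a `height x width x 3` numeric array with values in
#' \[0, 255\] (8 bit per channel), `(row, column)` indexed from the top-left.
#'
#' @param img object to validate.
#' @return the image, invisibly, if valid; otherwise an error.
#' @export
validate_rgb_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    abort_input("an RGB image must be a height x width x 3 array",
                "redeye_invalid_image")
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 255) {
    abort_input("RGB values must lie in [0, 255]", "redeye_invalid_image")
  }
  invisible(img)
}

#' Convert an RGB image to HSV planes
#'
#' Standard HSV with hue rescaled from \[0, 360) degrees to \[0, 255\] and S, V
#' rescaled to \[0, 255\].  The hue of achromatic pixels (R = G = B) is 0.
#'
#' @param img RGB image array (see [validate_rgb_image()]).
#' @return list with matrices `H`, `S`, `V`, each in \[0, 255\].
#' @export
#' @examples
#' px <- array(c(0, 0, 255), dim = c(1, 1, 3))
#' rgb_to_hsv_planes(px)$H  # blue: 240/360 * 255 = 170
rgb_to_hsv_planes <- function(img) {
  validate_rgb_image(img)
  d <- dim(img)[1:2]
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  list(
    H = matrix(hsv[1, ] * 255, d[1], d[2]),
    S = matrix(hsv[2, ] * 255, d[1], d[2]),
    V = matrix(hsv[3, ] * 255, d[1], d[2])
  )
}

#' Convert an RGB image to TSL planes
#'
#' Tint-Saturation-Lightness.  With `r = R/(R+G+B)`, `g = G/(R+G+B)`,
#' `r' = r - 1/3`, `g' = g - 1/3`: `S = sqrt(9/5 (r'^2 + g'^2))` (1 at pure
#' red, rescaled to \[0, 255\]), `L = 0.299 R + 0.587 G + 0.114 B`, and T is
#' the arctangent tint mapped to \[0, 255\].  Black pixels have S = T = 0.
#'
#' @inheritParams rgb_to_hsv_planes
#' @return list with matrices `T`, `S`, `L`, each in \[0, 255\].
#' @export
rgb_to_tsl <- function(img) {
  validate_rgb_image(img)
  d <- dim(img)
  R <- matrix(img[, , 1], d[1], d[2])
  G <- matrix(img[, , 2], d[1], d[2])
  B <- matrix(img[, , 3], d[1], d[2])
  tot <- R + G + B
  nz <- tot > 0
  rp <- gp <- matrix(0, nrow(R), ncol(R))
  rp[nz] <- R[nz] / tot[nz] - 1 / 3
  gp[nz] <- G[nz] / tot[nz] - 1 / 3
  S <- sqrt(9 / 5 * (rp^2 + gp^2)) * 255
  Tn <- matrix(0, nrow(R), ncol(R))
  pos <- gp > 0
  neg <- gp < 0
  Tn[pos] <- atan(rp[pos] / gp[pos]) / (2 * pi) + 1 / 4
  Tn[neg] <- atan(rp[neg] / gp[neg]) / (2 * pi) + 3 / 4
  list(T = clamp(Tn, 0, 1) * 255, S = clamp(S, 0, 255),
       L = 0.299 * R + 0.587 * G + 0.114 * B)
}

#' Convert an RGB image to L*a*b* planes (8-bit offset encoding)
#'
#' CIE L*a*b* under sRGB primaries and D65 white, stored as
#' `L = L* * 255/100`, `a = a* + 128`, `b = b* + 128`, clamped to \[0, 255\].
#' Achromatic pixels map to a = b = 128 exactly.
#'
#' @inheritParams rgb_to_hsv_planes
#' @return list with matrices `L`, `a`, `b`, each in \[0, 255\].
#' @export
rgb_to_lab <- function(img) {
  validate_rgb_image(img)
  d <- dim(img)[1:2]
  # sRGB linearisation via a 256-entry lookup (8-bit inputs), then the
  # standard sRGB/D65 XYZ matrix; the reference white is taken as the matrix
  # row sums so achromatic pixels land on a* = b* = 0 exactly.
  lin <- srgb_linear_lut()
  is_int <- all(img == floor(img))
  linearize <- function(ch) {
    if (is_int) lin[ch + 1L] else {
      v <- ch / 255
      ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
    }
  }
  r <- linearize(img[, , 1])
  g <- linearize(img[, , 2])
  b <- linearize(img[, , 3])
  M <- srgb_xyz_matrix()
  white <- rowSums(M)
  fx <- lab_f((M[1, 1] * r + M[1, 2] * g + M[1, 3] * b) / white[1])
  fy <- lab_f((M[2, 1] * r + M[2, 2] * g + M[2, 3] * b) / white[2])
  fz <- lab_f((M[3, 1] * r + M[3, 2] * g + M[3, 3] * b) / white[3])
  Ls <- 116 * fy - 16
  as <- 500 * (fx - fy)
  bs <- 200 * (fy - fz)
  list(
    L = matrix(clamp(Ls * 255 / 100, 0, 255), d[1], d[2]),
    a = matrix(clamp(as + 128, 0, 255), d[1], d[2]),
    b = matrix(clamp(bs + 128, 0, 255), d[1], d[2])
  )
}

srgb_xyz_matrix <- function() {
  matrix(c(0.4124564, 0.3575761, 0.1804375,
           0.2126729, 0.7151522, 0.0721750,
           0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
}

srgb_linear_lut <- local({
  lut <- NULL
  function() {
    if (is.null(lut)) {
      v <- (0:255) / 255
      lut <<- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
    }
    lut
  }
})

lab_f <- function(t) {
  eps <- 216 / 24389
  kappa <- 24389 / 27
  out <- (kappa * t + 16) / 116
  big <- t > eps
  out[big] <- t[big]^(1 / 3)
  out
}

#' Compute every colour plane used by the pipeline
#'
#' @inheritParams rgb_to_hsv_planes
#' @return object of class `color_planes`: a list with matrices `H`, `S_hsv`,
#'   `V`, `T`, `S_tsl`, `L_tsl`, `L_lab`, `a`, `b`, all in \[0, 255\].
#' @export
color_planes <- function(img) {
  hsv <- rgb_to_hsv_planes(img)
  tsl <- rgb_to_tsl(img)
  lab <- rgb_to_lab(img)
  structure(
    list(H = hsv$H, S_hsv = hsv$S, V = hsv$V,
         T = tsl$T, S_tsl = tsl$S, L_tsl = tsl$L,
         L_lab = lab$L, a = lab$a, b = lab$b),
    class = "color_planes"
  )
}
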