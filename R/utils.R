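# Internal helpers shared across the package.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never perturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Shift a matrix by (dr, dc) with replicate (edge-clamped) padding
#'
#' `mat_shift(m, dr, dc)[i, j] == m[clamp(i + dr), clamp(j + dc)]`.
#' @noRd
mat_shift <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  m[clamp(seq_len(nr) + dr, 1L, nr), clamp(seq_len(nc) + dc, 1L, nc), drop = FALSE]
}

#' Separable convolution with replicate padding
#' @noRd
sep_conv <- function(m, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  offs <- seq(-r, r)
  out <- matrix(0, nrow(m), ncol(m))
  for (k in seq_along(offs)) out <- out + kernel[k] * mat_shift(m, offs[k], 0L)
  m2 <- out
  out <- matrix(0, nrow(m), ncol(m))
  for (k in seq_along(offs)) out <- out + kernel[k] * mat_shift(m2, 0L, offs[k])
  out
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

abort_input <- function(msg, class) {
  rlang::abort(msg, class = c(class, "redeye_error"))
}
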