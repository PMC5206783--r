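# Independent brute-force oracles and small fixture builders.  The feature
# oracle is a literal per-pixel double loop over the printed accumulation
# formulas; it shares only the colour planes (whose conversions are tested
# separately against grDevices) with the implementation under test.

naive_feature_oracle <- function(img, planes, E, M) {
  h <- nrow(M)
  w <- ncol(M)
  nm <- sum(M)
  nr <- sum(apply(M, 1, any))
  acc <- numeric(24)
  sum_ve <- 0
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (!M[i, j]) next
      R <- img[i, j, 1]; G <- img[i, j, 2]; B <- img[i, j, 3]
      H <- planes$H[i, j]; S <- planes$S_hsv[i, j]; V <- planes$V[i, j]
      a <- planes$a[i, j]; b <- planes$b[i, j]; L <- planes$L_lab[i, j]
      ve <- E[i, j]
      veb <- !ve
      tot <- R + G + B
      chroma <- if (tot > 0) R / tot else 0
      if (ve) {
        sum_ve <- sum_ve + 1
        # mu: mean of H over the 3x3 neighbourhood clipped to the region
        s <- 0; n <- 0
        for (di in -1:1) for (dj in -1:1) {
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && M[ii, jj]) {
            s <- s + planes$H[ii, jj]; n <- n + 1
          }
        }
        acc[13] <- acc[13] + H * (s / n)
      }
      acc[1] <- acc[1] + (E[i, j] * M[i, j])
      acc[3] <- acc[3] + chroma * ve
      acc[4] <- acc[4] + chroma
      acc[5] <- acc[5] + (R - G) * ve
      acc[6] <- acc[6] + (R - G)
      acc[7] <- acc[7] + (R - B) * ve
      acc[8] <- acc[8] + (R - B)
      acc[9] <- acc[9] + (128 - H)
      acc[11] <- acc[11] + R * ve
      acc[12] <- acc[12] + H * ve
      acc[14] <- acc[14] + a
      acc[15] <- acc[15] + a * ve
      acc[16] <- acc[16] + (R + G) * veb
      acc[17] <- acc[17] + (240 - H) * veb
      acc[18] <- acc[18] + b * veb
      acc[19] <- acc[19] + R * veb
      acc[20] <- acc[20] + (128 - H) * veb
      acc[21] <- acc[21] + a * veb
      acc[22] <- acc[22] + (R + G + B) * veb
      acc[23] <- acc[23] + (V + S) * veb
      acc[24] <- acc[24] + L * veb
    }
  }
  out <- numeric(24)
  out[1] <- acc[1] / nr
  out[2] <- sum_ve / nm
  out[3] <- acc[3]
  out[4] <- acc[4]
  for (k in 5:9) out[k] <- acc[k] / nm
  out[10] <- sum_ve / nm * 100
  out[11] <- if (sum_ve == 0) 0 else acc[11] / sum_ve * 100
  out[12] <- if (sum_ve == 0) 0 else acc[12] / sum_ve * 100
  out[13] <- acc[13]
  for (k in 14:24) out[k] <- acc[k] / nm
  stats::setNames(out, paste0("F", 1:24))
}

# scalar even-odd point-in-polygon (crossing number, ray in +x direction)
naive_point_in_polygon <- function(vertices, y, x) {
  n <- nrow(vertices)
  inside <- FALSE
  for (e in seq_len(n)) {
    y1 <- vertices[e, 1]; x1 <- vertices[e, 2]
    f <- if (e == n) 1L else e + 1L
    y2 <- vertices[f, 1]; x2 <- vertices[f, 2]
    if ((y1 > y) != (y2 > y)) {
      xint <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
      if (x < xint) inside <- !inside
    }
  }
  inside
}

random_rgb_image <- function(h, w, seed) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

# random region/edge fixture on a small image; region guaranteed nonempty
random_feature_fixture <- function(seed, h = 24L, w = 24L) {
  img <- random_rgb_image(h, w, seed)
  set.seed(seed + 1000)
  M <- matrix(runif(h * w) > 0.4, h, w)
  if (!any(M)) M[1, 1] <- TRUE
  E <- matrix(runif(h * w) > 0.6, h, w)
  part <- structure(list(E = E, ve = E & M, ve_bar = M & !E),
                    class = "vessel_partition")
  list(img = img, planes = color_planes(img), M = M, E = E, part = part,
       region = region(M, "o"))
}

# small graded table with planted informative features
planted_feature_table <- function(seed, n = 100L, p = 24L, informative = 1:3,
                                  noise_sd = 0.3) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  y <- pmin(pmax(rowMeans(X[, informative, drop = FALSE]) * 4 +
                   rnorm(n, sd = noise_sd), 0), 4)
  list(X = as.data.frame(X), y = y,
       informative = paste0("f", informative))
}
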