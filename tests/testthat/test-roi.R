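test_that("a rectangle polygon covers exactly its pixel centres", {
  r <- polygon_to_mask(rbind(c(0, 0), c(0, 20), c(10, 20), c(10, 0)),
                       c(32, 32))
  expect_equal(pixel_count(r), 200L)
  expect_true(all(which(r$mask, arr.ind = TRUE)[, 1] <= 10))
})

test_that("polygon rasterisation matches a per-pixel even-odd oracle", {
  set.seed(3)
  for (rep in 1:8) {
    v <- cbind(runif(3, 0, 20), runif(3, 0, 20))  # triangles are simple
    got <- polygon_to_mask(v, c(20, 20))$mask
    want <- matrix(FALSE, 20, 20)
    for (i in 1:20) for (j in 1:20) {
      want[i, j] <- naive_point_in_polygon(v, i - 0.5, j - 0.5)
    }
    expect_identical(got, want)
  }
})

test_that("degenerate or out-of-bounds annotations are rejected", {
  expect_error(polygon_to_mask(rbind(c(0, 0), c(5, 5)), c(10, 10)),
               class = "redeye_invalid_annotation")
  expect_error(polygon_to_mask(rbind(c(0, 0), c(0, 12), c(5, 5)), c(10, 10)),
               class = "redeye_invalid_annotation")
})

test_that("orientation normalisation is a conditional involution", {
  img <- random_rgb_image(8, 10, seed = 5)
  mask <- region(matrix(runif(80) > 0.5, 8, 10))
  same <- orient_image(img, mask, pupil_side = "left", canonical = "left")
  expect_identical(same$img, img)
  expect_identical(same$mask$mask, mask$mask)
  flip <- orient_image(img, mask, pupil_side = "right", canonical = "left")
  expect_false(identical(flip$img, img))
  expect_equal(pixel_count(flip$mask), pixel_count(mask))
  back <- orient_image(flip$img, flip$mask, pupil_side = "right",
                       canonical = "left")
  expect_identical(back$img, img)
  expect_identical(back$mask$mask, mask$mask)
})

test_that("central square is centred on the mask centroid and intersected", {
  full <- region(matrix(TRUE, 1600, 1200))
  sq <- central_square(full, side = 512L)
  expect_equal(pixel_count(sq), 512L * 512L)
  fp <- attr(sq, "footprint")
  expect_equal(mean(fp$rows), 800.5, tolerance = 1)
  # a hole inside the square stays excluded
  holed <- matrix(TRUE, 1600, 1200)
  holed[790:809, 590:609] <- FALSE
  sq2 <- central_square(region(holed), side = 512L)
  expect_equal(pixel_count(sq2), 512L * 512L - 400L)
})

test_that("too-small conjunctivas are rejected with the discard error", {
  small <- matrix(FALSE, 1600, 1200)
  small[1:300, 1:900] <- TRUE  # bounding box 300 x 900
  expect_error(central_square(region(small), 512L),
               class = "redeye_too_small_conjunctiva")
  edge <- matrix(FALSE, 600, 600)
  edge[1:512, 1:512] <- TRUE   # bbox fits but the centred square overflows
  expect_error(central_square(region(edge), 512L),
               class = "redeye_too_small_conjunctiva")
})

test_that("grids partition the square and use the printed cell tags", {
  full <- region(matrix(TRUE, 700, 700))
  sq <- central_square(full, side = 512L)
  g22 <- subdivide_grid(sq, c(2, 2))
  expect_named(g22, c("g11", "g12", "g21", "g22"))
  expect_true(all(vapply(g22, pixel_count, numeric(1)) == 256L * 256L))
  g12 <- subdivide_grid(sq, c(1, 2))
  expect_named(g12, c("g1", "g2"))
  expect_equal(pixel_count(g12$g1), 512L * 256L)
  # conservation and disjointness
  total <- Reduce(`+`, lapply(g22, function(r) r$mask + 0L))
  expect_true(all(total <= 1L))
  expect_equal(sum(total), pixel_count(sq))
  # nestedness g <= t <= o
  for (cell in g22) expect_true(all(!cell$mask | sq$mask))
  expect_true(all(!sq$mask | full$mask))
  expect_error(subdivide_grid(sq, c(3, 3)), class = "redeye_bad_config")
})

test_that("central square commutes with lateral mirroring (generic mask)", {
  set.seed(9)
  m <- matrix(FALSE, 700, 800)
  m[80:640, 100:720] <- TRUE
  m[sample(length(m), 4000)] <- TRUE
  mask <- region(m)
  # an even-sided square centred on an integer-rounded centroid can only
  # mirror up to a one-pixel lateral shift (256 left / 255 right of centre);
  # the placements must agree to within that shift and the regions must
  # coincide after aligning
  a <- central_square(region(m[, ncol(m):1]), 512L)
  b <- central_square(mask, 512L)
  fa <- attr(a, "footprint")
  fb <- attr(b, "footprint")
  mirrored_cols <- ncol(m) + 1 - rev(fb$cols)
  expect_identical(fa$rows, fb$rows)
  expect_lte(max(abs(fa$cols - mirrored_cols)), 1L)
  bm <- b$mask[, ncol(m):1]
  common <- max(fa$cols[1], mirrored_cols[1]):min(fa$cols[2], mirrored_cols[2])
  expect_identical(a$mask[, common], bm[, common])
})
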