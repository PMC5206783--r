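test_that("vessel-edge partition splits a region exactly", {
  flat <- array(120, dim = c(40, 40, 3))
  reg <- region(matrix(TRUE, 40, 40))
  part <- detect_vessel_edges(flat, reg)
  expect_equal(sum(part$ve), 0)            # no gradients, no edges
  expect_identical(part$ve_bar, reg$mask)
  set.seed(8)
  img <- random_rgb_image(30, 30, seed = 8)
  m <- matrix(runif(900) > 0.5, 30, 30)
  p2 <- detect_vessel_edges(img, region(m))
  expect_equal(sum(p2$ve) + sum(p2$ve_bar), sum(m))
  expect_false(any(p2$ve & p2$ve_bar))
  expect_error(detect_vessel_edges(img, region(matrix(FALSE, 30, 30))),
               class = "redeye_bad_input")
})

test_that("a dark line yields edges confined to a band around it", {
  img <- array(200, dim = c(64, 64, 3))
  img[, 30:32, ] <- 50
  part <- detect_vessel_edges(img, region(matrix(TRUE, 64, 64)), sigma = 1.4)
  cols <- which(part$ve, arr.ind = TRUE)[, 2]
  expect_gt(length(cols), 0)
  band <- 2 * 1.4 + 1
  expect_true(all(cols >= 30 - band & cols <= 32 + band))
})

test_that("every feature matches the brute-force pixel-loop oracle", {
  for (seed in 1:50) {
    fx <- random_feature_fixture(seed)
    got <- compute_region_features(fx$img, fx$planes, fx$part, fx$region)
    want <- naive_feature_oracle(fx$img, fx$planes, fx$E, fx$M)
    for (k in 1:24) {
      denom <- max(abs(want[k]), 1)
      expect_lt(abs(got[k] - want[k]) / denom, 1e-9,
                label = sprintf("seed %d F%d rel err", seed, k))
    }
  }
})

test_that("single-feature access agrees with the block computation", {
  fx <- random_feature_fixture(99)
  all24 <- compute_region_features(fx$img, fx$planes, fx$part, fx$region)
  for (k in c(1, 4, 10, 13, 23)) {
    expect_equal(compute_feature(k, fx$img, fx$planes, fx$part, fx$region),
                 unname(all24[k]))
  }
  expect_error(compute_feature(25, fx$img, fx$planes, fx$part, fx$region),
               class = "redeye_bad_config")
})

test_that("constant-white region evaluates to the closed-form values", {
  img <- array(255, dim = c(16, 16, 3))
  reg <- region(matrix(TRUE, 16, 16))
  planes <- color_planes(img)
  part <- detect_vessel_edges(img, reg)   # constant: VE empty
  f <- compute_region_features(img, planes, part, reg)
  nm <- 256
  expect_equal(unname(f["F2"]), 0)
  expect_equal(unname(f["F10"]), 0)
  expect_equal(unname(f["F11"]), 0)
  expect_equal(unname(f["F4"]), nm / 3, tolerance = 1e-9)
  expect_equal(unname(f["F22"]), 765)
  expect_equal(unname(f["F14"]), 128, tolerance = 1e-9)
  expect_equal(unname(f["F9"]), 128)     # H = 0 convention for achromatic
  expect_equal(unname(f["F10"]), unname(100 * f["F2"]))
})

test_that("feature vectors have the printed layout and naming", {
  set.seed(21)
  img <- random_rgb_image(140, 140, seed = 21)
  mask <- region(matrix(TRUE, 140, 140))
  v22 <- assemble_feature_vector(img, mask, grid = c(2, 2), side = 64L)
  expect_length(v22, (2 * 2 + 2) * 24)
  expect_true(all(c("F1_o", "F24_t", "F23_g21", "F13_g12") %in% names(v22)))
  v12 <- assemble_feature_vector(img, mask, grid = c(1, 2), side = 64L)
  expect_length(v12, (1 * 2 + 2) * 24)
  expect_true(all(c("F2_g1", "F2_g2") %in% names(v12)))
  expect_false(any(duplicated(names(v22))))
  # o and t blocks lead, in feature order
  expect_equal(names(v22)[1:3], c("F1_o", "F2_o", "F3_o"))
  expect_equal(names(v22)[25], "F1_t")
  # the multi-grid path equals per-grid assembly
  multi <- assemble_feature_vectors(img, mask, grids = list(c(2, 2), c(1, 2)),
                                    side = 64L)
  expect_identical(multi[["2x2"]], v22)
  expect_identical(multi[["1x2"]], v12)
})

test_that("features are invariant under lateral mirroring of any region", {
  # features are sums over (pixel value, partition class) multisets, so
  # mirroring image, mask and edge set together must leave every value
  # unchanged, region by region (o, t and each grid cell)
  sc <- generate_scene(scene_params(width = 320L, height = 240L, grade = 3,
                                    eyelid_coverage = 0.05, seed = 14))
  img <- sc$image
  w <- ncol(img)
  planes <- color_planes(img)
  edges <- canny_edges(img[, , 2])
  img_m <- img[, w:1, , drop = FALSE]
  planes_m <- structure(lapply(planes, function(p) p[, w:1]),
                        class = "color_planes")
  edges_m <- edges[, w:1]
  sq <- central_square(sc$conjunctiva_mask, 128L)
  regions <- c(list(o = sc$conjunctiva_mask, t = sq),
               subdivide_grid(sq, c(2, 2)))
  for (reg in regions) {
    part <- detect_vessel_edges(img, reg, edges = edges)
    v <- compute_region_features(img, planes, part, reg)
    reg_m <- region(reg$mask[, w:1], reg$label)
    part_m <- detect_vessel_edges(img_m, reg_m, edges = edges_m)
    v_m <- compute_region_features(img_m, planes_m, part_m, reg_m)
    expect_equal(v_m, v, tolerance = 1e-12, label = reg$label)
  }
})

test_that("min-max normalisation is affine, stored, and reusable", {
  tab <- tibble::tibble(a = c(2, 4, 6), b = c(5, 5, 5), c = c(0, 1, 3))
  norm <- normalize_features(tab)
  expect_equal(norm$a, c(0, 0.5, 1))
  expect_equal(norm$b, c(0, 0, 0))      # constant column convention
  fit <- attr(norm, "normalizer")
  expect_equal(predict(fit, tab), tibble::as_tibble(norm)[names(tab)],
               ignore_attr = TRUE)
  held_out <- tibble::tibble(a = c(3, 10), b = c(7, 7), c = c(1.5, -2))
  out <- predict(fit, held_out)
  expect_equal(out$a, c(0.25, 2))       # affine: held-out rows may exceed 1
  expect_equal(out$c, c(0.5, -2 / 3))
  expect_error(normalize_features(tab[0, ]), class = "redeye_bad_input")
})
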