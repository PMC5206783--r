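# Synthetic ocular-surface scenes with ground truth.  A scene emulates the
# ingredients a slit-lamp photograph contributes to hyperemia grading: a
# near-white sclera under a smooth illumination gradient, curvilinear red
# vessels whose count and diffuse redness grow with the grade, a dark iris
# on one lateral side, eyelid occluders above and below, and sensor noise.
# Everything is driven by one seed, so a scene is bit-exact reproducible,
# and the true conjunctiva and vessel masks are recorded as ground truth.

#' Parameters of a synthetic scene
#'
#' Defaults mirror the acquisition conditions of clinical grading sets:
#' 1600 x 1200 px frames, a warm near-white sclera, +/-15 % illumination
#' drift across the field, a handful of visible vessels in a white eye
#' growing to dozens in severe hyperemia, and mild sensor noise.
#'
#' @param width,height image size in pixels.
#' @param grade true hyperemia grade in \[0, 4\].
#' @param vessel_count_base vessels at grade 0; the count is
#'   `vessel_count_base * (1 + grade)`.
#' @param vessel_width vessel diameter in pixels.
#' @param tortuosity angular noise (radians, per walk step) of vessel paths.
#' @param sclera_rgb base sclera colour (8-bit RGB triple).
#' @param illumination_gradient relative amplitude of the multiplicative
#'   illumination ramp (0.15 = +/-15 %).
#' @param iris_side `"left"` or `"right"`: lateral side holding the iris
#'   (the pupil side of the image).
#' @param eyelid_coverage fraction of the image height each eyelid occludes.
#' @param noise_sd Gaussian sensor noise, 8-bit intensity units.
#' @param seed integer seed fixing the scene bit-exactly.
#' @return list of class `scene_params`.
#' @export
scene_params <- function(width = 1600L, height = 1200L, grade = 2,
                         vessel_count_base = 8L, vessel_width = 3L,
                         tortuosity = 0.25, sclera_rgb = c(238, 232, 226),
                         illumination_gradient = 0.15,
                         iris_side = "left", eyelid_coverage = 0.12,
                         noise_sd = 4, seed = 1L) {
  stopifnot(width >= 1, height >= 1, grade >= 0, grade <= 4,
            vessel_count_base > 0, vessel_width >= 1, noise_sd >= 0,
            eyelid_coverage >= 0, eyelid_coverage < 0.5)
  iris_side <- match.arg(iris_side, c("left", "right"))
  structure(as.list(environment()), class = "scene_params")
}

#' Generate a synthetic conjunctiva scene
#'
#' @param params a [scene_params()].
#' @return object of class `synthetic_scene`: list with `image` (RGB array),
#'   `conjunctiva_mask` ([region()]), `vessel_mask` (logical matrix, a
#'   subset of the conjunctiva), `true_grade`, and `params`.
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, generate_scene_impl(params))
}

# Scene geometry (palpebral fissure, iris, conjunctiva) is a deterministic
# function of the parameters — no RNG — so masks and polygon ROIs can be
# derived without rendering any pixels.
scene_geometry <- function(p) {
  h <- p$height
  w <- p$width
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  # palpebral fissure: ellipse between the two lids (centred on the pixel
  # grid's symmetry point so left/right scenes mirror exactly)
  ey <- (h + 1) / 2
  ex <- (w + 1) / 2
  ar <- h * (0.5 - p$eyelid_coverage)
  ac <- w * 0.48
  opening <- ((rows - ey) / ar)^2 + ((cols - ex) / ac)^2 <= 1
  # iris: dark disc on the pupil side, partly inside the opening
  icx <- if (p$iris_side == "left") w * 0.06 else w + 1 - w * 0.06
  irad <- h * 0.30
  iris <- (rows - ey)^2 + (cols - icx)^2 <= irad^2
  list(rows = rows, cols = cols, opening = opening, iris = iris,
       conj = opening & !iris)
}

generate_scene_impl <- function(p) {
  h <- p$height
  w <- p$width
  g4 <- p$grade / 4
  geo <- scene_geometry(p)
  rows <- geo$rows
  cols <- geo$cols
  opening <- geo$opening
  iris <- geo$iris
  conj <- geo$conj

  # base colouring
  skin <- c(172, 124, 108)
  iris_rgb <- c(70, 48, 36)
  base <- p$sclera_rgb + stats::rnorm(3, sd = 3)
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    pl <- matrix(skin[ch], h, w)
    pl[opening] <- base[ch]
    pl[iris & opening] <- iris_rgb[ch]
    img[, , ch] <- pl
  }

  # diffuse hyperemia: conjunctiva shifts toward red with grade
  shift <- c(36, -22, -14) * g4
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[conj] <- pl[conj] + shift[ch]
    img[, , ch] <- pl
  }

  # vessels: seeded random-walk polylines dilated to vessel_width
  n_vessel <- round(p$vessel_count_base * (1 + p$grade))
  conj_idx <- which(conj)
  vessel <- matrix(FALSE, h, w)
  if (length(conj_idx) && n_vessel > 0) {
    off <- floor(p$vessel_width / 2)
    offs <- expand.grid(dr = -off:off, dc = -off:off)
    for (v in seq_len(n_vessel)) {
      start <- conj_idx[sample.int(length(conj_idx), 1L)]
      r0 <- ((start - 1L) %% h) + 1L
      c0 <- ((start - 1L) %/% h) + 1L
      n_steps <- sample(100:300, 1L)
      theta <- stats::runif(1, 0, 2 * pi) +
        cumsum(stats::rnorm(n_steps, sd = p$tortuosity))
      rr <- round(r0 + cumsum(1.5 * sin(theta)))
      cc <- round(c0 + cumsum(1.5 * cos(theta)))
      for (k in seq_len(nrow(offs))) {
        ri <- rr + offs$dr[k]
        ci <- cc + offs$dc[k]
        ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
        vessel[cbind(ri[ok], ci[ok])] <- TRUE
      }
    }
    vessel <- vessel & conj
  }
  vrgb <- c(150, 30, 35)
  alpha <- 0.8
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[vessel] <- (1 - alpha) * pl[vessel] + alpha * vrgb[ch]
    img[, , ch] <- pl
  }

  # multiplicative illumination ramp in a random direction
  phi <- stats::runif(1, 0, 2 * pi)
  proj <- (cos(phi) * (cols / w - 0.5) + sin(phi) * (rows / h - 0.5)) + 0.5
  field <- 1 + p$illumination_gradient * (2 * proj - 1)
  for (ch in 1:3) img[, , ch] <- img[, , ch] * field

  # sensor noise, clip, quantise
  img <- img + array(stats::rnorm(h * w * 3, sd = p$noise_sd), dim = dim(img))
  img <- round(clamp(img, 0, 255))

  structure(list(image = img, conjunctiva_mask = region(conj, "o"),
                 vessel_mask = vessel, true_grade = p$grade, params = p),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d, grade %.2f, %d conjunctiva px, %d vessel px\n",
              nrow(x$image), ncol(x$image), x$true_grade,
              pixel_count(x$conjunctiva_mask), sum(x$vessel_mask)))
  invisible(x)
}

#' Simulate two expert graders
#'
#' Each grader reports the true grade plus independent Gaussian noise,
#' clipped to \[0, 4\] and rounded to one decimal (graders score with
#' decimal precision).
#'
#' @param true_grade true grade in \[0, 4\].
#' @param noise_sd grader noise standard deviation in grade points.
#' @param seed optional seed.
#' @return numeric vector `c(grade1, grade2)`.
#' @export
simulate_expert_grades <- function(true_grade, noise_sd = 0.35, seed = NULL) {
  stopifnot(true_grade >= 0, true_grade <= 4)
  draw <- function() {
    round(clamp(true_grade + stats::rnorm(2, sd = noise_sd), 0, 4), 1)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Convex hull of the conjunctiva mask as a polygon annotation in the 0-based
# (row, col) pixel-centre frame.
mask_hull_polygon <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  pts <- cbind(idx[, 1] - 0.5, idx[, 2] - 0.5)
  hull <- grDevices::chull(pts[, 2], pts[, 1])
  pts[hull, , drop = FALSE]
}

#' Generate a synthetic graded dataset
#'
#' Produces `n` scenes with true grades drawn from `grade_dist`, simulated
#' expert grades, polygon ROIs (convex hull of the conjunctiva mask) and
#' pupil-side metadata — a drop-in replacement for a clinical grading set.
#' With `dir` set, writes the images (PNG), ground-truth masks (PNG), ROI
#' annotations (JSON) and the grading CSV to disk.
#'
#' @param n number of scenes.
#' @param seed master seed; every scene and grader draw derives from it.
#' @param grade_dist function `n -> n true grades in [0, 4]` (default
#'   uniform).
#' @param noise_sd grader noise (see [simulate_expert_grades()]).
#' @param width,height scene size in pixels.
#' @param dir optional output directory.
#' @param ... further arguments passed to [scene_params()].
#' @return tibble of class `redeye_dataset` with columns `image_id`,
#'   `params` (list of [scene_params()]; pixels are rendered lazily, one
#'   scene at a time, by [dataset_scene()]), `roi` (list of polygon vertex
#'   matrices), `pupil_side`, `grade1`, `grade2`, `true_grade`.
#' @export
generate_dataset <- function(n, seed = 1L, grade_dist = NULL, noise_sd = 0.35,
                             width = 1600L, height = 1200L, dir = NULL, ...) {
  stopifnot(n >= 1)
  grade_dist <- grade_dist %||% function(k) stats::runif(k, 0, 4)
  meta <- with_seed(seed, list(
    grades = grade_dist(n),
    sides = sample(c("left", "right"), n, replace = TRUE)
  ))
  rows <- purrr::map(seq_len(n), function(i) {
    sp <- scene_params(width = width, height = height, grade = meta$grades[i],
                       iris_side = meta$sides[i], seed = seed + i * 101L, ...)
    conj <- scene_geometry(sp)$conj
    gr <- simulate_expert_grades(sp$grade, noise_sd,
                                 seed = seed + i * 101L + 50L)
    tibble::tibble(
      image_id = sprintf("img%03d", i),
      params = list(sp),
      roi = list(mask_hull_polygon(conj)),
      pupil_side = meta$sides[i],
      grade1 = gr[1], grade2 = gr[2],
      true_grade = sp$grade
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("redeye_dataset", class(out))
  if (!is.null(dir)) write_dataset(out, dir)
  out
}

#' Materialise one scene of a dataset
#'
#' Datasets built by [generate_dataset()] carry scene parameters, not
#' pixels; this renders scene `i` (bit-exact, from its stored seed).
#' Datasets loaded from disk ([load_dataset()]) carry images directly and
#' are returned as stored.
#'
#' @param dataset a `redeye_dataset` tibble.
#' @param i row index.
#' @return a `synthetic_scene`.
#' @export
dataset_scene <- function(dataset, i) {
  if (!is.null(dataset[["scene"]]) && !is.null(dataset$scene[[i]])) {
    return(dataset$scene[[i]])
  }
  generate_scene(dataset$params[[i]])
}

#' Write a synthetic dataset to disk
#'
#' @param dataset a [generate_dataset()] tibble.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(dataset))) {
    id <- dataset$image_id[i]
    sc <- dataset_scene(dataset, i)
    png::writePNG(aperm(sc$image, c(1, 2, 3)) / 255,
                  file.path(dir, paste0(id, ".png")))
    png::writePNG(sc$conjunctiva_mask$mask * 1,
                  file.path(dir, paste0(id, "_mask.png")))
    jsonlite::write_json(
      list(image = id,
           vertices = unname(apply(dataset$roi[[i]], 1, as.numeric,
                                   simplify = FALSE)),
           pupil_side = dataset$pupil_side[i]),
      file.path(dir, paste0(id, "_roi.json")),
      auto_unbox = TRUE, digits = NA)
  }
  readr::write_csv(
    dplyr::select(tibble::as_tibble(dataset), "image_id", "grade1", "grade2",
                  "pupil_side"),
    file.path(dir, "grading.csv"))
  invisible(dir)
}

#' Default synthetic validation suite
#'
#' The packaged study conditions for offline validation: 1024 x 768 scenes
#' (the 512-px central-square geometry of full-size frames is preserved at a
#' tractable pixel budget), uniform grades on \[0, 4\], grader noise 0.35.
#'
#' @param n number of scenes (default 50).
#' @param seed master seed.
#' @param ... overrides passed to [generate_dataset()].
#' @return a `redeye_dataset` tibble.
#' @export
default_suite <- function(n = 50L, seed = 1L, ...) {
  generate_dataset(n, seed = seed, width = 1024L, height = 768L, ...)
}
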