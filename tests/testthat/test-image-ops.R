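test_that("central ROI mean matches its window contract", {
  # panel slice with the clinical 0.4 mm pitch: 1 cm ROI = 25 pixels
  det <- detector_spec(101, 101, 0.4, 4.04)
  w <- round(1 * 10 / det$pixel_pitch_mm)
  expect_equal(w, 25)
  img <- epid_image(matrix(100, 101, 101), detector = det)
  expect_equal(central_roi_mean(img), 100)
  # image linear in x, symmetric grid: mean equals the center value
  x <- seq_len(101)
  lin <- epid_image(outer(rep(1, 101), x), detector = det)
  expect_equal(central_roi_mean(lin), lin$grid[51, 51])
  # marker in the exact default window
  g <- matrix(0, 101, 101)
  g[39:63, 39:63] <- 7
  expect_equal(central_roi_mean(epid_image(g, detector = det)), 7)
  expect_error(central_roi_mean(img, roi_side_cm = 100), "larger")
  expect_error(central_roi_mean(img, roi_side_cm = -1), "positive")
})

test_that("ROI window parity rule shifts half a pixel toward the origin", {
  det <- detector_spec(6, 6, 64, 38.4)   # even grid, w even
  g <- matrix(0, 6, 6); g[3:4, 3:4] <- 1 # roi 1 cm -> round(10/64)=0 -> w=1?
  # w = max(1, round(10/64)) = 1: single pixel at floor((6-1)/2)+1 = 3
  expect_equal(central_roi_mean(epid_image(g, detector = det)), 1)
})

test_that("Otsu threshold separates a bimodal histogram", {
  set.seed(7)
  v <- c(stats::runif(600, 0, 0.2), stats::runif(400, 0.7, 1))
  thr <- otsu_threshold(v)
  expect_gt(thr, 0.2)
  expect_lt(thr, 0.7)
  expect_error(otsu_threshold(rep(3, 100)), "dynamic range")
})

test_that("Otsu segmentation agrees with the EBImage implementation", {
  nf <- noise_free_setup(128L)
  img <- simulate_epid_image(nf$sys, 10, NULL)
  thr <- otsu_threshold(img$grid)
  rng <- range(img$grid)
  thr_eb <- rng[1] + (rng[2] - rng[1]) *
    EBImage::otsu(EBImage::Image((img$grid - rng[1]) / (rng[2] - rng[1])),
                  range = c(0, 1), levels = 256)
  box <- function(t) {
    m <- img$grid > t
    c(diff(range(which(rowSums(m) > 0))), diff(range(which(colSums(m) > 0))))
  }
  expect_true(all(abs(box(thr) - box(thr_eb)) <= 2))
})

test_that("field-size estimation recovers squares, rectangles and scale invariance", {
  n <- 128L
  det <- tiny_det(n)
  pitch_cm <- det$pixel_pitch_mm / 10
  g <- matrix(0, n, n)
  # ideal binary square: 50 px = 16 cm at the detector = 10 cm nominal
  g[40:89, 40:89] <- 1000
  img <- epid_image(g, detector = det)
  est <- estimate_field_size(img)
  expect_lt(abs(est - 10), pitch_cm / 1.6 + 1e-9)
  # positive rescaling leaves the estimate unchanged
  expect_equal(estimate_field_size(epid_image(g * 7.3, detector = det)), est)
  # rectangle 8 x 12 nominal -> enclosing square 12
  g2 <- matrix(0, n, n)
  g2[45:84, 35:94] <- 500   # 40 px x 60 px: enclosing square from 60 px
  expect_lt(abs(estimate_field_size(epid_image(g2, detector = det)) - 12),
            pitch_cm / 1.6 + 1e-9)
  expect_error(estimate_field_size(uniform_image(5, n)), "dynamic range")
})

test_that("field-size recovery on penumbra-blurred fields is within 2 pitches", {
  nf <- noise_free_setup(128L)
  det <- nf$sys$detector
  tol <- 2 * det$pixel_pitch_mm / 10 / 1.6
  for (f in c(5, 10, 15, 20)) {
    img <- simulate_epid_image(nf$sys, f, NULL)
    img$meta$field_cm <- NULL
    expect_lt(abs(estimate_field_size(img) - f), tol + 1e-9)
  }
})

test_that("water-equivalent thickness is a density-weighted sum and additive", {
  expect_equal(effective_thickness(slab_stack(10, 1)), 10)
  expect_equal(effective_thickness(slab_stack(c(5, 2), c(1, 1.8))), 8.6)
  expect_equal(effective_thickness(slab_stack()), 0)
  expect_error(slab_stack(-1, 1), ">= 0")
  set.seed(11)
  a <- slab_stack(stats::runif(3, 0, 5), stats::runif(3, 0.5, 2))
  b <- slab_stack(stats::runif(2, 0, 5), stats::runif(2, 0.5, 2))
  ab <- slab_stack(c(a$thickness_cm, b$thickness_cm),
                   c(a$rel_density, b$rel_density))
  expect_equal(effective_thickness(ab),
               effective_thickness(a) + effective_thickness(b))
})

test_that("coarse-grid resampling preserves constants, midpoints and clamps", {
  det <- tiny_det(32)
  expect_equal(resample_to_epid_grid(matrix(4.2, 5, 5), 70, det),
               matrix(4.2, 32, 32))
  # 2x2 coarse grid: the beam axis sits at the cell center, so a spacing
  # that puts every pixel near the center recovers the corner mean
  coarse <- matrix(c(1, 3, 5, 7), 2, 2)
  fine <- resample_to_epid_grid(coarse, 1e6, det)
  expect_lt(max(abs(fine - mean(coarse))), 2e-3)
  # queries beyond the coarse support take the boundary value
  tiny <- resample_to_epid_grid(coarse, 0.1, det)
  expect_equal(tiny[1, 1], coarse[1, 1])
  expect_equal(tiny[32, 32], coarse[2, 2])
  expect_error(resample_to_epid_grid(matrix(1, 1, 5), 7, det), "2 x 2")
})

test_that("phantom projection maps regions through the divergent geometry", {
  det <- tiny_det(128)
  geo <- beam_geometry()
  # uniform phantom covering the projected panel
  ph <- phantom_map(matrix(12, 300, 300), spacing_cm = 0.1)
  proj <- project_phantom_thickness(ph, geo, det)
  expect_true(all(proj == 12))
  # empty beam
  ph0 <- phantom_map(matrix(0, 50, 50), spacing_cm = 0.1)
  expect_true(all(project_phantom_thickness(ph0, geo, det) == 0))
  # three lateral regions: edges magnified by 1.6 at the detector plane
  ph3 <- phantom_map_from_regions(list(
    list(x_min = -10, x_max = -2.5, y_min = -10, y_max = 10, wet_cm = 6),
    list(x_min = -2.5, x_max = 2.5, y_min = -10, y_max = 10, wet_cm = 10),
    list(x_min = 2.5, x_max = 10, y_min = -10, y_max = 10, wet_cm = 18)),
    extent_cm = 20, spacing_cm = 0.1)
  proj3 <- project_phantom_thickness(ph3, geo, det)
  prof <- proj3[64, ]
  x <- pixel_centers_cm(det)$x_cm
  pitch_cm <- det$pixel_pitch_mm / 10
  expect_equal(unique(prof[x > -3 & x < 3]), 10)          # central plateau
  expect_equal(unique(prof[x > -15 & x < -4.5]), 6)       # left plateau
  expect_equal(unique(prof[x > 4.5 & x < 15]), 18)        # right plateau
  # boundary between regions sits at 2.5 cm * 1.6 = 4 cm +- one pixel
  edge <- x[min(which(prof == 18))] - pitch_cm / 2
  expect_lt(abs(edge - 4), pitch_cm + 1e-9)
})

test_that("region areas scale with the squared magnification", {
  det <- tiny_det(128)
  geo <- beam_geometry()
  ph <- phantom_map_from_regions(list(
    list(x_min = -5, x_max = 5, y_min = -5, y_max = 5, wet_cm = 8)),
    extent_cm = 20, spacing_cm = 0.1)
  proj <- project_phantom_thickness(ph, geo, det)
  pitch_cm <- det$pixel_pitch_mm / 10
  area_cm2 <- sum(proj > 0) * pitch_cm^2
  # 10 x 10 cm2 region -> 16 x 16 cm2 at the detector, one pixel per edge slack
  expect_lt(abs(sqrt(area_cm2) - 16), 2 * pitch_cm + 1e-9)
})
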