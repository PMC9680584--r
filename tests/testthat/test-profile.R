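# helper: coarse sample of a fine grid at array positions (beam-axis
# centered), mimicking a detector-array measurement of the same shape
coarse_sample <- function(grid, spacing_mm, det, n_coarse = 21L) {
  pitch_cm <- det$pixel_pitch_mm / 10
  idx <- (nrow(grid) + 1) / 2 +
    (seq_len(n_coarse) - (n_coarse + 1) / 2) * spacing_mm / 10 / pitch_cm
  resample_separable(grid, idx, idx)
}

test_that("identical normalized shapes give a unity correction map", {
  det <- tiny_det(64)
  shape <- 1 + 0.1 * outer((seq_len(64) - 32.5)^2, (seq_len(64) - 32.5)^2,
                           `+`) / 32.5^4
  img <- epid_image(5000 * shape, detector = det)
  arr <- list(grid = coarse_sample(shape, 20, det), spacing_mm = 20)
  set <- build_profile_set(list(arr), list(img), thickness_cm = 0,
                           f_max_cm = 15)
  expect_equal(set$maps[[1]], matrix(1, 64, 64), tolerance = 1e-9)
  expect_equal(beam_axis_value(set$maps[[1]]), 1)
})

test_that("a flat portal image yields the array shape as correction map", {
  det <- tiny_det(64)
  x <- pixel_centers_cm(det)$x_cm
  shape <- 1 + 0.05 * outer(x^2, x^2, `+`) / max(x)^4  # smooth reference
  img <- uniform_image(4000, 64)
  arr <- list(grid = coarse_sample(shape, 20, det), spacing_mm = 20)
  set <- build_profile_set(list(arr), list(img), thickness_cm = 0,
                           f_max_cm = 15)
  # map equals the (resampled) reference shape
  expect_equal(set$maps[[1]], shape / beam_axis_value(shape),
               tolerance = 5e-3)
  expect_equal(beam_axis_value(set$maps[[1]]), 1)
})

test_that("profile-set construction validates its inputs", {
  det <- tiny_det(64)
  img <- uniform_image(100, 64)
  arr <- list(grid = matrix(1, 11, 11), spacing_mm = 20)
  expect_error(build_profile_set(list(arr), list(img, img), c(0, 4)),
               "match")
  expect_error(build_profile_set(list(arr), list(img), c(4)), "include 0")
  zero_img <- epid_image(matrix(0, 64, 64), detector = det)
  expect_error(build_profile_set(list(arr), list(zero_img), 0),
               "degenerate")
})

test_that("profile map retrieval: identity, thickness mean, lateral rescale", {
  nf <- noise_free_setup(128L)
  set <- nf$model$profiles
  # identity at f_max and a stored thickness: bit-identical map
  expect_identical(get_profile_map(set, set$f_max_cm, 8), set$maps[[3]])
  # thickness midway between stored 4 and 8: pixelwise mean of the maps
  mid <- get_profile_map(set, set$f_max_cm, 6)
  expect_equal(mid, (set$maps[[2]] + set$maps[[3]]) / 2, tolerance = 1e-12)
  # f = f_max / 2: value at x = 3 cm equals the stored map's value at 6 cm
  half <- get_profile_map(set, set$f_max_cm / 2, 0)
  det <- set$detector
  x <- pixel_centers_cm(det)$x_cm
  r <- (det$n_rows + 1) / 2
  at <- function(m, x_cm) {
    as.numeric(resample_separable(m, r, (det$n_cols + 1) / 2 +
                                    x_cm / (det$pixel_pitch_mm / 10)))
  }
  # double bilinear sampling differs at the curvature scale only
  expect_equal(at(half, 3), at(set$maps[[1]], 6), tolerance = 1e-3)
  expect_error(get_profile_map(set, -5, 0), "positive")
  expect_error(get_profile_map(set, 15, 25,
                               calibration_config(out_of_range = "error")),
               "outside")
})

test_that("double lateral rescale returns a smooth map within bilinear tolerance", {
  nf <- noise_free_setup(128L)
  set <- nf$model$profiles
  m <- set$maps[[1]]
  down <- get_profile_map(set, set$f_max_cm / 1.5, 0)
  # build a one-map set from the rescaled grid and rescale back
  tmp <- set
  tmp$maps <- list(down)
  tmp$thickness_cm <- 0
  tmp$f_max_cm <- set$f_max_cm / 1.5
  back <- get_profile_map(tmp, set$f_max_cm, 0)
  # compare where the map is smooth (inside the calibration field; beyond
  # the field edge the measured ratio carries sub-coarse-grid structure
  # that no bilinear round trip can represent)
  det <- set$detector
  cc <- pixel_centers_cm(det)
  inner <- outer(abs(cc$y_cm) <= 9, abs(cc$x_cm) <= 9, `&`)
  expect_lt(max(abs(back - m)[inner]), 1e-3)
})

test_that("every stored correction map is positive with unit axis value", {
  nf <- noise_free_setup(128L)
  for (m in nf$model$profiles$maps) {
    expect_true(all(m > 0))
    expect_true(all(is.finite(m)))
    expect_equal(beam_axis_value(m), 1)
  }
})
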