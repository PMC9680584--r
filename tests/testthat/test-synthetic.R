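test_that("system generation is deterministic and normalized at reference", {
  s1 <- generate_system(seed = 7, detector = tiny_det(64))
  s2 <- generate_system(seed = 7, detector = tiny_det(64))
  expect_identical(s1, s2)
  expect_equal(true_kf(s1, 10), 1)
  for (f in c(5, 10, 15, 20)) expect_equal(true_kd(s1, f, 0), 1)
  expect_error(generate_system(config = list(nonsense = 1)), "unknown")
  expect_error(generate_system(config = list(d0_gy = -1)), "invalid")
})

test_that("true dose has the closed-form center value and monotone physics", {
  nf <- noise_free_setup(128L)
  sys <- nf$sys
  open <- simulate_true_dose(sys, 10, NULL)
  expect_equal(beam_axis_value(open$grid), sys$d0_gy, tolerance = 1e-9)
  slab <- simulate_true_dose(sys, 10, slab_stack(10, 1))
  expect_equal(beam_axis_value(slab$grid),
               sys$d0_gy * exp(-10 * sys$mu_eff), tolerance = 1e-9)
  # relative profile is 1 on the beam axis
  rel <- open$grid / beam_axis_value(open$grid)
  expect_equal(beam_axis_value(rel), 1)
  # center dose strictly decreasing in thickness, output factor monotone in f
  doses <- vapply(c(0, 4, 8, 16), function(d) true_center_dose(sys, 10, d),
                  numeric(1))
  expect_true(all(diff(doses) < 0))
  ofs <- vapply(c(4, 8, 12, 20, 26), function(f) true_center_dose(sys, f, 0),
                numeric(1))
  expect_true(all(diff(ofs) > 0))
})

test_that("portal image simulation matches its closed form and is seeded", {
  nf <- noise_free_setup(128L)
  img <- simulate_epid_image(nf$sys, 10, NULL)
  expect_equal(beam_axis_value(img$grid),
               nf$sys$pixel_scale * nf$sys$d0_gy / nf$sys$n_sys,
               tolerance = 1e-9)
  expect_true(all(img$grid >= 0) && all(is.finite(img$grid)))
  noisy <- generate_system(seed = 3, detector = tiny_det(64))
  i1 <- simulate_epid_image(noisy, 10, NULL, noise_seed = 11)
  i2 <- simulate_epid_image(noisy, 10, NULL, noise_seed = 11)
  i3 <- simulate_epid_image(noisy, 10, NULL, noise_seed = 12)
  expect_identical(i1$grid, i2$grid)
  expect_false(identical(i1$grid, i3$grid))
  # frame averaging reduces the noise level
  i4 <- simulate_epid_image(noisy, 10, NULL, noise_seed = 11, n_frames = 16)
  flat <- simulate_epid_image(generate_system(
    config = list(noise_sd = 0), seed = 3, detector = tiny_det(64)), 10, NULL)
  expect_lt(stats::sd((i4$grid / flat$grid)[flat$grid > 1000]),
            stats::sd((i1$grid / flat$grid)[flat$grid > 1000]) / 2)
})

test_that("profile self-similarity holds across field sizes", {
  nf <- noise_free_setup(128L)
  sys <- nf$sys
  # P and the flattening depend only on field-normalized coordinates:
  # the 7.5 cm map sampled at x equals the 15 cm map sampled at 2x
  m15 <- true_profile_map(sys, 15, 4)
  m75 <- true_profile_map(sys, 7.5, 4)
  det <- sys$detector
  r <- (det$n_rows + 1) / 2
  inner <- which(abs(pixel_centers_cm(det)$x_cm) < 10)
  stretched <- resample_separable(m15, r, r + (seq_len(det$n_cols) - r) * 2)
  expect_equal(central_profile(m75)[inner], as.numeric(stretched)[inner],
               tolerance = 1e-3)
})

test_that("IMRT apertures are seeded, binary and leaf-quantized", {
  a1 <- generate_imrt_aperture(5, n_segments = 5)
  a2 <- generate_imrt_aperture(5, n_segments = 5)
  expect_identical(a1, a2)
  expect_true(all(a1$grid %in% c(0, 1)))
  expect_gt(a1$enclosing_square_cm, 0)
  expect_lte(a1$enclosing_square_cm, a1$max_field_cm)
  # open-region edges lie on leaf-width multiples (0.05 cm raster slack)
  cols <- which(colSums(a1$grid) > 0)
  x <- (cols - (ncol(a1$grid) + 1) / 2) * a1$spacing_cm
  edges <- c(min(x) - a1$spacing_cm / 2, max(x) + a1$spacing_cm / 2)
  offs <- (edges + a1$max_field_cm / 2) / a1$leaf_width_cm
  expect_lt(max(abs(offs - round(offs))), 0.11)
  expect_error(generate_imrt_aperture(1, max_field_cm = -5), "invalid")
})

test_that("the fixture set reproduces the calibration measurement design", {
  nf <- noise_free_setup(128L)
  ds <- nf$dataset
  expect_length(ds$kf$field_cm, 12)           # 4x4 .. 26x26 in 2 cm steps
  expect_equal(range(ds$kf$field_cm), c(4, 26))
  expect_equal(nrow(ds$kd$grid), 4 * 6)       # 4 fields x 6 thicknesses
  expect_setequal(unique(ds$kd$grid$field_cm), c(5, 10, 15, 20))
  expect_setequal(unique(ds$kd$grid$thickness_cm), seq(0, 20, 4))
  expect_length(ds$kprofile$thickness_cm, 6)  # 0 .. 20 cm at f_max = 15
  expect_equal(ds$kprofile$f_max_cm, 15)
  expect_equal(ds$reference$dose_gy, nf$sys$d0_gy)
})

test_that("noise-free calibration inverts the forward model at fixture points", {
  nf <- noise_free_setup(128L)
  for (i in c(1, 7, 24)) {
    f <- nf$dataset$kd$grid$field_cm[i]
    d <- nf$dataset$kd$grid$thickness_cm[i]
    img <- simulate_epid_image(nf$sys, f, d)
    dose <- convert_image_to_dose(nf$model, img)
    expect_equal(beam_axis_value(dose$grid), true_center_dose(nf$sys, f, d),
                 tolerance = 1e-6)
  }
})
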