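gamma_det <- function(n, pitch_mm = 2) {
  detector_spec(n, n, pitch_mm, n * pitch_mm / 10)
}

test_that("identical distributions give gamma 0 and a 100% pass rate", {
  det <- gamma_det(32)
  m <- random_smooth_map(32, seed = 1)
  ref <- dose_map(m, detector = det)
  res <- compute_gamma(ref, ref)
  expect_true(all(res$gamma[res$mask] == 0))
  expect_equal(res$pass_rate_pct, 100)
})

test_that("a uniform +3%-of-max offset gives gamma exactly 1", {
  det <- gamma_det(32)
  ref <- dose_map(matrix(2, 32, 32), detector = det)
  ev <- dose_map(matrix(2 * 1.03, 32, 32), detector = det)
  res <- compute_gamma(ref, ev, gamma_params(3, 3))
  expect_lt(max(abs(res$gamma[res$mask] - 1)), 1e-12)
  expect_equal(pass_rate(res), 100)
})

test_that("gamma equals the exhaustive brute-force oracle elementwise", {
  det <- gamma_det(32)
  params <- gamma_params(3, 3)
  for (seed in 1:6) {
    ref_m <- random_smooth_map(32, seed = seed)
    ev_m <- random_smooth_map(32, seed = seed + 100)
    # bring the two maps within a comparable scale
    ev_m <- ev_m * mean(ref_m) / mean(ev_m)
    res <- compute_gamma(dose_map(ref_m, detector = det),
                         dose_map(ev_m, detector = det), params)
    oracle <- gamma_bruteforce(ref_m, ev_m, pitch_mm = 2, dd_pct = 3,
                               dta_mm = 3, thr_pct = 10)
    expect_lt(max(abs(res$gamma - oracle), na.rm = TRUE), 1e-9)
    expect_identical(is.na(res$gamma), is.na(oracle))
  }
})

test_that("gamma is invariant under joint rescaling and monotone in dd / DTA", {
  det <- gamma_det(32)
  ref_m <- random_smooth_map(32, seed = 5)
  ev_m <- random_smooth_map(32, seed = 105) * 1.02
  ref <- dose_map(ref_m, detector = det)
  ev <- dose_map(ev_m, detector = det)
  base <- compute_gamma(ref, ev, gamma_params(3, 3))
  scaled <- compute_gamma(dose_map(7 * ref_m, detector = det),
                          dose_map(7 * ev_m, detector = det),
                          gamma_params(3, 3))
  expect_equal(base$gamma, scaled$gamma, tolerance = 1e-12)
  looser_dd <- compute_gamma(ref, ev, gamma_params(4, 3))
  looser_dta <- compute_gamma(ref, ev, gamma_params(3, 4))
  expect_true(all(looser_dd$gamma <= base$gamma + 1e-12, na.rm = TRUE))
  expect_true(all(looser_dta$gamma <= base$gamma + 1e-12, na.rm = TRUE))
})

test_that("a step edge translated by exactly one DTA passes at the edge", {
  det <- gamma_det(48)
  # DTA 2 mm = 1 pixel = 3 subsample steps: the offset lattice hits it
  ref_m <- matrix(0.05, 48, 48); ref_m[, 1:24] <- 1
  ev_m <- matrix(0.05, 48, 48); ev_m[, 1:25] <- 1   # edge shifted 1 px
  res <- compute_gamma(dose_map(ref_m, detector = det),
                       dose_map(ev_m, detector = det),
                       gamma_params(3, 2))
  expect_true(all(res$gamma[res$mask] <= 1 + 1e-9))
})

test_that("low-dose points are excluded and the pass rate counts correctly", {
  det <- gamma_det(32)
  ref_m <- matrix(1, 32, 32)
  ref_m[, 1:8] <- 0.05   # below the 10% threshold
  ev_m <- ref_m
  ev_m[, 9:16] <- 1.05   # 5% of max off: fails at 3%
  res <- compute_gamma(dose_map(ref_m, detector = det),
                       dose_map(ev_m, detector = det),
                       gamma_params(3, 0.5, search_radius_mm = 0.5))
  expect_equal(sum(res$mask), 32 * 24)
  expect_true(all(is.na(res$gamma[, 1:8])))
  # half gamma <= 1, a third above: direct count
  expect_equal(pass_rate(res), 100 * mean(res$gamma[res$mask] <= 1))
  expect_equal(pass_rate(res, threshold = 2), 100)
})

test_that("gamma guards degenerate input", {
  det <- gamma_det(16)
  z <- dose_map(matrix(0, 16, 16), detector = det)
  expect_error(compute_gamma(z, z), "maximum dose is zero")
  a <- dose_map(matrix(1, 16, 16), detector = det)
  b <- dose_map(matrix(1, 16, 32), detector = detector_spec(16, 32, 2, 6.4))
  expect_error(compute_gamma(a, b), "same grid")
})
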