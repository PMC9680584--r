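# Shared fixtures and independent oracles for the test suite.

# detector covering the 41 cm panel with n x n elements
tiny_det <- function(n) detector_spec(n, n, 410 / n, 41)

uniform_image <- function(value, n = 64, s = 1, det = tiny_det(n)) {
  epid_image(matrix(value, det$n_rows, det$n_cols), scaling_factor = s,
             detector = det)
}

# lazily built, cached fixtures (shared across test files in one session)
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# noise-free synthetic system + fixture set + calibration model
noise_free_setup <- function(n = 128L) {
  cached_fixture(paste0("nf", n), {
    sys <- generate_system(config = list(noise_sd = 0), seed = 42,
                           detector = tiny_det(n))
    ds <- generate_calibration_dataset(sys)
    list(sys = sys, dataset = ds, model = build_calibration_model(ds))
  })
}

# default-noise synthetic system + calibration model
noisy_setup <- function(n = 128L, seed = 42) {
  cached_fixture(paste0("noisy", n, "_", seed), {
    sys <- generate_system(seed = seed, detector = tiny_det(n))
    ds <- generate_calibration_dataset(sys)
    list(sys = sys, dataset = ds, model = build_calibration_model(ds))
  })
}

# logical in-field mask (|x|,|y| <= nominal side/2 * magnification)
in_field_mask <- function(det, field_cm, magnification = 1.6) {
  cc <- pixel_centers_cm(det)
  half <- field_cm * magnification / 2
  outer(abs(cc$y_cm) <= half, abs(cc$x_cm) <= half, `&`)
}

# smooth positive random map from a low-order cosine series
random_smooth_map <- function(n, seed) {
  set.seed(seed)
  x <- seq(-1, 1, length.out = n)
  g <- matrix(1, n, n)
  for (k in 1:3) {
    ax <- stats::runif(1, -0.3, 0.3)
    ay <- stats::runif(1, -0.3, 0.3)
    px <- stats::runif(1, 0, pi)
    py <- stats::runif(1, 0, pi)
    g <- g + ax * outer(rep(1, n), cos(k * pi * x + px)) +
      ay * outer(cos(k * pi * x + py), rep(1, n))
  }
  g - min(g) + 0.5
}

# Independent brute-force gamma oracle: per-point exhaustive search over
# the subsampled offset lattice, with its own bilinear interpolation.
gamma_bruteforce <- function(ref, ev, pitch_mm, dd_pct, dta_mm, thr_pct,
                             search_mm = 3 * dta_mm, sub = 3L) {
  nr <- nrow(ref); nc <- ncol(ref)
  dmax <- max(ref)
  dd_abs <- dd_pct / 100 * dmax
  step <- 1 / sub
  k <- ceiling(search_mm / pitch_mm / step)
  off <- expand.grid(dr = (-k:k) * step, dc = (-k:k) * step)
  d2 <- (off$dr^2 + off$dc^2) * pitch_mm^2
  keep <- d2 <= search_mm^2 + 1e-12
  off <- off[keep, ]
  s2 <- d2[keep] / dta_mm^2
  g <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (ref[i, j] < thr_pct / 100 * dmax) next
      r <- pmin(pmax(i + off$dr, 1), nr)
      c <- pmin(pmax(j + off$dc, 1), nc)
      r0 <- pmin(floor(r), nr - 1); fr <- r - r0
      c0 <- pmin(floor(c), nc - 1); fc <- c - c0
      vals <- ev[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
        ev[cbind(r0 + 1, c0)] * fr * (1 - fc) +
        ev[cbind(r0, c0 + 1)] * (1 - fr) * fc +
        ev[cbind(r0 + 1, c0 + 1)] * fr * fc
      g[i, j] <- sqrt(min(((vals - ref[i, j]) / dd_abs)^2 + s2))
    }
  }
  g
}
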