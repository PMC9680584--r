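# Seeded forward model of linac + phantom + EPID. The model is
# multiplicatively separable in exactly the factors the calibration
# corrects: true dose D = D0 * OF(f) * exp(-mu * d) * P * A_pen, portal
# signal I = s * D * R_f(f) * R_d(f, d) / (N_sys * F) * (1 + noise), where
# P are the beam horns and F the vendor flattening, both functions of
# field-normalized coordinates so the lateral-rescale rule of the profile
# correction is exact for this generator.

# run expr with a temporary RNG state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

synthetic_defaults <- function() {
  list(
    d0_gy = 0.4,            # reference central dose (Gy), f_ref, open beam
    mu_eff = 0.045,         # effective attenuation (1/cm), 6 MV broad beam
    of_exponent = 0.08,     # output factor OF(f) = (f/f_ref)^of_exponent
    rf_exponent = -0.05,    # detector field response R_f = (f/f_ref)^rf_exp
    kd_fields_cm = c(5, 10, 15, 20),
    kd_coef = rbind(        # 1/R_d(f, d) = 1 + c1 d + c2 d^2 + c3 d^3
      c(0.0120, -7.0e-4, 0.0),
      c(0.0220, -1.1e-3, 1.1e-5),
      c(0.0305, -1.25e-3, 1.3e-5),
      c(0.0300, -1.1e-3, 1.0e-5)),
    horn_amplitude = 0.06,  # beam-horn amplitude at d = 0
    horn_decay_cm = 15,     # horn amplitude decays exp(-d / this)
    flatten_amplitude = 0.10,  # flattening strength at d = 0
    flatten_decay_cm = 25,
    flatten_linear = 0.001, # slow thickness-linear flattening component
    flat_core = 0.35,       # flat central core (fraction of the half-side)
    n_sys = 8e-5,           # system gain (Gy per gray-value unit)
    pixel_scale = 1,        # vendor pixel scaling factor s
    penumbra_width_mm = 15, # penumbra edge half-width at the detector plane
                            # (smoothstep edge; 80-20% distance ~ 9.7 mm)
    noise_sd = 0.003,       # multiplicative noise standard deviation
    transmission = 0.002,   # jaw/leaf transmission floor
    f_ref_cm = 10,
    f_max_cm = 15
  )
}

#' Generate a synthetic linac + EPID system
#'
#' Builds the seeded ground-truth forward model used to produce portal
#' images, true dose maps and the complete calibration fixture set. All
#' reference normalizations hold exactly: the output factor, detector field
#' response and thickness response equal 1 at the reference field /
#' reference thickness, and the beam-profile and flattening operators equal
#' 1 on the beam axis.
#'
#' @param config Named list overriding entries of the default configuration
#'   (dose and response parameters, noise level, transmission, ...).
#' @param seed Integer seed; the base of every noise stream drawn from this
#'   system.
#' @param detector A [detector_spec()] for all simulated images.
#' @param geometry A [beam_geometry()].
#' @return A `synthetic_system` object.
#' @export
generate_system <- function(config = list(), seed = 1,
                            detector = detector_spec(),
                            geometry = beam_geometry()) {
  cfg <- synthetic_defaults()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration entries: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(config)] <- config
  with(cfg, {
    if (d0_gy <= 0 || mu_eff < 0 || n_sys <= 0 || pixel_scale <= 0 ||
        noise_sd < 0 || transmission < 0 || transmission >= 1 ||
        penumbra_width_mm < 0 || flat_core <= 0 || flat_core >= 1) {
      stop("invalid synthetic configuration ranges", call. = FALSE)
    }
  })
  if (nrow(cfg$kd_coef) != length(cfg$kd_fields_cm)) {
    stop("kd_coef must have one row per kd field size", call. = FALSE)
  }
  structure(c(cfg, list(seed = as.integer(seed), detector = detector,
                        geometry = geometry)),
            class = "synthetic_system")
}

#' @export
print.synthetic_system <- function(x, ...) {
  cat(sprintf("Synthetic linac+EPID system (seed %d): D0 = %g Gy, mu_eff = %g /cm,\n",
              x$seed, x$d0_gy, x$mu_eff))
  cat(sprintf("  noise sd %.2g, penumbra half-width %g mm, %d x %d detector\n",
              x$noise_sd, x$penumbra_width_mm,
              x$detector$n_rows, x$detector$n_cols))
  invisible(x)
}

# --- true response functions -------------------------------------------------

#' True system responses (ground truth for calibration recovery)
#'
#' `true_kf` and `true_kd` return the correction factors a perfect
#' calibration of this system must find (the reciprocal detector responses);
#' `true_profile_map` the exact profile-correction map; `true_center_dose`
#' the beam-axis dose a chamber measures.
#'
#' @param system A [generate_system()] result.
#' @param field_cm Nominal field side (cm).
#' @param thickness_cm Water-equivalent thickness (cm); scalar or array.
#' @return Numeric value(s) / matrix for the map.
#' @export
true_kf <- function(system, field_cm) {
  knots <- seq(4, 26, by = 2)
  kf <- (knots / system$f_ref_cm)^(-system$rf_exponent)
  stats::approx(knots, kf, xout = pmin(pmax(field_cm, 4), 26),
                method = "linear")$y
}

#' @rdname true_kf
#' @export
true_kd <- function(system, field_cm, thickness_cm) {
  co <- kd_coef_at(system, field_cm)
  1 + co[1] * thickness_cm + co[2] * thickness_cm^2 + co[3] * thickness_cm^3
}

# linearly interpolate the cubic coefficients in field side (clamped)
kd_coef_at <- function(system, field_cm) {
  fs <- system$kd_fields_cm
  f <- min(max(field_cm, fs[1]), fs[length(fs)])
  i <- min(max(findInterval(f, fs), 1L), length(fs) - 1L)
  w <- (f - fs[i]) / (fs[i + 1] - fs[i])
  (1 - w) * system$kd_coef[i, ] + w * system$kd_coef[i + 1, ]
}

output_factor <- function(system, field_cm) {
  (field_cm / system$f_ref_cm)^system$of_exponent
}

# The reciprocal response 1/R_f (the correction the calibration looks up)
# is piecewise-linear in f through the 2-cm field-size knots (clamped); the
# knots sample a power law, keeping the small-field over-response and
# large-field under-response shape between calibrated field sizes.
field_response <- function(system, field_cm) {
  1 / true_kf(system, field_cm)
}

thickness_response <- function(system, field_cm, thickness_cm) {
  1 / true_kd(system, field_cm, thickness_cm)
}

horn_amp <- function(system, d) {
  system$horn_amplitude * exp(-d / system$horn_decay_cm)
}

flatten_amp <- function(system, d) {
  system$flatten_amplitude * exp(-d / system$flatten_decay_cm) +
    system$flatten_linear * d
}

# radial shape shared by horns and flattening: zero inside the flat core,
# quadratic rise towards the field edge (rho = 1 at the edge)
radial_shape <- function(system, rho) {
  (pmax(rho - system$flat_core, 0) / (1 - system$flat_core))^2
}

# field-normalized radius rho = sqrt(u^2 + v^2), u = x / (f_det / 2)
rho_grid <- function(system, field_cm) {
  cc <- pixel_centers_cm(system$detector)
  half <- field_side_at_detector_cm(field_cm, system$geometry) / 2
  u2 <- (cc$x_cm / half)^2
  v2 <- (cc$y_cm / half)^2
  sqrt(outer(v2, u2, `+`))
}

#' @rdname true_kf
#' @export
true_profile_map <- function(system, field_cm, thickness_cm) {
  g <- radial_shape(system, rho_grid(system, field_cm))
  1 + flatten_amp(system, thickness_cm) * g
}

#' @rdname true_kf
#' @export
true_center_dose <- function(system, field_cm, thickness_cm = 0) {
  system$d0_gy * output_factor(system, field_cm) *
    exp(-system$mu_eff * thickness_cm)
}

# --- apertures ---------------------------------------------------------------

#' Generate a seeded IMRT-like aperture
#'
#' Union of seeded rectangular MLC-segment openings at the isocenter plane;
#' all rectangle edges are quantized to the leaf width. Transmission is
#' binary (0 or 1) before penumbra convolution.
#'
#' @param seed Integer seed.
#' @param n_segments Number of rectangular segments (>= 1).
#' @param max_field_cm Maximum field extent (cm) the aperture fits in.
#' @param leaf_width_cm MLC leaf width at the isocenter (cm).
#' @param spacing_cm Rasterization spacing of the aperture grid (cm).
#' @return An `aperture` object with the binary transmission grid, its
#'   spacing, and the enclosing-square side `enclosing_square_cm`.
#' @export
generate_imrt_aperture <- function(seed, n_segments = 5, max_field_cm = 15,
                                   leaf_width_cm = 0.5, spacing_cm = 0.1) {
  if (n_segments < 1) stop("need at least one segment", call. = FALSE)
  if (max_field_cm <= 0 || leaf_width_cm <= 0) {
    stop("invalid aperture dimensions", call. = FALSE)
  }
  n_leaf <- floor(max_field_cm / leaf_width_cm)
  n <- max(2L, as.integer(round(max_field_cm / spacing_cm)))
  x <- (seq_len(n) - (n + 1) / 2) * spacing_cm
  grid <- matrix(0, n, n)
  with_local_seed(seed, {
    for (s in seq_len(n_segments)) {
      jx <- sort(sample.int(n_leaf + 1L, 2L) - 1L)
      jy <- sort(sample.int(n_leaf + 1L, 2L) - 1L)
      while (jx[1] == jx[2]) jx <- sort(sample.int(n_leaf + 1L, 2L) - 1L)
      while (jy[1] == jy[2]) jy <- sort(sample.int(n_leaf + 1L, 2L) - 1L)
      ed <- -max_field_cm / 2 + leaf_width_cm * c(jx, jy)
      cols <- which(x > ed[1] & x < ed[2])
      rows <- which(x > ed[3] & x < ed[4])
      grid[rows, cols] <- 1
    }
  })
  rows <- range(which(rowSums(grid) > 0))
  cols <- range(which(colSums(grid) > 0))
  side <- max(diff(rows) + 1L, diff(cols) + 1L) * spacing_cm
  structure(list(grid = grid, spacing_cm = spacing_cm,
                 leaf_width_cm = leaf_width_cm, max_field_cm = max_field_cm,
                 enclosing_square_cm = side, seed = as.integer(seed)),
            class = "aperture")
}

# Penumbra model: a smoothstep edge of compact support (half-width w at
# the detector plane). Compact support keeps the field interior at exactly
# 1, so reference normalizations are not polluted by edge tails.
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# transmission profile across an edge; t = signed distance inside (cm)
edge_profile <- function(t, w_cm) {
  if (w_cm <= 0) return(as.numeric(t >= 0))
  smoothstep((t + w_cm) / (2 * w_cm))
}

# separable convolution with the smoothstep-derivative kernel (compact
# support, zero padding); reproduces edge_profile on straight edges
blur_separable <- function(m, w_px) {
  if (w_px <= 0) return(m)
  r <- max(1L, as.integer(ceiling(w_px)))
  u <- ((-r):r + w_px) / (2 * w_px)
  k <- ifelse(u > 0 & u < 1, u * (1 - u), 0)
  k <- k / sum(k)
  one_pass <- function(mm) {
    pad <- matrix(0, r, ncol(mm))
    f <- stats::filter(rbind(pad, mm, pad), k, sides = 2)
    matrix(f[(r + 1):(r + nrow(mm)), ], nrow(mm), ncol(mm))
  }
  t(one_pass(t(one_pass(m))))
}

# --- forward model -----------------------------------------------------------

# effective water-equivalent thickness on the detector grid: 0, scalar, or
# a per-pixel matrix
effective_thickness_input <- function(system, phantom) {
  if (is.null(phantom)) return(0)
  if (inherits(phantom, "slab_stack")) return(effective_thickness(phantom))
  if (inherits(phantom, "phantom_map")) {
    return(project_phantom_thickness(phantom, system$geometry,
                                     system$detector))
  }
  if (is.numeric(phantom)) return(phantom)
  stop("phantom must be NULL, a slab_stack, a phantom_map or numeric",
       call. = FALSE)
}

# penumbra-convolved aperture transmission on the detector grid, plus the
# nominal enclosing-square side
aperture_on_detector <- function(system, field) {
  det <- system$detector
  w_px <- system$penumbra_width_mm / det$pixel_pitch_mm
  if (is.numeric(field)) {
    if (length(field) != 1L || field <= 0) {
      stop("field size must be a positive scalar", call. = FALSE)
    }
    cc <- pixel_centers_cm(det)
    half <- field_side_at_detector_cm(field, system$geometry) / 2
    w_cm <- system$penumbra_width_mm / 10
    edge <- function(x) {
      edge_profile(x + half, w_cm) + edge_profile(half - x, w_cm) - 1
    }
    a <- outer(edge(cc$y_cm), edge(cc$x_cm))
    return(list(a_pen = a, f_enc = field))
  }
  if (inherits(field, "aperture")) {
    cc <- pixel_centers_cm(det)
    mag <- system$geometry$magnification
    pg <- field$grid
    rows <- round((nrow(pg) + 1) / 2 + (cc$y_cm / mag) / field$spacing_cm)
    cols <- round((ncol(pg) + 1) / 2 + (cc$x_cm / mag) / field$spacing_cm)
    mask <- matrix(0, det$n_rows, det$n_cols)
    rin <- rows >= 1 & rows <= nrow(pg)
    cin <- cols >= 1 & cols <= ncol(pg)
    mask[rin, cin] <- pg[rows[rin], cols[cin]]
    return(list(a_pen = blur_separable(mask, w_px),
                f_enc = field$enclosing_square_cm))
  }
  stop("field must be a nominal side (cm) or an aperture", call. = FALSE)
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

forward_components <- function(system, field, phantom) {
  ap <- aperture_on_detector(system, field)
  d_eff <- effective_thickness_input(system, phantom)
  g <- radial_shape(system, rho_grid(system, ap$f_enc))
  p_shape <- 1 + horn_amp(system, d_eff) * g
  a <- system$transmission + (1 - system$transmission) * ap$a_pen
  dose <- system$d0_gy * output_factor(system, ap$f_enc) *
    exp(-system$mu_eff * d_eff) * p_shape * a
  list(dose = dose, f_enc = ap$f_enc, d_eff = d_eff, g = g)
}

#' Simulate the ground-truth dose distribution at the detector plane
#'
#' `D(x,y) = D0 * OF(f) * exp(-mu_eff * d_eff(x,y)) * P(x,y; f, d) *
#' A_pen(x,y)` where `A_pen` is the aperture magnified to the detector plane
#' and convolved with the penumbra kernel, and `P` carries the beam horns.
#'
#' @param system A [generate_system()] result.
#' @param field Nominal square field side (cm) or an
#'   [generate_imrt_aperture()] aperture.
#' @param phantom `NULL` (open beam), a [slab_stack()], a [phantom_map()],
#'   or a numeric water-equivalent thickness (scalar or detector-grid
#'   matrix).
#' @return A [dose_map()] of kind `"absolute_Gy"`.
#' @export
simulate_true_dose <- function(system, field, phantom = NULL) {
  fc <- forward_components(system, field, phantom)
  dose_map(fc$dose, kind = "absolute_Gy", detector = system$detector,
           geometry = system$geometry)
}

#' Simulate a portal image
#'
#' Applies the detector field-size and thickness responses and the vendor
#' flattening to the true dose, divides by the system gain, multiplies by
#' the pixel scaling factor, and adds seeded multiplicative noise:
#' `I = s * D * R_f(f) * R_d(f, d) / (N_sys * F_d(x,y)) * (1 + eps)`.
#'
#' @inheritParams simulate_true_dose
#' @param noise_seed Seed of the noise stream; identical calls give
#'   identical images. Defaults to the system seed.
#' @param n_frames Number of independently noisy frames averaged into the
#'   returned image (calibration acquisitions average repeated frames).
#' @return An [epid_image()] with `field_cm` (and, for uniform phantoms,
#'   `thickness_cm`) recorded in the metadata.
#' @export
simulate_epid_image <- function(system, field, phantom = NULL,
                                noise_seed = system$seed, n_frames = 1) {
  fc <- forward_components(system, field, phantom)
  flat <- 1 + flatten_amp(system, fc$d_eff) * fc$g
  signal <- system$pixel_scale * fc$dose *
    field_response(system, fc$f_enc) *
    thickness_response(system, fc$f_enc, fc$d_eff) /
    (system$n_sys * flat)
  if (system$noise_sd > 0) {
    npx <- length(signal)
    eps <- with_local_seed(noise_seed, {
      e <- stats::rnorm(npx, sd = system$noise_sd)
      if (n_frames > 1) {
        for (k in seq_len(n_frames - 1)) {
          e <- e + stats::rnorm(npx, sd = system$noise_sd)
        }
        e <- e / n_frames
      }
      e
    })
    signal <- signal * (1 + matrix(eps, nrow(signal), ncol(signal)))
  }
  meta <- list(field_cm = fc$f_enc)
  if (length(fc$d_eff) == 1L) meta$thickness_cm <- fc$d_eff
  epid_image(pmax(signal, 0), scaling_factor = system$pixel_scale,
             detector = system$detector, geometry = system$geometry,
             meta = meta)
}

# closed-form true dose at arbitrary detector-plane points (square fields,
# uniform thickness) -- stands in for chamber / detector-array sampling
true_dose_at_points <- function(system, field_cm, thickness_cm, x_cm, y_cm) {
  half <- field_side_at_detector_cm(field_cm, system$geometry) / 2
  w_cm <- system$penumbra_width_mm / 10
  edge <- function(x) {
    edge_profile(x + half, w_cm) + edge_profile(half - x, w_cm) - 1
  }
  a <- system$transmission +
    (1 - system$transmission) * outer(edge(y_cm), edge(x_cm))
  rho <- sqrt(outer((y_cm / half)^2, (x_cm / half)^2, `+`))
  p <- 1 + horn_amp(system, thickness_cm) * radial_shape(system, rho)
  system$d0_gy * output_factor(system, field_cm) *
    exp(-system$mu_eff * thickness_cm) * p * a
}

#' Generate the complete calibration fixture set
#'
#' Reproduces the calibration measurement design: the reference pair at
#' 10 x 10 cm2 / d = 0, the field-size series at square fields 4-26 cm in
#' 2 cm steps (open beam), the thickness grid at fields {5, 10, 15, 20} cm
#' times thicknesses {0, 4, ..., 20} cm, and profile pairs
#' (detector-array relative profile + portal image) at f_max = 15 x 15 cm2
#' for the same thickness series, the array profiles delivered on a coarse
#' grid.
#'
#' @param system A [generate_system()] result.
#' @param n_frames Frames averaged per calibration image (see
#'   [simulate_epid_image()]).
#' @param seed Base seed for the acquisition noise streams.
#' @param array_spacing_mm Coarse detector-array grid spacing (mm) at the
#'   detector plane.
#' @return A fixture bundle: list with elements `reference` (dose + image),
#'   `kf` (field series), `kd` (field x thickness grid), `kprofile` (array
#'   profiles + images), plus `geometry`, `detector`, `f_ref_cm`.
#' @export
generate_calibration_dataset <- function(system, n_frames = 4,
                                         seed = system$seed,
                                         array_spacing_mm = 7) {
  f_ref <- system$f_ref_cm
  reference <- list(
    dose_gy = true_center_dose(system, f_ref, 0),
    image = simulate_epid_image(system, f_ref, NULL,
                                noise_seed = seed + 1L, n_frames = n_frames))

  kf_fields <- seq(4, 26, by = 2)
  kf_images <- lapply(seq_along(kf_fields), function(i) {
    simulate_epid_image(system, kf_fields[i], NULL,
                        noise_seed = seed + 100L + i, n_frames = n_frames)
  })
  kf <- list(field_cm = kf_fields,
             dose_gy = true_center_dose(system, kf_fields, 0),
             images = kf_images)

  kd_grid <- expand.grid(thickness_cm = seq(0, 20, by = 4),
                         field_cm = c(5, 10, 15, 20))[, 2:1]
  kd_grid$dose_gy <- true_center_dose(system, kd_grid$field_cm,
                                      kd_grid$thickness_cm)
  kd_images <- lapply(seq_len(nrow(kd_grid)), function(i) {
    simulate_epid_image(system, kd_grid$field_cm[i], kd_grid$thickness_cm[i],
                        noise_seed = seed + 200L + i, n_frames = n_frames)
  })
  kd <- list(grid = kd_grid, images = kd_images)

  f_max <- system$f_max_cm
  prof_d <- seq(0, 20, by = 4)
  half_extent <- field_side_at_detector_cm(f_max, system$geometry) / 2 + 2
  n_coarse <- 2L * ceiling(half_extent * 10 / array_spacing_mm) + 1L
  coarse_x <- (seq_len(n_coarse) - (n_coarse + 1) / 2) * array_spacing_mm / 10
  array_profiles <- lapply(prof_d, function(d) {
    dd <- true_dose_at_points(system, f_max, d, coarse_x, coarse_x)
    list(grid = dd / dd[(n_coarse + 1) %/% 2, (n_coarse + 1) %/% 2],
         spacing_mm = array_spacing_mm)
  })
  prof_images <- lapply(seq_along(prof_d), function(k) {
    simulate_epid_image(system, f_max, prof_d[k],
                        noise_seed = seed + 300L + k, n_frames = n_frames)
  })
  kprofile <- list(f_max_cm = f_max, thickness_cm = prof_d,
                   array_profiles = array_profiles, images = prof_images)

  list(reference = reference, kf = kf, kd = kd, kprofile = kprofile,
       geometry = system$geometry, detector = system$detector,
       f_ref_cm = f_ref, seed = seed)
}
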