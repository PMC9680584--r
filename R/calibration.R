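#' Calibration configuration
#'
#' @param roi_side_cm Side of the central averaging window at the detector
#'   plane (cm); 1 cm (25 pixels at the default panel).
#' @param out_of_range Policy for field-size / thickness queries outside the
#'   calibrated support: `"clamp_with_warning"` returns the nearest support
#'   value and warns, `"error"` raises.
#' @param profile_floor Relative signal level (fraction of the beam-axis
#'   value) below which the profile-correction ratio is undefined and set
#'   to 1 (no correction where there is no signal).
#' @param gamma Default gamma-analysis parameters, see [gamma_params()].
#' @return A `calibration_config` object.
#' @export
calibration_config <- function(roi_side_cm = 1,
                               out_of_range = c("clamp_with_warning", "error"),
                               profile_floor = 1e-3,
                               gamma = gamma_params()) {
  out_of_range <- match.arg(out_of_range)
  if (roi_side_cm <= 0) stop("roi_side_cm must be positive", call. = FALSE)
  structure(list(roi_side_cm = roi_side_cm, out_of_range = out_of_range,
                 profile_floor = profile_floor, gamma = gamma),
            class = "calibration_config")
}

# Clamp a query to the calibrated support according to the configured policy.
clamp_support <- function(x, lo, hi, policy, what) {
  out_low <- x < lo
  out_high <- x > hi
  if (any(out_low | out_high)) {
    msg <- sprintf("%s outside calibrated support [%g, %g]", what, lo, hi)
    if (policy == "error") stop(msg, call. = FALSE)
    warning(paste0(msg, "; clamping to the nearest support value"),
            call. = FALSE)
    x <- pmin(pmax(x, lo), hi)
  }
  x
}

roi_mean_checked <- function(image, roi_side_cm, what = "image") {
  m <- central_roi_mean(image, roi_side_cm)
  if (!is.finite(m) || m <= .Machine$double.eps) {
    stop(sprintf("degenerate %s: central ROI mean is zero", what),
         call. = FALSE)
  }
  m
}

#' Cross-calibration factor N
#'
#' Converts central gray values into absorbed dose to water under reference
#' conditions (reference field, no phantom):
#' `N = s_ref * D_ref(0,0) / mean(I_ref)` where the mean is taken over the
#' central region of interest.
#'
#' @param dose_ref_gy Ionization-chamber dose (Gy) at the beam axis under
#'   reference conditions.
#' @param image_ref Reference-field [epid_image()].
#' @param f_ref_cm Reference nominal field side (cm).
#' @param d_ref_cm Reference phantom thickness (cm); 0 = open beam.
#' @param config A [calibration_config()].
#' @return A `calibration_factor` object with fields `N` (Gy per gray-value
#'   unit), `s_ref`, `f_ref_cm`, `d_ref_cm`.
#' @export
compute_calibration_factor <- function(dose_ref_gy, image_ref,
                                       f_ref_cm = 10, d_ref_cm = 0,
                                       config = calibration_config()) {
  if (!is.numeric(dose_ref_gy) || dose_ref_gy <= 0) {
    stop("reference dose must be positive", call. = FALSE)
  }
  m <- roi_mean_checked(image_ref, config$roi_side_cm, "reference image")
  structure(list(N = image_ref$scaling_factor * dose_ref_gy / m,
                 s_ref = image_ref$scaling_factor,
                 f_ref_cm = f_ref_cm, d_ref_cm = d_ref_cm),
            class = "calibration_factor")
}

#' Field-size correction factor for one field
#'
#' Ratio of dose-per-signal at the clinical field size to that at the
#' reference field size, both without phantom:
#' `k_f = (D_clin / mean(I_clin)) / (D_ref / mean(I_ref))`. Values below 1
#' correct a signal over-response (small fields), values above 1 an
#' under-response (large fields).
#'
#' @param dose_clin_gy,image_clin Chamber dose and portal image at the
#'   clinical field size.
#' @param dose_ref_gy,image_ref Chamber dose and portal image at the
#'   reference field size.
#' @param config A [calibration_config()].
#' @return Scalar k_f.
#' @export
compute_field_size_factor <- function(dose_clin_gy, image_clin,
                                      dose_ref_gy, image_ref,
                                      config = calibration_config()) {
  if (dose_clin_gy <= 0 || dose_ref_gy <= 0) {
    stop("doses must be positive", call. = FALSE)
  }
  m_clin <- roi_mean_checked(image_clin, config$roi_side_cm, "clinical image") /
    image_clin$scaling_factor
  m_ref <- roi_mean_checked(image_ref, config$roi_side_cm, "reference image") /
    image_ref$scaling_factor
  (dose_clin_gy / m_clin) / (dose_ref_gy / m_ref)
}

#' Thickness correction factor for one (field, thickness) pair
#'
#' Ratio of dose-per-signal behind the phantom to that of the open beam at
#' the same field size: `k_d = (D_d / mean(I_d)) / (D_0 / mean(I_0))`.
#'
#' @param dose_d_gy,image_d Chamber dose and portal image behind thickness d.
#' @param dose_0_gy,image_0 Chamber dose and portal image at d = 0, same
#'   field size.
#' @param config A [calibration_config()].
#' @return Scalar k_d.
#' @export
compute_thickness_factor <- function(dose_d_gy, image_d,
                                     dose_0_gy, image_0,
                                     config = calibration_config()) {
  if (dose_d_gy <= 0 || dose_0_gy <= 0) {
    stop("doses must be positive", call. = FALSE)
  }
  m_d <- roi_mean_checked(image_d, config$roi_side_cm, "phantom image") /
    image_d$scaling_factor
  m_0 <- roi_mean_checked(image_0, config$roi_side_cm, "open-beam image") /
    image_0$scaling_factor
  (dose_d_gy / m_d) / (dose_0_gy / m_0)
}

#' Build the field-size correction table
#'
#' Stores (field side, k_f) support points for piecewise-linear
#' interpolation. The entry at the reference field is forced to exactly 1
#' (it is 1 by definition; measured values may carry rounding noise).
#'
#' @param field_cm Nominal field sides (cm), distinct; must include `f_ref_cm`.
#' @param kf Corresponding k_f values (> 0).
#' @param f_ref_cm Reference field side (cm).
#' @return A `kf_table` object, sorted by field side.
#' @export
build_kf_table <- function(field_cm, kf, f_ref_cm = 10) {
  if (length(field_cm) != length(kf) || length(field_cm) < 2) {
    stop("need at least two (field, k_f) entries", call. = FALSE)
  }
  if (anyDuplicated(field_cm)) {
    stop("duplicate field sizes in k_f table", call. = FALSE)
  }
  i_ref <- which(abs(field_cm - f_ref_cm) < 1e-9)
  if (length(i_ref) != 1L) {
    stop("k_f table must contain the reference field size", call. = FALSE)
  }
  if (abs(kf[i_ref] - 1) > 1e-3) {
    warning("k_f at the reference field deviates from 1 by more than 0.1%; ",
            "forcing to 1", call. = FALSE)
  }
  kf[i_ref] <- 1
  if (any(kf <= 0)) stop("k_f values must be positive", call. = FALSE)
  ord <- order(field_cm)
  structure(list(field_cm = field_cm[ord], kf = kf[ord], f_ref_cm = f_ref_cm),
            class = "kf_table")
}

#' Field-size correction lookup
#'
#' Exact at support points, piecewise linear between them; outside the
#' support the configured out-of-range policy applies.
#'
#' @param table A [build_kf_table()] result.
#' @param field_cm Nominal field side(s) (cm), > 0.
#' @param config A [calibration_config()].
#' @return k_f value(s).
#' @export
lookup_kf <- function(table, field_cm, config = calibration_config()) {
  if (any(!is.finite(field_cm)) || any(field_cm <= 0)) {
    stop("field size must be positive", call. = FALSE)
  }
  f <- clamp_support(field_cm, min(table$field_cm), max(table$field_cm),
                     config$out_of_range, "field size")
  stats::approx(table$field_cm, table$kf, xout = f, method = "linear")$y
}

#' Build the thickness correction table
#'
#' For each calibrated field side, fits the measured k_d(d) values with a
#' least-squares third-degree polynomial hard-constrained through (0, 1)
#' (the correction is exactly 1 at the reference thickness by definition).
#' Lookups evaluate the per-field cubic and interpolate linearly across
#' field sides.
#'
#' @param grid Data frame with columns `field_cm`, `thickness_cm`, `kd`;
#'   every field side needs >= 4 thickness points including 0.
#' @return A `kd_table` object with the measured grid and the fitted cubic
#'   coefficients per field side.
#' @export
build_kd_table <- function(grid) {
  need <- c("field_cm", "thickness_cm", "kd")
  if (!all(need %in% names(grid))) {
    stop("grid needs columns field_cm, thickness_cm, kd", call. = FALSE)
  }
  if (any(grid$kd <= 0)) stop("k_d values must be positive", call. = FALSE)
  fields <- sort(unique(grid$field_cm))
  coefs <- matrix(NA_real_, length(fields), 3,
                  dimnames = list(NULL, c("c1", "c2", "c3")))
  for (i in seq_along(fields)) {
    sub <- grid[grid$field_cm == fields[i], ]
    if (nrow(sub) < 4) {
      stop(sprintf("field %g cm: need >= 4 thickness points for a cubic fit",
                   fields[i]), call. = FALSE)
    }
    if (!any(sub$thickness_cm == 0)) {
      stop(sprintf("field %g cm: thickness grid must include d = 0",
                   fields[i]), call. = FALSE)
    }
    d <- sub$thickness_cm
    # constrained through (0, 1): fit k_d - 1 on d, d^2, d^3 without intercept
    fit <- stats::lm.fit(cbind(d, d^2, d^3), sub$kd - 1)
    coefs[i, ] <- fit$coefficients
  }
  structure(list(field_cm = fields,
                 thickness_cm = sort(unique(grid$thickness_cm)),
                 grid = grid[order(grid$field_cm, grid$thickness_cm), ],
                 coef = coefs),
            class = "kd_table")
}

# Evaluate the constrained cubic of field-row i at thicknesses d.
kd_eval_cubic <- function(table, i, d) {
  co <- unname(table$coef[i, ])
  1 + co[1] * d + co[2] * d^2 + co[3] * d^3
}

#' Thickness correction lookup
#'
#' Evaluates the fitted cubic of the two bracketing field sides at the
#' requested thickness and interpolates linearly in field side. Queries
#' outside the calibrated support follow the configured policy.
#'
#' @param table A [build_kd_table()] result.
#' @param field_cm Nominal field side (cm), scalar.
#' @param thickness_cm Water-equivalent thickness(es) (cm), >= 0; may be a
#'   vector or matrix for per-pixel evaluation.
#' @param config A [calibration_config()].
#' @return k_d value(s) with the shape of `thickness_cm`.
#' @export
lookup_kd <- function(table, field_cm, thickness_cm,
                      config = calibration_config()) {
  if (any(thickness_cm < 0)) stop("thickness must be >= 0", call. = FALSE)
  if (length(field_cm) != 1L || field_cm <= 0) {
    stop("field size must be a positive scalar", call. = FALSE)
  }
  dims <- dim(thickness_cm)
  d <- clamp_support(as.numeric(thickness_cm),
                     min(table$thickness_cm), max(table$thickness_cm),
                     config$out_of_range, "thickness")
  f <- clamp_support(field_cm, min(table$field_cm), max(table$field_cm),
                     config$out_of_range, "field size")
  fs <- table$field_cm
  if (length(fs) == 1L) {
    out <- kd_eval_cubic(table, 1L, d)
  } else {
    i <- findInterval(f, fs, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(fs) - 1L)
    w <- (f - fs[i]) / (fs[i + 1] - fs[i])
    out <- (1 - w) * kd_eval_cubic(table, i, d) +
      w * kd_eval_cubic(table, i + 1L, d)
  }
  if (!is.null(dims)) dim(out) <- dims
  out
}

#' Build the lateral profile-correction set
#'
#' For each calibrated thickness, both the array profile and the portal
#' image are center-normalized and their pointwise ratio is resampled onto
#' the detector pixel lattice. The stored maps therefore equal 1 on the
#' beam axis, and the absolute dose scale is carried exclusively by
#' `N * k_f * k_d`. The ratio is formed at the coarse array positions (the
#' portal image is sampled there bilinearly) and then interpolated to the
#' full grid: the steep field-edge penumbra, present identically in both
#' profiles, cancels in the ratio before any interpolation touches it, so
#' the correction map stays smooth across the field edge. Where the
#' normalized portal signal falls below `profile_floor` the ratio is
#' undefined and set to 1.
#'
#' @param array_profiles List (one per thickness) of lists with elements
#'   `grid` (coarse relative dose matrix, beam-axis centered) and
#'   `spacing_mm`.
#' @param epid_images List of [epid_image()]s, same thicknesses, ascending.
#' @param thickness_cm Ascending thicknesses (cm) including 0.
#' @param f_max_cm Field side (cm) the profiles were measured with.
#' @param config A [calibration_config()].
#' @return A `kprofile_set` object.
#' @export
build_profile_set <- function(array_profiles, epid_images, thickness_cm,
                              f_max_cm = 15, config = calibration_config()) {
  n <- length(thickness_cm)
  if (length(array_profiles) != n || length(epid_images) != n) {
    stop("array profiles, portal images and thickness list must match",
         call. = FALSE)
  }
  if (is.unsorted(thickness_cm, strictly = TRUE) || thickness_cm[1] != 0) {
    stop("thicknesses must be strictly ascending and include 0", call. = FALSE)
  }
  detector <- epid_images[[1]]$detector
  pitch_cm <- detector$pixel_pitch_mm / 10
  maps <- vector("list", n)
  for (k in seq_len(n)) {
    arr <- array_profiles[[k]]$grid
    spacing_mm <- array_profiles[[k]]$spacing_mm
    arr_axis <- beam_axis_value(arr)
    img <- epid_images[[k]]$grid
    img_axis <- beam_axis_value(img)
    if (!is.finite(arr_axis) || arr_axis <= .Machine$double.eps ||
        !is.finite(img_axis) || img_axis <= .Machine$double.eps) {
      stop("degenerate input: zero beam-axis value", call. = FALSE)
    }
    arr_rel <- arr / arr_axis
    # portal image sampled at the coarse array positions
    img_rows <- (nrow(img) + 1) / 2 +
      (seq_len(nrow(arr)) - (nrow(arr) + 1) / 2) * spacing_mm / 10 / pitch_cm
    img_cols <- (ncol(img) + 1) / 2 +
      (seq_len(ncol(arr)) - (ncol(arr) + 1) / 2) * spacing_mm / 10 / pitch_cm
    img_rel <- resample_separable(img, img_rows, img_cols) / img_axis
    ratio <- matrix(1, nrow(arr_rel), ncol(arr_rel))
    ok <- img_rel > config$profile_floor
    ratio[ok] <- arr_rel[ok] / img_rel[ok]
    ratio <- resample_to_epid_grid(ratio, spacing_mm, detector)
    # re-anchor the beam axis exactly at 1 (guards resampling round-off)
    ratio <- ratio / beam_axis_value(ratio)
    maps[[k]] <- ratio
  }
  structure(list(f_max_cm = f_max_cm, thickness_cm = thickness_cm,
                 maps = maps, detector = detector),
            class = "kprofile_set")
}

#' Profile-correction map for arbitrary field size and thickness
#'
#' Interpolates linearly (pixelwise) between the two calibrated thickness
#' maps bracketing `thickness_cm`, then rescales the map laterally about
#' the beam axis to the requested field size: the output at detector
#' offset (x, y) is the interpolated map sampled at
#' `(x * f_max / f, y * f_max / f)` (bilinear, clamped to the map boundary).
#' For `f = f_max` and a stored thickness the stored map is returned
#' unchanged.
#'
#' @param set A [build_profile_set()] result.
#' @param field_cm Nominal field side (cm), > 0.
#' @param thickness_cm Scalar water-equivalent thickness (cm), >= 0.
#' @param config A [calibration_config()].
#' @return Correction-map matrix on the detector grid.
#' @export
get_profile_map <- function(set, field_cm, thickness_cm,
                            config = calibration_config()) {
  if (length(field_cm) != 1L || !is.finite(field_cm) || field_cm <= 0) {
    stop("field size must be a positive scalar", call. = FALSE)
  }
  if (thickness_cm < 0) stop("thickness must be >= 0", call. = FALSE)
  d <- clamp_support(thickness_cm, min(set$thickness_cm), max(set$thickness_cm),
                     config$out_of_range, "thickness")
  m <- profile_interp_thickness(set, d)
  rescale_about_axis(m, set$f_max_cm / field_cm)
}

# Linear interpolation between stored thickness maps (scalar thickness).
profile_interp_thickness <- function(set, d) {
  td <- set$thickness_cm
  if (d <= td[1]) return(set$maps[[1]])
  if (d >= td[length(td)]) return(set$maps[[length(td)]])
  i <- findInterval(d, td)
  if (td[i] == d) return(set$maps[[i]])
  w <- (d - td[i]) / (td[i + 1] - td[i])
  (1 - w) * set$maps[[i]] + w * set$maps[[i + 1]]
}

# Lateral rescale about the beam axis by `scale`; scale > 1 compresses the
# feature pattern (samples further out), scale < 1 expands it. Identity for
# scale == 1 (bit-identical).
rescale_about_axis <- function(grid, scale) {
  if (scale == 1) return(grid)
  cr <- (nrow(grid) + 1) / 2
  cc <- (ncol(grid) + 1) / 2
  resample_separable(grid,
                     cr + (seq_len(nrow(grid)) - cr) * scale,
                     cc + (seq_len(ncol(grid)) - cc) * scale)
}

#' Assemble a calibration model
#'
#' @param factor A [compute_calibration_factor()] result.
#' @param kf_table A [build_kf_table()] result.
#' @param kd_table A [build_kd_table()] result.
#' @param profile_set A [build_profile_set()] result.
#' @param geometry,detector Shared beam geometry and detector specification.
#' @param config A [calibration_config()].
#' @return A `calibration_model` object.
#' @export
calibration_model <- function(factor, kf_table, kd_table, profile_set,
                              geometry, detector,
                              config = calibration_config()) {
  stopifnot(inherits(factor, "calibration_factor"),
            inherits(kf_table, "kf_table"),
            inherits(kd_table, "kd_table"),
            inherits(profile_set, "kprofile_set"))
  if (profile_set$detector$n_rows != detector$n_rows ||
      profile_set$detector$n_cols != detector$n_cols) {
    stop("profile set detector grid does not match the model detector",
         call. = FALSE)
  }
  structure(list(factor = factor, kf = kf_table, kd = kd_table,
                 profiles = profile_set, geometry = geometry,
                 detector = detector, config = config),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("EPID dose calibration model\n")
  cat(sprintf("  N = %.6g Gy per gray-value unit (f_ref %g cm, d_ref %g cm, s_ref %g)\n",
              x$factor$N, x$factor$f_ref_cm, x$factor$d_ref_cm, x$factor$s_ref))
  cat(sprintf("  k_f support: %g - %g cm (%d points)\n",
              min(x$kf$field_cm), max(x$kf$field_cm), length(x$kf$field_cm)))
  cat(sprintf("  k_d support: fields {%s} cm, thickness %g - %g cm\n",
              paste(x$kd$field_cm, collapse = ", "),
              min(x$kd$thickness_cm), max(x$kd$thickness_cm)))
  cat(sprintf("  k_profile: f_max %g cm, %d thickness maps on %d x %d grid\n",
              x$profiles$f_max_cm, length(x$profiles$maps),
              x$detector$n_rows, x$detector$n_cols))
  invisible(x)
}

#' Build a calibration model from a measurement bundle
#'
#' Runs the full calibration workflow on a fixture bundle (as produced by
#' [generate_calibration_dataset()] or read from disk with
#' [read_fixture_bundle()]): computes N from the reference pair, the k_f
#' table from the field-size series, the k_d table from the
#' field-by-thickness grid, and the profile-correction set from the array
#' and portal profile pairs.
#'
#' @param dataset Fixture bundle (see [generate_calibration_dataset()]).
#' @param config A [calibration_config()].
#' @return A [calibration_model()].
#' @export
build_calibration_model <- function(dataset, config = calibration_config()) {
  ref <- dataset$reference
  fac <- compute_calibration_factor(ref$dose_gy, ref$image,
                                    f_ref_cm = dataset$f_ref_cm,
                                    d_ref_cm = 0, config = config)
  kf_vals <- vapply(seq_along(dataset$kf$field_cm), function(i) {
    compute_field_size_factor(dataset$kf$dose_gy[i], dataset$kf$images[[i]],
                              ref$dose_gy, ref$image, config = config)
  }, numeric(1))
  kf_tab <- build_kf_table(dataset$kf$field_cm, kf_vals,
                           f_ref_cm = dataset$f_ref_cm)

  kd_df <- dataset$kd$grid
  kd_vals <- numeric(nrow(kd_df))
  for (i in seq_len(nrow(kd_df))) {
    i0 <- which(kd_df$field_cm == kd_df$field_cm[i] & kd_df$thickness_cm == 0)
    kd_vals[i] <- compute_thickness_factor(
      kd_df$dose_gy[i], dataset$kd$images[[i]],
      kd_df$dose_gy[i0], dataset$kd$images[[i0]], config = config)
  }
  kd_tab <- build_kd_table(data.frame(field_cm = kd_df$field_cm,
                                      thickness_cm = kd_df$thickness_cm,
                                      kd = kd_vals))

  prof <- build_profile_set(dataset$kprofile$array_profiles,
                            dataset$kprofile$images,
                            dataset$kprofile$thickness_cm,
                            f_max_cm = dataset$kprofile$f_max_cm,
                            config = config)
  calibration_model(fac, kf_tab, kd_tab, prof,
                    geometry = dataset$geometry,
                    detector = dataset$detector, config = config)
}
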