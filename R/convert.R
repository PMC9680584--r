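#' Convert a portal image into an absolute dose-to-water map
#'
#' Applies the full calibration chain at the detector plane:
#' `D(x,y) = N * I(x,y)/s * k_f(f) * k_d(f, d) * k_profile(x, y, d; f)`.
#' The nominal field size `f` is taken from the image metadata when present,
#' otherwise estimated from the image with [estimate_field_size()]
#' (enclosing-square assignment). A scalar thickness applies one `k_d` value
#' and one profile map; a per-pixel thickness map (e.g. from
#' [project_phantom_thickness()]) evaluates `k_d` and the thickness
#' interpolation of the profile correction pixelwise, while the lateral
#' rescale still uses the single enclosing-square field size.
#'
#' @param model A [calibration_model()].
#' @param image An [epid_image()] on the model's detector grid.
#' @param thickness_cm Scalar water-equivalent thickness (cm), or a matrix of
#'   per-pixel thicknesses on the detector grid. Defaults to the image
#'   metadata entry, else 0.
#' @return A [dose_map()] of kind `"absolute_Gy"`.
#' @export
convert_image_to_dose <- function(model, image, thickness_cm = NULL) {
  if (nrow(image$grid) != model$detector$n_rows ||
      ncol(image$grid) != model$detector$n_cols) {
    stop("image does not match the model's detector grid", call. = FALSE)
  }
  if (is.null(thickness_cm)) {
    thickness_cm <- if (!is.null(image$meta$thickness_cm)) {
      image$meta$thickness_cm
    } else 0
  }
  if (any(thickness_cm < 0)) stop("thickness must be >= 0", call. = FALSE)

  f <- image$meta$field_cm
  if (is.null(f)) f <- estimate_field_size(image, model$geometry)

  cfg <- model$config
  kf <- lookup_kf(model$kf, f, cfg)

  if (is.matrix(thickness_cm)) {
    if (!all(dim(thickness_cm) == dim(image$grid))) {
      stop("per-pixel thickness map must match the image dimensions",
           call. = FALSE)
    }
    kd <- lookup_kd(model$kd, f, thickness_cm, cfg)
    kp <- profile_map_per_pixel(model$profiles, f, thickness_cm, cfg)
  } else {
    kd <- lookup_kd(model$kd, f, thickness_cm, cfg)
    kp <- get_profile_map(model$profiles, f, thickness_cm, cfg)
  }

  dose <- model$factor$N * image$grid / image$scaling_factor * kf * kd * kp
  dose_map(pmax(dose, 0), kind = "absolute_Gy",
           detector = model$detector, geometry = model$geometry)
}

# Per-pixel-thickness profile correction: every stored thickness map is
# laterally rescaled to the requested field size, then the thickness
# interpolation is carried out pixelwise with each pixel's own thickness.
profile_map_per_pixel <- function(set, field_cm, thickness_cm, config) {
  td <- set$thickness_cm
  d <- clamp_support(as.numeric(thickness_cm), min(td), max(td),
                     config$out_of_range, "thickness")
  scale <- set$f_max_cm / field_cm
  maps <- lapply(set$maps, rescale_about_axis, scale = scale)
  k <- length(td)
  if (k == 1L) return(maps[[1]])
  i <- pmin(pmax(findInterval(d, td), 1L), k - 1L)
  w <- (d - td[i]) / (td[i + 1] - td[i])
  npx <- length(d)
  a <- array(unlist(maps, use.names = FALSE), dim = c(npx, k))
  lo <- a[cbind(seq_len(npx), i)]
  hi <- a[cbind(seq_len(npx), i + 1L)]
  out <- (1 - w) * lo + w * hi
  dim(out) <- dim(thickness_cm)
  out
}
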