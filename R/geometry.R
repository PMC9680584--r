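#' Beam geometry of the linac / portal-imager arrangement
#'
#' Describes the fixed source-to-detector and source-to-axis distances of the
#' treatment machine. Nominal field sizes are defined at the isocenter plane
#' (at the source-axis distance); the portal imager sits further downstream,
#' so lateral lengths are magnified by `sdd/sad` at the detector plane.
#'
#' @param source_detector_distance_cm Source-to-detector distance (cm).
#' @param source_axis_distance_cm Source-to-isocenter distance (cm).
#' @return A `beam_geometry` object with fields `sdd_cm`, `sad_cm` and the
#'   derived `magnification = sdd/sad`.
#' @examples
#' g <- beam_geometry()
#' g$magnification  # 1.6
#' @export
beam_geometry <- function(source_detector_distance_cm = 160,
                          source_axis_distance_cm = 100) {
  sdd <- source_detector_distance_cm
  sad <- source_axis_distance_cm
  if (!is.numeric(sdd) || !is.numeric(sad) || length(sdd) != 1L ||
      length(sad) != 1L || !is.finite(sdd) || !is.finite(sad)) {
    stop("distances must be finite numeric scalars", call. = FALSE)
  }
  if (sad <= 0 || sdd < sad) {
    stop("require sdd >= sad > 0", call. = FALSE)
  }
  structure(
    list(sdd_cm = sdd, sad_cm = sad, magnification = sdd / sad),
    class = "beam_geometry"
  )
}

#' Detector panel specification
#'
#' @param n_rows,n_cols Number of detector elements per axis.
#' @param pixel_pitch_mm Element spacing (mm) at the detector plane.
#' @param active_side_cm Active side length of the panel (cm); must agree with
#'   `n_cols * pixel_pitch_mm` to within 0.5 cm.
#' @return A `detector_spec` object.
#' @examples
#' detector_spec()$pixel_pitch_mm  # 0.4 mm = 41 cm / 1024
#' @export
detector_spec <- function(n_rows = 1024, n_cols = 1024,
                          pixel_pitch_mm = 0.4, active_side_cm = 41) {
  if (n_rows < 2 || n_cols < 2 || pixel_pitch_mm <= 0 || active_side_cm <= 0) {
    stop("detector dimensions must be positive (>= 2 elements per axis)",
         call. = FALSE)
  }
  if (abs(n_cols * pixel_pitch_mm / 10 - active_side_cm) > 0.5) {
    stop("pixel pitch inconsistent with active side length (> 0.5 cm off)",
         call. = FALSE)
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pixel_pitch_mm = pixel_pitch_mm, active_side_cm = active_side_cm),
    class = "detector_spec"
  )
}

#' Pixel-center coordinates at the detector plane
#'
#' The beam axis pierces the panel at the grid center, i.e. at continuous
#' (1-based) index `(n + 1) / 2` on each axis; for an even number of elements
#' it falls between the two central pixels. Coordinates are in cm.
#'
#' @param detector A [detector_spec()].
#' @return List with numeric vectors `x_cm` (columns) and `y_cm` (rows).
#' @export
pixel_centers_cm <- function(detector) {
  pitch_cm <- detector$pixel_pitch_mm / 10
  list(
    x_cm = (seq_len(detector$n_cols) - (detector$n_cols + 1) / 2) * pitch_cm,
    y_cm = (seq_len(detector$n_rows) - (detector$n_rows + 1) / 2) * pitch_cm
  )
}

#' Convert a nominal (isocenter) field side to its detector-plane side
#'
#' @param field_cm Nominal square field side at the isocenter (cm).
#' @param geometry A [beam_geometry()].
#' @return Side length at the detector plane (cm).
#' @export
field_side_at_detector_cm <- function(field_cm, geometry) {
  stopifnot(is.numeric(field_cm), all(field_cm > 0))
  field_cm * geometry$magnification
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("Beam geometry: SDD %.1f cm, SAD %.1f cm (magnification %.3f)\n",
              x$sdd_cm, x$sad_cm, x$magnification))
  invisible(x)
}

#' @export
print.detector_spec <- function(x, ...) {
  cat(sprintf("Detector: %d x %d elements, %.4g mm pitch, %.3g cm active side\n",
              x$n_rows, x$n_cols, x$pixel_pitch_mm, x$active_side_cm))
  invisible(x)
}
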