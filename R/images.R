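#' Portal image container
#'
#' Holds the raw, unitless gray-value grid delivered by the acquisition
#' software together with the vendor pixel scaling factor `s` (the software
#' scale that converts the acquired panel signal into displayable gray
#' values; every image is divided by its own `s` before dose conversion).
#'
#' @param grid Numeric matrix of gray values (finite, >= 0); rows index the
#'   detector y axis, columns the x axis.
#' @param scaling_factor Pixel scaling factor `s` (> 0), per image.
#' @param detector A [detector_spec()] matching `dim(grid)`.
#' @param geometry A [beam_geometry()].
#' @param meta Optional named list; recognized entries are `field_cm`
#'   (nominal square field side) and `thickness_cm`.
#' @return An `epid_image` object.
#' @export
epid_image <- function(grid, scaling_factor = 1,
                       detector = NULL, geometry = beam_geometry(),
                       meta = list()) {
  if (!is.matrix(grid) || !is.numeric(grid)) {
    stop("grid must be a numeric matrix", call. = FALSE)
  }
  if (is.null(detector)) {
    detector <- detector_spec(n_rows = nrow(grid), n_cols = ncol(grid),
                              pixel_pitch_mm = 410 / ncol(grid))
  }
  if (nrow(grid) != detector$n_rows || ncol(grid) != detector$n_cols) {
    stop("grid dimensions do not match the detector specification",
         call. = FALSE)
  }
  if (any(!is.finite(grid)) || any(grid < 0)) {
    stop("gray values must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(scaling_factor) || length(scaling_factor) != 1L ||
      scaling_factor <= 0) {
    stop("scaling factor s must be a positive scalar", call. = FALSE)
  }
  structure(
    list(grid = grid, scaling_factor = scaling_factor,
         detector = detector, geometry = geometry, meta = meta),
    class = "epid_image"
  )
}

#' Dose map container
#'
#' @param grid Numeric matrix of dose values; finite and >= 0.
#' @param kind Either `"absolute_Gy"` or `"relative"` (center-normalized;
#'   the beam-axis sample equals 1 within 1e-9).
#' @param detector A [detector_spec()] matching `dim(grid)`.
#' @param geometry A [beam_geometry()].
#' @return A `dose_map` object.
#' @export
dose_map <- function(grid, kind = c("absolute_Gy", "relative"),
                     detector = NULL, geometry = beam_geometry()) {
  kind <- match.arg(kind)
  if (!is.matrix(grid) || !is.numeric(grid)) {
    stop("grid must be a numeric matrix", call. = FALSE)
  }
  if (is.null(detector)) {
    detector <- detector_spec(n_rows = nrow(grid), n_cols = ncol(grid),
                              pixel_pitch_mm = 410 / ncol(grid))
  }
  if (nrow(grid) != detector$n_rows || ncol(grid) != detector$n_cols) {
    stop("grid dimensions do not match the detector specification",
         call. = FALSE)
  }
  if (any(!is.finite(grid)) || any(grid < 0)) {
    stop("dose values must be finite and non-negative", call. = FALSE)
  }
  if (kind == "relative") {
    ax <- beam_axis_value(grid)
    if (abs(ax - 1) > 1e-9) {
      stop("relative dose map must equal 1 at the beam-axis sample",
           call. = FALSE)
    }
  }
  structure(
    list(grid = grid, kind = kind, detector = detector, geometry = geometry),
    class = "dose_map"
  )
}

#' @export
print.epid_image <- function(x, ...) {
  cat(sprintf("EPID image %d x %d, s = %.4g, gray range [%.4g, %.4g]\n",
              nrow(x$grid), ncol(x$grid), x$scaling_factor,
              min(x$grid), max(x$grid)))
  if (!is.null(x$meta$field_cm)) {
    cat(sprintf("  nominal field %.3g cm", x$meta$field_cm))
    if (!is.null(x$meta$thickness_cm)) {
      cat(sprintf(", thickness %.3g cm", mean(x$meta$thickness_cm)))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
print.dose_map <- function(x, ...) {
  unit <- if (x$kind == "absolute_Gy") "Gy" else "(relative)"
  cat(sprintf("Dose map %d x %d %s, range [%.4g, %.4g], axis %.6g\n",
              nrow(x$grid), ncol(x$grid), unit, min(x$grid), max(x$grid),
              beam_axis_value(x$grid)))
  invisible(x)
}

# --- bilinear sampling -------------------------------------------------------

#' Bilinear sampling on a separable lattice
#'
#' Samples `grid` at all combinations of the fractional (1-based) row and
#' column coordinates. Coordinates outside the grid are clamped to the
#' boundary (nearest-edge continuation); integer coordinates reproduce the
#' stored values exactly.
#'
#' @param grid Numeric matrix.
#' @param rows,cols Fractional 1-based coordinates.
#' @return Matrix of dimension `length(rows) x length(cols)`.
#' @export
resample_separable <- function(grid, rows, cols) {
  nr <- nrow(grid); nc <- ncol(grid)
  rows <- pmin(pmax(rows, 1), nr)
  cols <- pmin(pmax(cols, 1), nc)
  r0 <- pmin(floor(rows), nr - 1L); r1 <- r0 + 1L; fr <- rows - r0
  c0 <- pmin(floor(cols), nc - 1L); c1 <- c0 + 1L; fc <- cols - c0
  g00 <- grid[r0, c0, drop = FALSE]
  g10 <- grid[r1, c0, drop = FALSE]
  g01 <- grid[r0, c1, drop = FALSE]
  g11 <- grid[r1, c1, drop = FALSE]
  wr <- matrix(fr, nrow = length(rows), ncol = length(cols))
  wc <- matrix(fc, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  (1 - wr) * ((1 - wc) * g00 + wc * g01) + wr * ((1 - wc) * g10 + wc * g11)
}

# Bilinear sample at arbitrary (row, col) fractional coordinate pairs.
bilinear_at <- function(grid, rows, cols) {
  nr <- nrow(grid); nc <- ncol(grid)
  rows <- pmin(pmax(rows, 1), nr)
  cols <- pmin(pmax(cols, 1), nc)
  r0 <- pmin(floor(rows), nr - 1L); fr <- rows - r0
  c0 <- pmin(floor(cols), nc - 1L); fc <- cols - c0
  (1 - fr) * (1 - fc) * grid[cbind(r0, c0)] +
    (1 - fr) * fc * grid[cbind(r0, c0 + 1L)] +
    fr * (1 - fc) * grid[cbind(r0 + 1L, c0)] +
    fr * fc * grid[cbind(r0 + 1L, c0 + 1L)]
}

#' Beam-axis sample of a grid
#'
#' Bilinear sample at the grid center (continuous index `(n+1)/2` per axis).
#' On an even-sized grid this is the mean of the four central elements; on an
#' odd-sized grid it is the central element itself.
#'
#' @param grid Numeric matrix.
#' @return Scalar sample value.
#' @export
beam_axis_value <- function(grid) {
  bilinear_at(grid, (nrow(grid) + 1) / 2, (ncol(grid) + 1) / 2)
}

#' Central lateral profile of a grid
#'
#' The profile along the detector x axis through the beam axis, obtained by
#' bilinear sampling at y = 0 (for an even number of rows: the mean of the
#' two central rows).
#'
#' @param grid Numeric matrix.
#' @return Numeric vector of length `ncol(grid)`.
#' @export
central_profile <- function(grid) {
  as.numeric(resample_separable(grid, (nrow(grid) + 1) / 2, seq_len(ncol(grid))))
}

#' Resample a coarse measurement grid onto the detector pixel lattice
#'
#' Bilinear interpolation of a coarse, beam-axis-centered grid (e.g. a 2D
#' ionization-chamber array profile) onto the full detector grid; positions
#' outside the coarse support take the nearest boundary value.
#'
#' @param coarse Numeric matrix (>= 2 x 2), centered on the beam axis.
#' @param spacing_mm Coarse grid spacing (mm) at the detector plane.
#' @param detector Target [detector_spec()].
#' @return Numeric matrix of dimension `n_rows x n_cols`.
#' @export
resample_to_epid_grid <- function(coarse, spacing_mm, detector) {
  if (!is.matrix(coarse) || nrow(coarse) < 2 || ncol(coarse) < 2) {
    stop("coarse grid must be a matrix with at least 2 x 2 points",
         call. = FALSE)
  }
  if (!is.numeric(spacing_mm) || spacing_mm <= 0) {
    stop("spacing must be positive", call. = FALSE)
  }
  cc <- pixel_centers_cm(detector)
  # coarse pixel centers: index (n+1)/2 sits on the beam axis
  rows <- (nrow(coarse) + 1) / 2 + cc$y_cm * 10 / spacing_mm
  cols <- (ncol(coarse) + 1) / 2 + cc$x_cm * 10 / spacing_mm
  resample_separable(coarse, rows, cols)
}
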