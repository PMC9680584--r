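#' Otsu threshold of a gray-value sample
#'
#' Classic histogram threshold maximizing the between-class variance,
#' computed on 256 equal-width bins after min-max normalization, with no
#' pre-smoothing. Returned on the original gray-value scale.
#'
#' @param values Numeric vector or matrix with non-degenerate range.
#' @param n_bins Number of histogram bins.
#' @return Threshold value; pixels strictly above it belong to the field.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (length(v) == 0L || rng[1] == rng[2]) {
    stop("image has no dynamic range; cannot locate a field", call. = FALSE)
  }
  u <- (v - rng[1]) / (rng[2] - rng[1])
  idx <- pmin(floor(u * n_bins), n_bins - 1L)  # bin index 0..n_bins-1
  counts <- tabulate(idx + 1L, nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b)  # threshold between bin k and k+1
  rng[1] + (k / n_bins) * (rng[2] - rng[1])
}

#' Estimate the nominal field size from a portal image
#'
#' Thresholds the image with the Otsu method, takes the axis-aligned bounding
#' box of the above-threshold pixels, and assigns the field to the square
#' that encloses it: the side is the larger of the box width and height,
#' converted from the detector plane to the isocenter plane via the
#' geometric magnification. Rectangular or irregular fields are thereby
#' assigned their enclosing square.
#'
#' @param image An [epid_image()].
#' @param geometry A [beam_geometry()]; defaults to the image's.
#' @return Nominal square field side at the isocenter (cm).
#' @export
estimate_field_size <- function(image, geometry = image$geometry) {
  thr <- otsu_threshold(image$grid)
  mask <- image$grid > thr
  if (!any(mask)) {
    stop("no field found: empty mask after thresholding", call. = FALSE)
  }
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  side_px <- max(rows[2] - rows[1] + 1L, cols[2] - cols[1] + 1L)
  side_det_cm <- side_px * image$detector$pixel_pitch_mm / 10
  side_det_cm / geometry$magnification
}

#' Mean gray value in the central region of interest
#'
#' Arithmetic mean over a centered square window of
#' `round(roi_side_cm * 10 / pixel_pitch_mm)` pixels per side (25 pixels at
#' the default panel). When the window parity does not allow exact
#' centering, the window shifts half a pixel toward the origin
#' (start index `floor((n - w) / 2)`, 0-based), which is deterministic and
#' symmetric for matching parities.
#'
#' @param image An [epid_image()] (or [dose_map()]).
#' @param roi_side_cm Window side at the detector plane (cm).
#' @return Mean gray value in the window.
#' @export
central_roi_mean <- function(image, roi_side_cm = 1) {
  if (!is.numeric(roi_side_cm) || roi_side_cm <= 0) {
    stop("roi_side_cm must be positive", call. = FALSE)
  }
  grid <- image$grid
  w <- max(1L, as.integer(round(roi_side_cm * 10 / image$detector$pixel_pitch_mm)))
  if (w > nrow(grid) || w > ncol(grid)) {
    stop("ROI larger than the image", call. = FALSE)
  }
  r0 <- floor((nrow(grid) - w) / 2)
  c0 <- floor((ncol(grid) - w) / 2)
  mean(grid[(r0 + 1L):(r0 + w), (c0 + 1L):(c0 + w)])
}

#' Slab phantom description
#'
#' An ordered stack of homogeneous slabs, each with a physical thickness and
#' a density relative to the RW3 reference material.
#'
#' @param thickness_cm Numeric vector of slab thicknesses (cm, >= 0).
#' @param rel_density Densities relative to RW3 (>= 0); recycled.
#' @return A `slab_stack` object (a data.frame).
#' @export
slab_stack <- function(thickness_cm = numeric(0), rel_density = numeric(0)) {
  if (length(thickness_cm) > 0 && length(rel_density) == 0) rel_density <- 1
  if (any(thickness_cm < 0)) stop("slab thicknesses must be >= 0", call. = FALSE)
  if (any(rel_density < 0)) stop("relative densities must be >= 0", call. = FALSE)
  out <- data.frame(thickness_cm = as.numeric(thickness_cm),
                    rel_density = rep_len(as.numeric(rel_density),
                                          length(thickness_cm)))
  class(out) <- c("slab_stack", class(out))
  out
}

#' Water-equivalent thickness of a slab stack
#'
#' Each slab thickness is scaled by its density relative to the reference
#' material (RW3), and the contributions are summed.
#'
#' @param stack A [slab_stack()].
#' @param reference_density Density of the reference material the relative
#'   densities refer to (defaults to 1, i.e. densities already relative).
#' @return Water-equivalent thickness (cm).
#' @export
effective_thickness <- function(stack, reference_density = 1) {
  if (nrow(stack) == 0) return(0)
  sum(stack$thickness_cm * stack$rel_density / reference_density)
}

#' Two-dimensional water-equivalent thickness phantom
#'
#' A grid of water-equivalent thickness values defined at the isocenter
#' plane, centered on the beam axis.
#'
#' @param grid Numeric matrix of water-equivalent thickness (cm, >= 0).
#' @param spacing_cm Grid spacing (cm) at the isocenter plane.
#' @return A `phantom_map` object.
#' @export
phantom_map <- function(grid, spacing_cm) {
  if (!is.matrix(grid) || any(!is.finite(grid)) || any(grid < 0)) {
    stop("phantom grid must be a finite, non-negative matrix", call. = FALSE)
  }
  if (!is.numeric(spacing_cm) || spacing_cm <= 0) {
    stop("spacing must be positive", call. = FALSE)
  }
  structure(list(grid = grid, spacing_cm = spacing_cm), class = "phantom_map")
}

#' Build a phantom map from axis-aligned rectangular regions
#'
#' Convenience constructor: rectangles are specified at the isocenter plane
#' in cm relative to the beam axis; later regions overwrite earlier ones.
#'
#' @param regions List of lists with fields `x_min`, `x_max`, `y_min`,
#'   `y_max` (cm) and `wet_cm` (water-equivalent thickness).
#' @param extent_cm Total side length of the phantom grid (cm).
#' @param spacing_cm Grid spacing (cm).
#' @return A [phantom_map()].
#' @export
phantom_map_from_regions <- function(regions, extent_cm = 30, spacing_cm = 0.1) {
  n <- max(2L, as.integer(round(extent_cm / spacing_cm)))
  x <- (seq_len(n) - (n + 1) / 2) * spacing_cm
  grid <- matrix(0, n, n)
  for (rg in regions) {
    cols <- which(x >= rg$x_min & x <= rg$x_max)
    rows <- which(x >= rg$y_min & x <= rg$y_max)
    if (length(rows) && length(cols)) grid[rows, cols] <- rg$wet_cm
  }
  phantom_map(grid, spacing_cm)
}

#' Project phantom thickness onto the detector grid
#'
#' Maps each detector pixel back along the divergent ray through the source
#' to the isocenter plane (lateral scale `1/magnification`) and assigns the
#' phantom's water-equivalent thickness there (nearest grid value);
#' positions outside the phantom grid are treated as air (0 cm).
#'
#' @param phantom A [phantom_map()].
#' @param geometry A [beam_geometry()].
#' @param detector A [detector_spec()].
#' @return Matrix of per-pixel water-equivalent thickness (cm) on the
#'   detector grid.
#' @export
project_phantom_thickness <- function(phantom, geometry, detector) {
  cc <- pixel_centers_cm(detector)
  # isocenter-plane coordinates of each detector pixel
  xi <- cc$x_cm / geometry$magnification
  yi <- cc$y_cm / geometry$magnification
  pg <- phantom$grid
  rows <- round((nrow(pg) + 1) / 2 + yi / phantom$spacing_cm)
  cols <- round((ncol(pg) + 1) / 2 + xi / phantom$spacing_cm)
  rin <- rows >= 1 & rows <= nrow(pg)
  cin <- cols >= 1 & cols <= ncol(pg)
  out <- matrix(0, detector$n_rows, detector$n_cols)
  if (any(rin) && any(cin)) {
    out[rin, cin] <- pg[rows[rin], cols[cin]]
  }
  out
}
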