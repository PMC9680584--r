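#' Gamma-analysis parameters
#'
#' @param dose_difference_percent Dose-difference criterion (percent of the
#'   global reference maximum).
#' @param distance_to_agreement_mm Distance-to-agreement criterion (mm).
#' @param low_dose_threshold_percent Reference points below this percentage
#'   of the global reference maximum are excluded from evaluation.
#' @param search_radius_mm Radius of the spatial search; must be at least
#'   the distance-to-agreement (default 3 x DTA).
#' @param subsample_factor The evaluated map is sampled on a lattice refined
#'   by this factor (bilinear) so the search resolves sub-pixel distances.
#' @param normalization Only `"global"` is provided.
#' @return A `gamma_params` object.
#' @export
gamma_params <- function(dose_difference_percent = 3,
                         distance_to_agreement_mm = 3,
                         low_dose_threshold_percent = 10,
                         search_radius_mm = 3 * distance_to_agreement_mm,
                         subsample_factor = 3L,
                         normalization = "global") {
  if (dose_difference_percent <= 0 || distance_to_agreement_mm <= 0 ||
      low_dose_threshold_percent <= 0 || subsample_factor < 1) {
    stop("gamma parameters must be positive", call. = FALSE)
  }
  if (search_radius_mm < distance_to_agreement_mm) {
    stop("search radius must be >= distance-to-agreement", call. = FALSE)
  }
  normalization <- match.arg(normalization, "global")
  structure(list(dose_difference_percent = dose_difference_percent,
                 distance_to_agreement_mm = distance_to_agreement_mm,
                 low_dose_threshold_percent = low_dose_threshold_percent,
                 search_radius_mm = search_radius_mm,
                 subsample_factor = as.integer(subsample_factor),
                 normalization = normalization),
            class = "gamma_params")
}

#' 2D gamma index between a reference and an evaluated dose map
#'
#' For every reference point above the low-dose threshold, the gamma index
#' is the minimum over evaluated positions `e` within the search radius of
#' `sqrt((dD/(dd% * Dmax))^2 + (|r - e| / DTA)^2)`, with the evaluated map
#' sampled bilinearly on a lattice refined by the subsample factor and the
#' dose difference normalized globally to the reference maximum. A point
#' passes the criterion when gamma <= 1.
#'
#' @param reference Reference [dose_map()] (planning / ground-truth dose).
#' @param evaluated Evaluated [dose_map()] (EPID-derived dose), same grid.
#' @param params A [gamma_params()].
#' @return A `gamma_result` with elements `gamma` (matrix; `NA` outside the
#'   evaluated mask), `mask` (logical matrix), `pass_rate_pct`, `params`.
#' @export
compute_gamma <- function(reference, evaluated, params = gamma_params()) {
  ref <- reference$grid
  ev <- evaluated$grid
  if (!all(dim(ref) == dim(ev))) {
    stop("reference and evaluated maps must share the same grid",
         call. = FALSE)
  }
  pitch <- reference$detector$pixel_pitch_mm
  d_max <- max(ref)
  if (d_max <= 0) stop("degenerate reference: maximum dose is zero",
                       call. = FALSE)
  dd_abs <- params$dose_difference_percent / 100 * d_max
  mask <- ref >= params$low_dose_threshold_percent / 100 * d_max

  step_px <- 1 / params$subsample_factor
  r_px <- params$search_radius_mm / pitch
  k <- ceiling(r_px / step_px)
  off <- expand.grid(dr = (-k:k) * step_px, dc = (-k:k) * step_px)
  dist2_mm <- (off$dr^2 + off$dc^2) * pitch^2
  keep <- dist2_mm <= params$search_radius_mm^2 + 1e-12
  off <- off[keep, ]
  dist2_mm <- dist2_mm[keep]
  ord <- order(dist2_mm)
  off <- off[ord, ]
  s2 <- dist2_mm[ord] / params$distance_to_agreement_mm^2

  rows <- seq_len(nrow(ref))
  cols <- seq_len(ncol(ref))
  gamma2 <- ((ev - ref) / dd_abs)^2  # offset (0, 0)
  worst <- if (any(mask)) max(gamma2[mask]) else Inf
  for (m in seq_along(s2)[-1]) {
    if (s2[m] >= worst) break  # larger offsets cannot improve any point
    shifted <- resample_separable(ev, rows + off$dr[m], cols + off$dc[m])
    cand <- ((shifted - ref) / dd_abs)^2 + s2[m]
    gamma2 <- pmin(gamma2, cand)
    worst <- if (any(mask)) max(gamma2[mask]) else Inf
  }
  g <- sqrt(gamma2)
  g[!mask] <- NA_real_
  res <- structure(list(gamma = g, mask = mask, params = params,
                        pass_rate_pct = NA_real_),
                   class = "gamma_result")
  res$pass_rate_pct <- if (any(mask)) pass_rate(res) else NA_real_
  res
}

#' Gamma pass rate
#'
#' Percentage of evaluated points (reference points above the low-dose
#' threshold) whose gamma index does not exceed the pass threshold.
#'
#' @param result A [compute_gamma()] result.
#' @param threshold Pass threshold on gamma (1 by convention). Ties at the
#'   threshold are decided with a relative 1e-12 guard so that points
#'   sitting exactly on the criterion (e.g. a uniform offset of exactly the
#'   dose-difference tolerance) count as passing despite floating-point
#'   round-off.
#' @return Pass rate in percent.
#' @export
pass_rate <- function(result, threshold = 1) {
  g <- result$gamma[result$mask]
  if (length(g) == 0L) {
    stop("no evaluated points above the low-dose threshold", call. = FALSE)
  }
  100 * mean(g <= threshold * (1 + 1e-12))
}

#' @export
print.gamma_result <- function(x, ...) {
  p <- x$params
  cat(sprintf("Gamma analysis (%g%%, %g mm, %s, %g%% threshold)\n",
              p$dose_difference_percent, p$distance_to_agreement_mm,
              p$normalization, p$low_dose_threshold_percent))
  cat(sprintf("  evaluated points: %d; pass rate: %.2f%%; mean gamma: %.3f\n",
              sum(x$mask), x$pass_rate_pct, mean(x$gamma[x$mask])))
  invisible(x)
}
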