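# Readers and writers: plain-text grids, 16-bit TIFF portal images with
# JSON sidecars, chamber CSV tables, fixture-bundle directories, and the
# calibration-model archive.

#' Read / write a plain-text numeric grid
#'
#' Space-separated values, one grid row per line, full double precision
#' (`%.17g`; the round trip is exact).
#'
#' @param path File path.
#' @param grid Numeric matrix.
#' @return `read_grid` returns a numeric matrix.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty grid file: ", path, call. = FALSE)
  rows <- strsplit(trimws(lines), "[[:space:]]+")
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    stop("ragged grid file (truncated?): ", path, call. = FALSE)
  }
  matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
}

#' @rdname read_grid
#' @export
write_grid <- function(grid, path) {
  stopifnot(is.matrix(grid))
  lines <- apply(grid, 1L, function(r) paste(sprintf("%.17g", r),
                                             collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Write a portal image as 16-bit TIFF with a JSON sidecar
#'
#' Gray values are scaled into the 16-bit range by `gray_max` (recorded in
#' the sidecar together with the pixel scaling factor `s`, the pixel pitch
#' and any field/thickness metadata).
#'
#' @param image An [epid_image()].
#' @param path Output path (`.tif`); the sidecar is written to `path.json`.
#' @return `path`, invisibly.
#' @export
write_portal_tiff <- function(image, path) {
  gray_max <- max(image$grid)
  if (gray_max <= 0) gray_max <- 1
  tiff::writeTIFF(image$grid / gray_max, path, bits.per.sample = 16L,
                  compression = "none")
  sidecar <- list(s = image$scaling_factor, gray_max = gray_max,
                  pixel_pitch_mm = image$detector$pixel_pitch_mm,
                  sdd_cm = image$geometry$sdd_cm,
                  sad_cm = image$geometry$sad_cm)
  if (!is.null(image$meta$field_cm)) sidecar$field_cm <- image$meta$field_cm
  if (!is.null(image$meta$thickness_cm)) {
    sidecar$thickness_cm <- image$meta$thickness_cm
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a portal image from disk
#'
#' Supports 16-bit TIFF (with optional JSON sidecar carrying the pixel
#' scaling factor and metadata) and plain-text grids. The detector
#' specification is inferred from the image dimensions (41 cm panel)
#' unless supplied.
#'
#' @param path Image path (`.tif`, `.tiff`, or plain-text grid).
#' @param s_override Pixel scaling factor used when no sidecar provides one.
#' @param detector Optional [detector_spec()]; must match the image size.
#' @param geometry A [beam_geometry()].
#' @return An [epid_image()].
#' @export
load_portal_image <- function(path, s_override = NULL, detector = NULL,
                              geometry = beam_geometry()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  meta <- list()
  s <- s_override
  if (ext %in% c("tif", "tiff")) {
    grid <- tryCatch(tiff::readTIFF(path),
                     error = function(e) stop("unreadable TIFF: ", path,
                                              call. = FALSE))
    if (is.array(grid) && length(dim(grid)) == 3L) grid <- grid[, , 1]
    gray_max <- 1
    sidecar_path <- paste0(path, ".json")
    if (file.exists(sidecar_path)) {
      sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
      if (!is.null(sc$s)) s <- sc$s
      if (!is.null(sc$gray_max)) gray_max <- sc$gray_max
      if (!is.null(sc$field_cm)) meta$field_cm <- sc$field_cm
      if (!is.null(sc$thickness_cm)) meta$thickness_cm <- sc$thickness_cm
      if (!is.null(sc$sdd_cm) && !is.null(sc$sad_cm)) {
        geometry <- beam_geometry(sc$sdd_cm, sc$sad_cm)
      }
      if (is.null(detector) && !is.null(sc$pixel_pitch_mm)) {
        detector <- detector_spec(nrow(grid), ncol(grid), sc$pixel_pitch_mm,
                                  ncol(grid) * sc$pixel_pitch_mm / 10)
      }
    }
    grid <- grid * gray_max
  } else {
    grid <- read_grid(path)
  }
  if (is.null(s)) s <- 1
  epid_image(grid, scaling_factor = s, detector = detector,
             geometry = geometry, meta = meta)
}

#' Read / write chamber readings and correction tables as CSV
#'
#' Comma-separated, dot decimal, mandatory header. Columns: `field_cm`,
#' `thickness_cm`, and `dose_Gy` or `k_value`.
#'
#' @param path CSV path.
#' @param table Data frame to write.
#' @return `read_measurement_csv` returns a data.frame.
#' @export
read_measurement_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!"field_cm" %in% names(df)) {
    stop("CSV must have a field_cm column", call. = FALSE)
  }
  df
}

#' @rdname read_measurement_csv
#' @export
write_measurement_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- fixture bundles ---------------------------------------------------------

#' Write / read a calibration fixture bundle directory
#'
#' Layout: `manifest.json` (design, seed, geometry, detector), chamber
#' readings in `chamber.csv`, portal images as 16-bit TIFF with sidecars,
#' and the coarse detector-array profiles as plain-text grids.
#'
#' @param dataset Bundle as returned by [generate_calibration_dataset()].
#' @param dir Directory path.
#' @return `read_fixture_bundle` returns a bundle list suitable for
#'   [build_calibration_model()].
#' @export
write_fixture_bundle <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  det <- dataset$detector
  geo <- dataset$geometry
  manifest <- list(
    schema = "epidcal-bundle", version = 1L,
    f_ref_cm = dataset$f_ref_cm, seed = dataset$seed,
    detector = det[c("n_rows", "n_cols", "pixel_pitch_mm", "active_side_cm")],
    geometry = list(sdd_cm = geo$sdd_cm, sad_cm = geo$sad_cm),
    kf_field_cm = dataset$kf$field_cm,
    kd_field_cm = unique(dataset$kd$grid$field_cm),
    kd_thickness_cm = unique(dataset$kd$grid$thickness_cm),
    kprofile_f_max_cm = dataset$kprofile$f_max_cm,
    kprofile_thickness_cm = dataset$kprofile$thickness_cm,
    array_spacing_mm = dataset$kprofile$array_profiles[[1]]$spacing_mm)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17))

  chamber <- rbind(
    data.frame(role = "reference", field_cm = dataset$f_ref_cm,
               thickness_cm = 0, dose_Gy = dataset$reference$dose_gy),
    data.frame(role = "kf", field_cm = dataset$kf$field_cm,
               thickness_cm = 0, dose_Gy = dataset$kf$dose_gy),
    data.frame(role = "kd", field_cm = dataset$kd$grid$field_cm,
               thickness_cm = dataset$kd$grid$thickness_cm,
               dose_Gy = dataset$kd$grid$dose_gy))
  write_measurement_csv(chamber, file.path(dir, "chamber.csv"))

  write_portal_tiff(dataset$reference$image, file.path(dir, "reference.tif"))
  for (i in seq_along(dataset$kf$field_cm)) {
    write_portal_tiff(dataset$kf$images[[i]],
                      file.path(dir, sprintf("kf_f%02d.tif",
                                             dataset$kf$field_cm[i])))
  }
  for (i in seq_len(nrow(dataset$kd$grid))) {
    write_portal_tiff(dataset$kd$images[[i]],
                      file.path(dir, sprintf("kd_f%02d_d%02d.tif",
                                             dataset$kd$grid$field_cm[i],
                                             dataset$kd$grid$thickness_cm[i])))
  }
  for (k in seq_along(dataset$kprofile$thickness_cm)) {
    d <- dataset$kprofile$thickness_cm[k]
    write_portal_tiff(dataset$kprofile$images[[k]],
                      file.path(dir, sprintf("kprofile_d%02d.tif", d)))
    write_grid(dataset$kprofile$array_profiles[[k]]$grid,
               file.path(dir, sprintf("array_d%02d.txt", d)))
  }
  invisible(dir)
}

#' @rdname write_fixture_bundle
#' @export
read_fixture_bundle <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) {
    stop("not a fixture bundle (no manifest.json): ", dir, call. = FALSE)
  }
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (is.null(man$schema) || man$schema != "epidcal-bundle") {
    stop("unrecognized bundle schema", call. = FALSE)
  }
  det <- detector_spec(man$detector$n_rows, man$detector$n_cols,
                       man$detector$pixel_pitch_mm,
                       man$detector$active_side_cm)
  geo <- beam_geometry(man$geometry$sdd_cm, man$geometry$sad_cm)
  chamber <- read_measurement_csv(file.path(dir, "chamber.csv"))
  load_img <- function(name) {
    load_portal_image(file.path(dir, name), detector = det, geometry = geo)
  }
  ref_dose <- chamber$dose_Gy[chamber$role == "reference"][1]
  reference <- list(dose_gy = ref_dose, image = load_img("reference.tif"))

  kf_fields <- man$kf_field_cm
  kf <- list(
    field_cm = kf_fields,
    dose_gy = vapply(kf_fields, function(f) {
      chamber$dose_Gy[chamber$role == "kf" & chamber$field_cm == f][1]
    }, numeric(1)),
    images = lapply(kf_fields, function(f) {
      load_img(sprintf("kf_f%02d.tif", f))
    }))

  kd_grid <- expand.grid(thickness_cm = man$kd_thickness_cm,
                         field_cm = man$kd_field_cm)[, 2:1]
  kd_grid$dose_gy <- vapply(seq_len(nrow(kd_grid)), function(i) {
    chamber$dose_Gy[chamber$role == "kd" &
                      chamber$field_cm == kd_grid$field_cm[i] &
                      chamber$thickness_cm == kd_grid$thickness_cm[i]][1]
  }, numeric(1))
  kd <- list(grid = kd_grid,
             images = lapply(seq_len(nrow(kd_grid)), function(i) {
               load_img(sprintf("kd_f%02d_d%02d.tif", kd_grid$field_cm[i],
                                kd_grid$thickness_cm[i]))
             }))

  prof_d <- man$kprofile_thickness_cm
  kprofile <- list(
    f_max_cm = man$kprofile_f_max_cm, thickness_cm = prof_d,
    array_profiles = lapply(prof_d, function(d) {
      list(grid = read_grid(file.path(dir, sprintf("array_d%02d.txt", d))),
           spacing_mm = man$array_spacing_mm)
    }),
    images = lapply(prof_d, function(d) {
      load_img(sprintf("kprofile_d%02d.tif", d))
    }))

  list(reference = reference, kf = kf, kd = kd, kprofile = kprofile,
       geometry = geo, detector = det, f_ref_cm = man$f_ref_cm,
       seed = man$seed)
}

# --- calibration-model archive -----------------------------------------------

#' Save / load a calibration model archive
#'
#' The archive is a directory with a JSON manifest (schema version,
#' geometry, detector, calibration factor, k_f and k_d tables, configuration)
#' plus one full-precision plain-text grid per profile-correction thickness
#' map. The round trip reproduces all scalars exactly and all maps
#' bit-identically.
#'
#' @param model A [calibration_model()].
#' @param path Archive directory.
#' @return `load_model` returns the reconstructed [calibration_model()].
#' @export
save_model <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  man <- list(
    schema = "epidcal-model", version = 1L,
    geometry = list(sdd_cm = model$geometry$sdd_cm,
                    sad_cm = model$geometry$sad_cm),
    detector = model$detector[c("n_rows", "n_cols", "pixel_pitch_mm",
                                "active_side_cm")],
    factor = unclass(model$factor),
    kf = list(field_cm = model$kf$field_cm, kf = model$kf$kf,
              f_ref_cm = model$kf$f_ref_cm),
    kd = list(field_cm = model$kd$field_cm,
              thickness_cm = model$kd$thickness_cm,
              coef = lapply(seq_along(model$kd$field_cm), function(i) {
                as.numeric(model$kd$coef[i, ])
              }),
              grid = model$kd$grid),
    kprofile = list(f_max_cm = model$profiles$f_max_cm,
                    thickness_cm = model$profiles$thickness_cm),
    config = list(roi_side_cm = model$config$roi_side_cm,
                  out_of_range = model$config$out_of_range,
                  profile_floor = model$config$profile_floor))
  jsonlite::write_json(man, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17))
  for (k in seq_along(model$profiles$maps)) {
    write_grid(model$profiles$maps[[k]],
               file.path(path, sprintf("kprofile_d%02d.txt",
                                       model$profiles$thickness_cm[k])))
  }
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath)) {
    stop("not a model archive (no manifest.json): ", path, call. = FALSE)
  }
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (is.null(man$schema) || man$schema != "epidcal-model") {
    stop("unrecognized model schema", call. = FALSE)
  }
  if (is.null(man$version) || man$version != 1L) {
    stop("incompatible model archive version: ",
         if (is.null(man$version)) "missing" else man$version, call. = FALSE)
  }
  required <- c("geometry", "detector", "factor", "kf", "kd", "kprofile",
                "config")
  missing <- setdiff(required, names(man))
  if (length(missing)) {
    stop("model manifest is missing required entries: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(man$factor$N) || !is.numeric(man$factor$N) ||
      man$factor$N <= 0) {
    stop("model manifest validation failed: calibration factor N missing ",
         "or invalid", call. = FALSE)
  }
  det <- detector_spec(man$detector$n_rows, man$detector$n_cols,
                       man$detector$pixel_pitch_mm,
                       man$detector$active_side_cm)
  geo <- beam_geometry(man$geometry$sdd_cm, man$geometry$sad_cm)
  cfg <- calibration_config(roi_side_cm = man$config$roi_side_cm,
                            out_of_range = man$config$out_of_range,
                            profile_floor = man$config$profile_floor)
  fac <- structure(list(N = man$factor$N, s_ref = man$factor$s_ref,
                        f_ref_cm = man$factor$f_ref_cm,
                        d_ref_cm = man$factor$d_ref_cm),
                   class = "calibration_factor")
  kf_tab <- build_kf_table(man$kf$field_cm, man$kf$kf,
                           f_ref_cm = man$kf$f_ref_cm)
  coef <- man$kd$coef
  if (is.list(coef)) coef <- do.call(rbind, coef)
  coef <- matrix(as.numeric(coef), ncol = 3,
                 dimnames = list(NULL, c("c1", "c2", "c3")))
  kd_grid <- as.data.frame(man$kd$grid)
  kd_tab <- structure(list(field_cm = man$kd$field_cm,
                           thickness_cm = man$kd$thickness_cm,
                           grid = kd_grid, coef = coef),
                      class = "kd_table")
  prof_d <- man$kprofile$thickness_cm
  maps <- lapply(prof_d, function(d) {
    read_grid(file.path(path, sprintf("kprofile_d%02d.txt", d)))
  })
  prof <- structure(list(f_max_cm = man$kprofile$f_max_cm,
                         thickness_cm = prof_d, maps = maps,
                         detector = det),
                    class = "kprofile_set")
  calibration_model(fac, kf_tab, kd_tab, prof, geometry = geo,
                    detector = det, config = cfg)
}

# --- descriptions and run configs --------------------------------------------

#' Read a phantom description from YAML or JSON
#'
#' Two forms are supported: a slab list
#' (`slabs: [{thickness_cm: ..., rel_density: ...}, ...]`) producing a
#' [slab_stack()], and a 2D region phantom
#' (`phantom: {extent_cm: ..., spacing_cm: ..., regions: [{x_min, x_max,
#' y_min, y_max, wet_cm}, ...]}`) producing a [phantom_map()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [slab_stack()] or [phantom_map()].
#' @export
read_phantom_description <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  desc <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    stop("unsupported phantom description format: .", ext, call. = FALSE)
  }
  if (!is.null(desc$slabs)) {
    th <- vapply(desc$slabs, function(s) as.numeric(s$thickness_cm), 0)
    rd <- vapply(desc$slabs, function(s) {
      if (is.null(s$rel_density)) 1 else as.numeric(s$rel_density)
    }, 0)
    return(slab_stack(th, rd))
  }
  if (!is.null(desc$phantom)) {
    ph <- desc$phantom
    return(phantom_map_from_regions(
      ph$regions,
      extent_cm = if (is.null(ph$extent_cm)) 30 else ph$extent_cm,
      spacing_cm = if (is.null(ph$spacing_cm)) 0.1 else ph$spacing_cm))
  }
  stop("phantom description needs a 'slabs' or 'phantom' entry",
       call. = FALSE)
}

#' Read a YAML run configuration for the command-line interface
#'
#' Keys mirror the CLI options; unknown keys are rejected. Command-line
#' options take precedence over the file.
#'
#' @param path YAML file.
#' @return Named list of options.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  allowed <- c("seed", "out", "n", "noise", "segments", "bundle", "model",
               "image", "thickness", "s", "ref", "eval", "dd", "dta",
               "threshold", "gamma-out", "strict", "verbose")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown run-config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg
}
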