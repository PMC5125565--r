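#' Calibrated RGB image
#'
#' Container for an 8-bit RGB brightfield image together with its physical
#' pixel calibration. A pixel is a square of side `um_per_px` micrometres;
#' the grid is row-major with the origin at the top-left corner.
#'
#' @param pixels numeric array `h x w x 3` with channel values in `[0, 255]`.
#' @param um_per_px micrometres per pixel edge (positive).
#' @param sample_id sample identifier string.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, um_per_px = 0.275, sample_id = "sample") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an h x w x 3 array")
  if (any(dim(pixels)[1:2] < 1L)) stop("image grid must be non-empty")
  if (!is.numeric(um_per_px) || length(um_per_px) != 1L || !is.finite(um_per_px) ||
      um_per_px <= 0)
    stop("`um_per_px` must be a positive number")
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
    stop("channel values must lie in [0, 255]")
  structure(list(pixels = pixels, um_per_px = um_per_px,
                 sample_id = as.character(sample_id)),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_image> %s: %d x %d px @ %g um/px (%.3f x %.3f mm)\n",
              x$sample_id, d[1], d[2], x$um_per_px,
              d[1] * x$um_per_px / 1000, d[2] * x$um_per_px / 1000))
  invisible(x)
}

#' Integer label mask with a legend
#'
#' @param labels integer matrix; 0 means unassigned, other values must be
#'   listed in `legend`.
#' @param legend named character vector mapping label value (name) to region
#'   name, e.g. `c("1" = "CTCL")`.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, legend) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  if (length(legend) < 1L || is.null(names(legend)))
    stop("`legend` must be a non-empty named vector")
  keys <- as.integer(names(legend))
  if (anyNA(keys) || any(keys <= 0L)) stop("legend keys must be positive integers")
  used <- sort(unique(as.integer(labels)))
  extra <- setdiff(used, c(0L, keys))
  if (length(extra))
    stop("labels not covered by legend: ", paste(extra, collapse = ", "))
  structure(list(labels = labels, legend = setNames(as.character(legend),
                                                    as.character(keys))),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px; regions: %s\n",
              nrow(x$labels), ncol(x$labels),
              paste(sprintf("%s=%s", names(x$legend), x$legend), collapse = " ")))
  invisible(x)
}

# sidecar path for calibration / legend metadata
sidecar_path <- function(path) paste0(path, ".json")

#' Read a calibrated image from TIFF or PNG
#'
#' The calibration is taken, in order of precedence, from the `um_per_px`
#' argument, a JSON sidecar written by [write_calibrated_image()], embedded
#' resolution metadata (TIFF resolution tags or PNG dpi), and finally
#' `default_um_per_px`. The default of 0.275 um/pixel corresponds to a 20x
#' brightfield scan.
#'
#' @param path image file path (`.tif`, `.tiff`, `.png`).
#' @param um_per_px explicit calibration override, or `NULL`.
#' @param default_um_per_px fallback calibration.
#' @param sample_id sample identifier; defaults to the file name.
#' @return A [calibrated_image()].
#' @export
load_calibrated_image <- function(path, um_per_px = NULL,
                                  default_um_per_px = 0.275,
                                  sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.null(um_per_px) && (!is.finite(um_per_px) || um_per_px <= 0))
    stop("`um_per_px` must be positive")
  ext <- tolower(tools::file_ext(path))
  meta_upp <- NA_real_
  arr <- switch(ext,
    tif = , tiff = {
      a <- tryCatch(tiff::readTIFF(path, info = TRUE),
                    error = function(e) stop("unreadable TIFF: ", path,
                                             " (", conditionMessage(e), ")"))
      xres <- attr(a, "x.resolution")
      unit <- attr(a, "resolution.unit")
      if (!is.null(xres) && is.finite(xres) && xres > 0) {
        if (identical(unit, "cm")) meta_upp <- 1e4 / xres
        else if (is.null(unit) || identical(unit, "inch")) meta_upp <- 25400 / xres
      }
      a
    },
    png = {
      a <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) stop("unreadable PNG: ", path,
                                             " (", conditionMessage(e), ")"))
      info <- attr(a, "info")
      if (!is.null(info$dpi) && all(is.finite(info$dpi)) && info$dpi[1] > 0)
        meta_upp <- 25400 / info$dpi[1]
      a
    },
    stop("unsupported image format: .", ext)
  )
  if (is.na(meta_upp) && file.exists(sidecar_path(path))) {
    sc <- tryCatch(jsonlite::read_json(sidecar_path(path)), error = function(e) NULL)
    if (!is.null(sc$um_per_px) && is.finite(sc$um_per_px) && sc$um_per_px > 0)
      meta_upp <- as.numeric(sc$um_per_px)
  }
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  arr <- array(as.numeric(arr), dim(arr))   # drop reader metadata attributes
  upp <- if (!is.null(um_per_px)) um_per_px
         else if (is.finite(meta_upp)) meta_upp
         else default_um_per_px
  if (is.null(sample_id)) sample_id <- tools::file_path_sans_ext(basename(path))
  calibrated_image(round(arr * 255), um_per_px = upp, sample_id = sample_id)
}

#' Write a calibrated image
#'
#' TIFF output stores the calibration in a JSON sidecar (`<path>.json`);
#' PNG output embeds it in the dpi field as well.
#'
#' @param image a [calibrated_image()].
#' @param path output path (`.tif`/`.tiff`/`.png`).
#' @export
write_calibrated_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  ext <- tolower(tools::file_ext(path))
  arr <- pmin(pmax(image$pixels, 0), 255) / 255
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(arr, path, dpi = 25400 / image$um_per_px)
  } else stop("unsupported image format: .", ext)
  jsonlite::write_json(list(um_per_px = image$um_per_px,
                            sample_id = image$sample_id),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a label mask as 16-bit TIFF plus JSON legend sidecar
#'
#' The round trip is exact label-for-label for labels up to 65535.
#'
#' @param mask a [label_mask()].
#' @param path output `.tif` path; the legend goes to `<path>.json`.
#' @export
write_region_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 65535L) stop("labels exceed 16-bit range")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  jsonlite::write_json(list(legend = as.list(mask$legend)),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_region_mask
#' @return `read_region_mask` returns the reconstructed [label_mask()].
#' @export
read_region_mask <- function(path) {
  labels <- round(tiff::readTIFF(path) * 65535)
  storage.mode(labels) <- "integer"
  sc <- jsonlite::read_json(sidecar_path(path))
  legend <- unlist(sc$legend)
  label_mask(labels, legend)
}

#' Write a per-sample, per-region metrics table as CSV
#'
#' One row per (sample, region), sorted by sample id and region in the order
#' CTCL, P1, P2. Undefined ratios (e.g. percent degranulated where no mast
#' cell was found) are written as empty fields. The decimal separator is
#' always `.`.
#'
#' @param rows a data frame of sample metrics (rows from
#'   [compute_sample_metrics()], possibly concatenated).
#' @param path output CSV path.
#' @export
write_metrics_table <- function(rows, path) {
  cols <- c("sample_id", "group", "stage", "region", "area_mm2", "total_cells",
            "mc_count", "mc_per_mm2", "mc_pct_of_cells", "pct_degranulated")
  if (is.null(rows) || nrow(rows) == 0L) {
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  for (cn in setdiff(cols, names(rows))) rows[[cn]] <- NA
  rows <- rows[, cols]
  ord <- order(rows$sample_id, match(rows$region, c("CTCL", "P1", "P2")))
  rows <- rows[ord, , drop = FALSE]
  write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pipeline run configuration
#'
#' All tunable parameters of the pipeline with their defaults. Physical
#' parameters are in micrometres (or as stated); densities in cells/mm^2;
#' optical densities in OD units.
#'
#' @param um_per_px default calibration (um/pixel) used when an image carries
#'   none.
#' @param d1_um,d2_um outer edges of the P1 and P2 proximity bands.
#' @param parzen_sigma_um Gaussian bandwidth of the Parzen density estimator.
#' @param parzen_decim integer decimation factor for density evaluation
#'   (1 = full grid; larger values evaluate on a coarse grid and bilinearly
#'   upsample).
#' @param rho_min cell-density threshold (cells/mm^2) defining the lymphoma
#'   infiltrate.
#' @param infiltrate_close_um,infiltrate_min_area_mm2 morphological closing
#'   radius and minimum component area for the infiltrate mask.
#' @param tissue_od_min,tissue_close_um,tissue_min_area_mm2 background
#'   exclusion: OD-sum threshold, closing radius, minimum component area.
#' @param epidermis_max_depth_um,epidermis_close_um epidermis heuristic:
#'   maximal depth of the surface collar searched and closing radius.
#' @param nuc_sigma_um,nuc_od_floor,nuc_d_min_um,nuc_d_max_um,nuc_min_sep_um,nuc_ws_tol_um
#'   nuclear segmentation: smoothing sigma, absolute OD floor under the Otsu
#'   threshold, equivalent-diameter gates, minimum centroid separation, and
#'   watershed merge tolerance.
#' @param mc_od_floor,mc_median_um,mc_a_noise_um2,mc_r_link_um,mc_a_min_um2,mc_a_body_um2,mc_s_min
#'   mast-cell detection: tryptase OD floor, median-filter radius, minimum
#'   blob area, single-linkage radius, minimum cluster area, minimum compact
#'   body area, and minimum solidity of a non-degranulated body.
#' @param alpha two-sided significance level.
#' @param zero_method handling of zero paired differences: `"drop"`
#'   (classic) or `"pratt"`.
#' @param seed integer seed recorded in run logs.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(um_per_px = 0.275,
                       d1_um = 30, d2_um = 60,
                       parzen_sigma_um = 25, parzen_decim = 1L,
                       rho_min = 4000,
                       infiltrate_close_um = 15, infiltrate_min_area_mm2 = 0.005,
                       tissue_od_min = 0.12, tissue_close_um = 5,
                       tissue_min_area_mm2 = 0.01,
                       epidermis_max_depth_um = 150, epidermis_close_um = 15,
                       nuc_sigma_um = 0.7, nuc_od_floor = 0.10,
                       nuc_d_min_um = 3, nuc_d_max_um = 20,
                       nuc_min_sep_um = 3, nuc_ws_tol_um = 0.15,
                       mc_od_floor = 0.15, mc_median_um = 0.5,
                       mc_a_noise_um2 = 2, mc_r_link_um = 12,
                       mc_a_min_um2 = 15, mc_a_body_um2 = 40, mc_s_min = 0.8,
                       alpha = 0.05, zero_method = c("drop", "pratt"),
                       seed = 1L) {
  cfg <- list(um_per_px = um_per_px, d1_um = d1_um, d2_um = d2_um,
              parzen_sigma_um = parzen_sigma_um,
              parzen_decim = as.integer(parzen_decim),
              rho_min = rho_min, infiltrate_close_um = infiltrate_close_um,
              infiltrate_min_area_mm2 = infiltrate_min_area_mm2,
              tissue_od_min = tissue_od_min, tissue_close_um = tissue_close_um,
              tissue_min_area_mm2 = tissue_min_area_mm2,
              epidermis_max_depth_um = epidermis_max_depth_um,
              epidermis_close_um = epidermis_close_um,
              nuc_sigma_um = nuc_sigma_um, nuc_od_floor = nuc_od_floor,
              nuc_d_min_um = nuc_d_min_um, nuc_d_max_um = nuc_d_max_um,
              nuc_min_sep_um = nuc_min_sep_um, nuc_ws_tol_um = nuc_ws_tol_um,
              mc_od_floor = mc_od_floor, mc_median_um = mc_median_um,
              mc_a_noise_um2 = mc_a_noise_um2, mc_r_link_um = mc_r_link_um,
              mc_a_min_um2 = mc_a_min_um2, mc_a_body_um2 = mc_a_body_um2,
              mc_s_min = mc_s_min, alpha = alpha,
              zero_method = match.arg(zero_method), seed = as.integer(seed))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  pos <- c("um_per_px", "d1_um", "d2_um", "parzen_sigma_um", "rho_min",
           "nuc_sigma_um", "nuc_d_min_um", "nuc_d_max_um", "nuc_min_sep_um",
           "mc_r_link_um", "mc_a_min_um2", "mc_a_body_um2")
  for (p in pos)
    if (!is.finite(cfg[[p]]) || cfg[[p]] <= 0)
      stop("config field `", p, "` must be positive")
  if (cfg$d1_um >= cfg$d2_um) stop("band edges must satisfy 0 < d1 < d2")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (cfg$parzen_decim < 1L) stop("parzen_decim must be >= 1")
  if (cfg$nuc_d_min_um >= cfg$nuc_d_max_um) stop("nucleus diameter gates inverted")
  if (cfg$mc_s_min <= 0 || cfg$mc_s_min > 1) stop("mc_s_min must lie in (0, 1]")
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Only keys present in the file override the defaults of [run_config()].
#'
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config a `run_config` object.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
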