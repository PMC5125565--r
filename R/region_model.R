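# --- morphological helpers ----------------------------------------------

disc_brush <- function(radius_px) {
  sz <- 2L * max(1L, round(radius_px)) + 1L
  makeBrush(sz, shape = "disc")
}

close_mask <- function(mask, radius_px) {
  if (radius_px < 1) return(mask)
  imageData(closing(Image(mask * 1), disc_brush(radius_px))) > 0
}

# drop connected components smaller than `min_px` pixels (8-connectivity)
drop_small_components <- function(mask, min_px) {
  if (!any(mask) || min_px <= 1) return(mask)
  lab <- label8(mask)
  area <- tabulate(lab[lab > 0L])
  keep <- which(area >= min_px)
  array(lab %in% keep, dim(mask))
}

# 4-neighbour dilation by one pixel (logical OR of shifted copies)
shift_or <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-nr, ]
  out[-nr, ] <- out[-nr, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -nc]
  out[, -nc] <- out[, -nc] | m[, -1]
  out
}

#' Tissue mask from optical density
#'
#' Background exclusion: pixels whose summed OD over the three channels
#' exceeds a threshold, followed by morphological closing and removal of
#' speckle components.
#'
#' @param od `h x w x 3` OD array from [rgb_to_od()].
#' @param config a [run_config()]; uses `tissue_od_min`, `tissue_close_um`,
#'   `tissue_min_area_mm2`.
#' @param um_per_px calibration.
#' @return Logical matrix (TRUE = tissue).
#' @export
tissue_mask <- function(od, config = run_config(), um_per_px = config$um_per_px) {
  odsum <- od[, , 1] + od[, , 2] + od[, , 3]
  m <- odsum > config$tissue_od_min
  m <- close_mask(m, config$tissue_close_um / um_per_px)
  min_px <- config$tissue_min_area_mm2 * 1e6 / um_per_px^2
  drop_small_components(m, min_px)
}

#' Epidermis mask heuristic
#'
#' The epidermis is sought as the connected band of high nuclear
#' (hematoxylin) density adjacent to the tissue/background boundary, within
#' a collar of configurable depth. Within the collar the smoothed H map is
#' thresholded by Otsu; components touching the boundary are kept. When an
#' override mask is supplied it replaces the heuristic verbatim.
#'
#' @param H hematoxylin concentration matrix.
#' @param tissue tissue mask (logical matrix).
#' @param config a [run_config()].
#' @param um_per_px calibration.
#' @param override optional mask replacing the heuristic.
#' @return Logical matrix (TRUE = epidermis); empty with a warning when no
#'   qualifying band exists.
#' @export
epidermis_mask <- function(H, tissue, config = run_config(),
                           um_per_px = config$um_per_px, override = NULL) {
  tissue <- as_binary_matrix(tissue)
  if (!is.null(override)) {
    ov <- as_binary_matrix(override)
    if (!all(dim(ov) == dim(tissue)))
      stop("override mask shape does not match the image grid")
    return(ov)
  }
  stopifnot(all(dim(H) == dim(tissue)))
  none <- array(FALSE, dim(tissue))
  if (!any(tissue) || !any(!tissue)) {
    warning("no tissue/background boundary; epidermis left empty")
    return(none)
  }
  # distance of tissue pixels to background
  bdist <- imageData(distmap(Image(tissue * 1))) * um_per_px
  collar <- tissue & bdist <= config$epidermis_max_depth_um
  if (!any(collar)) return(none)
  sig_px <- 10 / um_per_px   # ~nucleus-scale pooling of the H signal
  Hs <- imageData(gblur(Image(H), sigma = sig_px))
  if (diff(range(Hs[collar])) < 0.02) {
    warning("no nuclear-density contrast at the surface; epidermis left empty")
    return(none)
  }
  thr <- otsu_vec(Hs[collar])
  band <- collar & Hs >= thr
  band <- close_mask(band, config$epidermis_close_um / um_per_px)
  band <- band & collar
  # keep components adjacent to the surface (nuclear signal is diluted by
  # the background within a blur length, so allow a small standoff)
  if (any(band)) {
    lab <- label8(band)
    surface <- unique(lab[lab > 0L & bdist <= max(20, 2 * um_per_px)])
    band <- array(lab %in% surface[surface > 0], dim(tissue))
  }
  if (!any(band)) {
    warning("no epidermal band adjacent to the surface; epidermis left empty")
    return(none)
  }
  # a real epidermal band carries denser nuclear signal than the rest of
  # the tissue; without that contrast the threshold is meaningless
  deep <- tissue & !collar
  ref <- if (any(deep)) Hs[deep] else Hs[collar & !band]
  if (length(ref) && median(Hs[band]) < 1.15 * median(ref)) {
    warning("no nuclear-density contrast at the surface; epidermis left empty")
    return(none)
  }
  # close the gap between the band and the surface: collar pixels not in the
  # band are added unless they connect to dermis-side tissue
  rest <- collar & !band
  if (any(rest)) {
    rlab <- label8(rest)
    outer_tissue <- tissue & !collar
    touches_deep <- unique(rlab[rlab > 0L &
      (shift_or(outer_tissue) | bdist > config$epidermis_max_depth_um - 2 * um_per_px)])
    gaps <- array(rlab > 0L & !(rlab %in% touches_deep), dim(tissue))
    band <- band | gaps
  }
  band
}

#' Parzen-window cell-density map
#'
#' Kernel density estimate of local cell density: an isotropic Gaussian
#' kernel integrating to one cell is centred on every detected centroid and
#' the sum expressed in cells/mm^2. Optionally evaluated on a decimated grid
#' and bilinearly upsampled.
#'
#' @param cells a [cell_set()].
#' @param dim_px `c(rows, cols)` of the target grid.
#' @param um_per_px calibration.
#' @param sigma_um kernel bandwidth in micrometres.
#' @param decim integer decimation factor (1 = full resolution).
#' @return Object of class `density_map`: matrix `values` (cells/mm^2) with
#'   `sigma_um`, `n_cells`, `um_per_px`.
#' @export
parzen_density <- function(cells, dim_px, um_per_px, sigma_um = 25,
                           decim = 1L) {
  if (sigma_um <= 0) stop("sigma_um must be positive")
  decim <- max(1L, as.integer(decim))
  n <- if (inherits(cells, "cell_set")) cells$count else nrow(cells)
  cent <- if (inherits(cells, "cell_set")) cells$centroids else cells
  out_zero <- structure(list(values = matrix(0, dim_px[1], dim_px[2]),
                             sigma_um = sigma_um, n_cells = 0L,
                             um_per_px = um_per_px), class = "density_map")
  if (n == 0L) return(out_zero)
  cdim <- ceiling(dim_px / decim)
  # bin centroids onto the (coarse) grid
  ri <- pmin(pmax(ceiling(cent$row / decim), 1L), cdim[1])
  ci <- pmin(pmax(ceiling(cent$col / decim), 1L), cdim[2])
  counts <- matrix(0, cdim[1], cdim[2])
  for (k in seq_len(n)) counts[ri[k], ci[k]] <- counts[ri[k], ci[k]] + 1
  sig_px <- sigma_um / (um_per_px * decim)
  rad <- ceiling(4 * sig_px)
  k1 <- dnorm(seq(-rad, rad), sd = sig_px)
  kern <- outer(k1, k1)
  kern <- kern / sum(kern)   # each kernel carries exactly one cell
  sm <- imageData(filter2(Image(counts), kern, boundary = 0))
  px_area_mm2 <- (um_per_px * decim)^2 * 1e-6
  dens <- sm / px_area_mm2
  if (decim > 1L) {
    dens <- imageData(resize(Image(dens), w = dim_px[1], h = dim_px[2]))
  }
  dens[dens < 0] <- 0
  structure(list(values = dens, sigma_um = sigma_um, n_cells = n,
                 um_per_px = um_per_px), class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d x %d px; sigma %g um; %d cells; max %.0f cells/mm^2\n",
              nrow(x$values), ncol(x$values), x$sigma_um, x$n_cells,
              max(x$values)))
  invisible(x)
}

#' Extract the lymphoma infiltrate from the density map
#'
#' Dermis pixels whose local cell density reaches `rho_min` form the raw
#' infiltrate; morphological closing, hole filling and a minimum-area filter
#' regularise it. An override (e.g. a manually edited mask) replaces the
#' automatic result verbatim.
#'
#' @param density a `density_map` from [parzen_density()].
#' @param dermis dermis mask (logical matrix).
#' @param config a [run_config()]; uses `rho_min`, `infiltrate_close_um`,
#'   `infiltrate_min_area_mm2`.
#' @param um_per_px calibration.
#' @param override optional mask replacing the automatic extraction.
#' @return Logical matrix (TRUE = infiltrate).
#' @export
extract_infiltrate <- function(density, dermis, config = run_config(),
                               um_per_px = config$um_per_px, override = NULL) {
  dermis <- as_binary_matrix(dermis)
  if (!is.null(override)) {
    ov <- as_binary_matrix(override)
    if (!all(dim(ov) == dim(dermis)))
      stop("override mask shape does not match the image grid")
    return(ov)
  }
  vals <- if (inherits(density, "density_map")) density$values else density
  stopifnot(all(dim(vals) == dim(dermis)))
  m <- dermis & vals >= config$rho_min
  if (!any(m)) return(m)
  m <- close_mask(m, config$infiltrate_close_um / um_per_px)
  m <- imageData(fillHull(Image(m * 1))) > 0
  m <- m & dermis
  drop_small_components(m, config$infiltrate_min_area_mm2 * 1e6 / um_per_px^2)
}

REGION_LEGEND <- c("1" = "EPIDERMIS", "2" = "CTCL", "3" = "P1", "4" = "P2",
                   "5" = "DERMIS_OTHER")

#' Proximity bands around the infiltrate
#'
#' Builds the full region partition: epidermis, infiltrate (CTCL), the
#' proximity bands P1 (distance to the infiltrate in `(0, d1]`) and P2
#' (`(d1, d2]`), and the remaining dermis. Distances are Euclidean in
#' micrometres from the Euclidean distance transform of the infiltrate
#' mask. Bands are restricted to the dermis; on conflicts the priority is
#' EPIDERMIS > CTCL > P1 > P2 > DERMIS_OTHER.
#'
#' @param ctcl infiltrate mask (logical matrix).
#' @param epidermis epidermis mask.
#' @param tissue tissue mask.
#' @param um_per_px calibration.
#' @param d1,d2 band edges in micrometres, `0 < d1 < d2`.
#' @return A `region_set`: a [label_mask()] with legend
#'   `1=EPIDERMIS, 2=CTCL, 3=P1, 4=P2, 5=DERMIS_OTHER` and attributes
#'   `d1_um`, `d2_um`, `um_per_px`.
#' @export
proximity_bands <- function(ctcl, epidermis, tissue, um_per_px,
                            d1 = 30, d2 = 60) {
  if (d1 <= 0 || d1 >= d2) stop("band edges must satisfy 0 < d1 < d2")
  ctcl <- as_binary_matrix(ctcl)
  epidermis <- as_binary_matrix(epidermis)
  tissue <- as_binary_matrix(tissue)
  stopifnot(all(dim(ctcl) == dim(tissue)), all(dim(epidermis) == dim(tissue)))
  dermis <- tissue & !epidermis
  lab <- matrix(0L, nrow(tissue), ncol(tissue))
  if (any(ctcl)) {
    dist_um <- imageData(distmap(Image(1 - ctcl * 1))) * um_per_px
    lab[dermis & dist_um > d1 & dist_um <= d2] <- 4L
    lab[dermis & dist_um > 0 & dist_um <= d1] <- 3L
  } else {
    message("empty infiltrate mask: P1 and P2 are empty")
  }
  lab[dermis & lab == 0L] <- 5L
  lab[dermis & ctcl] <- 2L
  lab[epidermis] <- 1L
  out <- label_mask(lab, REGION_LEGEND)
  attr(out, "d1_um") <- d1
  attr(out, "d2_um") <- d2
  attr(out, "um_per_px") <- um_per_px
  class(out) <- c("region_set", class(out))
  out
}

#' Region areas in mm^2
#'
#' @param regions a `region_set` from [proximity_bands()].
#' @return Named numeric vector of areas per region name.
#' @export
region_areas <- function(regions) {
  upp <- attr(regions, "um_per_px")
  px_area <- upp^2 * 1e-6
  counts <- tabulate(regions$labels, nbins = max(as.integer(names(regions$legend))))
  setNames(counts[as.integer(names(regions$legend))] * px_area,
           unname(regions$legend))
}
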