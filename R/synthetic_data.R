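# --- painting primitives -------------------------------------------------

# Paint filled ellipses (semi-axes in um, orientation theta) into `mat`
# (max-combine). Vectorised over ellipses so the target matrix is copied at
# most once per call; always marks at least the pixel nearest each centre,
# so sub-pixel granules remain visible at coarse calibrations.
paint_ellipses <- function(mat, cx_um, cy_um, a_um, b_um, theta, value,
                           um_per_px) {
  nr <- nrow(mat); nc <- ncol(mat)
  for (i in seq_along(cx_um)) {
    rmax <- max(a_um[i], b_um[i])
    r0 <- max(1L, floor((cy_um[i] - rmax) / um_per_px))
    r1 <- min(nr, ceiling((cy_um[i] + rmax) / um_per_px + 1))
    c0 <- max(1L, floor((cx_um[i] - rmax) / um_per_px))
    c1 <- min(nc, ceiling((cx_um[i] + rmax) / um_per_px + 1))
    if (r0 > r1 || c0 > c1) next
    ys <- ((r0:r1) - 0.5) * um_per_px - cy_um[i]
    xs <- ((c0:c1) - 0.5) * um_per_px - cx_um[i]
    ct <- cos(theta[i]); st <- sin(theta[i])
    u <- (outer(ys * 0, xs, `+`) * ct + outer(ys, xs * 0, `+`) * st) / a_um[i]
    v <- (outer(ys, xs * 0, `+`) * ct - outer(ys * 0, xs, `+`) * st) / b_um[i]
    inside <- u^2 + v^2 <= 1
    if (!any(inside)) {
      rr <- min(max(round(cy_um[i] / um_per_px + 0.5), 1L), nr)
      cc <- min(max(round(cx_um[i] / um_per_px + 0.5), 1L), nc)
      mat[rr, cc] <- max(mat[rr, cc], value[i])
      next
    }
    ridx <- rep.int(r0:r1, times = length(xs))[inside]
    cidx <- rep(c0:c1, each = length(ys))[inside]
    idx <- (cidx - 1L) * nr + ridx
    mat[idx] <- pmax(mat[idx], value[i])
  }
  mat
}

# Hard-core dart throwing over several zones sharing one exclusion
# distance. A bucket grid with cell size = min separation limits the
# neighbourhood test to 3x3 cells; buckets are a fixed-capacity integer
# matrix kept local so all updates are in place.
#
# counts: named integer vector of targets per zone; zone_idx: list of
# linear pixel index vectors (nr x nc grid) per zone; seed_x/seed_y:
# pre-existing points that also exclude.
place_hardcore_zones <- function(counts, zone_idx, nr, um_per_px, min_sep_um,
                                 width_um, height_um,
                                 seed_x = numeric(), seed_y = numeric(),
                                 max_attempts_per_point = 40L) {
  ngx <- max(1L, as.integer(ceiling(width_um / min_sep_um)) + 2L)
  ngy <- max(1L, as.integer(ceiling(height_um / min_sep_um)) + 2L)
  cap <- 8L
  bucket <- matrix(0L, cap, ngx * ngy)
  bcnt <- integer(ngx * ngy)
  total_cap <- sum(counts) + length(seed_x) + 1L
  px <- numeric(total_cap); py <- numeric(total_cap); npts <- 0L
  min_sep2 <- min_sep_um^2
  ncell <- ngx * ngy
  nbr_off <- c(-ngx - 1L, -ngx, -ngx + 1L, -1L, 0L, 1L, ngx - 1L, ngx, ngx + 1L)
  for (i in seq_along(seed_x)) {
    npts <- npts + 1L
    px[npts] <- seed_x[i]; py[npts] <- seed_y[i]
    gx <- min(max(as.integer(seed_x[i] / min_sep_um) + 1L, 1L), ngx)
    gy <- min(max(as.integer(seed_y[i] / min_sep_um) + 1L, 1L), ngy)
    k <- (gy - 1L) * ngx + gx
    if (bcnt[k] < cap) { bcnt[k] <- bcnt[k] + 1L; bucket[bcnt[k], k] <- npts }
  }
  out <- vector("list", length(counts))
  for (z in seq_along(counts)) {
    n <- counts[z]
    idxs <- zone_idx[[z]]
    if (n <= 0L || !length(idxs)) {
      out[[z]] <- data.frame(x_um = numeric(), y_um = numeric())
      next
    }
    budget <- n * max_attempts_per_point
    pick <- idxs[sample.int(length(idxs), budget, replace = TRUE)]
    cand_x <- (((pick - 1L) %/% nr) + runif(budget)) * um_per_px
    cand_y <- (((pick - 1L) %% nr) + runif(budget)) * um_per_px
    cand_k <- (pmin(pmax(as.integer(cand_y / min_sep_um) + 1L, 1L), ngy) - 1L) * ngx +
      pmin(pmax(as.integer(cand_x / min_sep_um) + 1L, 1L), ngx)
    xs <- numeric(n); ys <- numeric(n); placed <- 0L
    for (a in seq_len(budget)) {
      x <- cand_x[a]; y <- cand_y[a]
      free <- TRUE
      for (k in cand_k[a] + nbr_off) {
        if (k < 1L || k > ncell) next
        bc <- bcnt[k]
        if (bc == 0L) next
        ids <- bucket[seq_len(bc), k]
        if (any((px[ids] - x)^2 + (py[ids] - y)^2 < min_sep2)) {
          free <- FALSE
          break
        }
      }
      if (free) {
        npts <- npts + 1L
        px[npts] <- x; py[npts] <- y
        k <- cand_k[a]
        if (bcnt[k] < cap) { bcnt[k] <- bcnt[k] + 1L; bucket[bcnt[k], k] <- npts }
        placed <- placed + 1L
        xs[placed] <- x; ys[placed] <- y
        if (placed == n) break
      }
    }
    out[[z]] <- data.frame(x_um = xs[seq_len(placed)], y_um = ys[seq_len(placed)])
  }
  out
}

# Batch-paint filled circles (max-combine). Pixel-offset stencils are cached
# per radius discretised to 1/4 pixel.
paint_disks <- function(mat, x_um, y_um, r_um, value, um_per_px) {
  n <- length(x_um)
  if (!n) return(mat)
  r_um <- rep_len(r_um, n); value <- rep_len(value, n)
  nr <- nrow(mat); nc <- ncol(mat)
  r_px <- round(4 * r_um / um_per_px) / 4
  cache <- list()
  for (key in as.character(unique(r_px))) {
    rp <- as.numeric(key)
    R <- max(0L, ceiling(rp))
    off <- expand.grid(dr = -R:R, dc = -R:R)
    keep <- off$dr^2 + off$dc^2 <= rp^2
    if (!any(keep)) keep[which.min(off$dr^2 + off$dc^2)] <- TRUE
    cache[[key]] <- list(dr = off$dr[keep], dc = off$dc[keep])
  }
  cr <- pmin(pmax(ceiling(y_um / um_per_px), 1L), nr)
  cc <- pmin(pmax(ceiling(x_um / um_per_px), 1L), nc)
  for (i in seq_len(n)) {
    st <- cache[[as.character(r_px[i])]]
    rr <- cr[i] + st$dr; ccc <- cc[i] + st$dc
    ok <- rr >= 1L & rr <= nr & ccc >= 1L & ccc <= nc
    idx <- (ccc[ok] - 1L) * nr + rr[ok]
    mat[idx] <- pmax(mat[idx], value[i])
  }
  mat
}

# --- scene specification -------------------------------------------------

#' Specification of a synthetic IHC scene
#'
#' Describes a skin section emulating a hematoxylin-counterstained,
#' AEC/tryptase-stained biopsy: a background strip, an epidermal band of
#' high nuclear density, a dermis, a disc-shaped dense lymphoma infiltrate,
#' and mast cells in two morphologies (single compact ellipse body for
#' non-degranulated cells; a small central remnant plus satellite granules
#' for degranulated cells). All randomness is fixed by `seed`.
#'
#' @param size_px `c(rows, cols)` of the image grid.
#' @param um_per_px calibration.
#' @param margin_um background (no tissue) strip at the top.
#' @param epidermis_um thickness of the epidermal band.
#' @param infiltrate_r_um radius of the infiltrate disc (0 = none).
#' @param d1_um,d2_um proximity-band edges used for the ground-truth zones.
#' @param nuclear_density cells/mm^2 named by zone
#'   (`EPIDERMIS`, `CTCL`, `DERMIS`; the dermis value applies to P1, P2 and
#'   the remaining dermis).
#' @param mc_density mast cells/mm^2 named by zone
#'   (`CTCL`, `P1`, `P2`, `DERMIS_OTHER`).
#' @param mc_count_mode `"poisson"` (counts drawn per zone) or `"fixed"`
#'   (deterministic rounded targets).
#' @param frac_degranulated fraction of mast cells planted degranulated.
#' @param fragment_range inclusive range of total fragment count of a
#'   degranulated cell (central remnant plus satellites).
#' @param nucleus_diam_um,mc_body_axes_um,remnant_diam_um,granule_diam_um,satellite_radius_um
#'   morphology ranges in micrometres (uniform draws).
#' @param nucleus_min_sep_um,mc_min_sep_um hard-core separations.
#' @param stroma_h faint hematoxylin background of tissue (OD), so tissue
#'   is distinguishable from the slide background.
#' @param h_amp,t_amp peak OD of nuclei on the H map and of mast-cell
#'   bodies on the T map.
#' @param noise_sd Gaussian pixel noise (8-bit intensity units).
#' @param stains a [stain_model()] used for rendering.
#' @param seed integer seed fixing all randomness.
#' @return A validated list of class `scene_spec`.
#' @export
scene_spec <- function(size_px = c(352L, 352L), um_per_px = 2,
                       margin_um = 10, epidermis_um = 80,
                       infiltrate_r_um = 200, d1_um = 30, d2_um = 60,
                       nuclear_density = c(EPIDERMIS = 6000, CTCL = 8000,
                                           DERMIS = 1500),
                       mc_density = c(CTCL = 250, P1 = 250, P2 = 125,
                                      DERMIS_OTHER = 100),
                       mc_count_mode = c("poisson", "fixed"),
                       frac_degranulated = 0.4,
                       fragment_range = c(4L, 7L),
                       nucleus_diam_um = c(6, 8),
                       mc_body_axes_um = c(8, 14),
                       remnant_diam_um = c(3, 5),
                       granule_diam_um = c(1.5, 3),
                       satellite_radius_um = c(4, 9),
                       nucleus_min_sep_um = 4, mc_min_sep_um = 35,
                       stroma_h = 0.10, h_amp = 0.55, t_amp = 0.9,
                       noise_sd = 5,
                       stains = default_stain_model(), seed = 1L) {
  spec <- list(size_px = as.integer(size_px), um_per_px = um_per_px,
               margin_um = margin_um, epidermis_um = epidermis_um,
               infiltrate_r_um = infiltrate_r_um, d1_um = d1_um,
               d2_um = d2_um, nuclear_density = nuclear_density,
               mc_density = mc_density,
               mc_count_mode = match.arg(mc_count_mode),
               frac_degranulated = frac_degranulated,
               fragment_range = as.integer(fragment_range),
               nucleus_diam_um = nucleus_diam_um,
               mc_body_axes_um = mc_body_axes_um,
               remnant_diam_um = remnant_diam_um,
               granule_diam_um = granule_diam_um,
               satellite_radius_um = satellite_radius_um,
               nucleus_min_sep_um = nucleus_min_sep_um,
               mc_min_sep_um = mc_min_sep_um,
               stroma_h = stroma_h, h_amp = h_amp, t_amp = t_amp,
               noise_sd = noise_sd, stains = stains, seed = as.integer(seed))
  validate_scene_spec(spec)
}

validate_scene_spec <- function(spec) {
  if (any(spec$size_px < 8L)) stop("scene too small")
  if (spec$um_per_px <= 0) stop("um_per_px must be positive")
  if (any(spec$nuclear_density < 0) || any(spec$mc_density < 0))
    stop("densities must be non-negative")
  if (spec$frac_degranulated < 0 || spec$frac_degranulated > 1)
    stop("frac_degranulated must lie in [0, 1]")
  if (spec$d1_um <= 0 || spec$d1_um >= spec$d2_um)
    stop("band edges must satisfy 0 < d1 < d2")
  if (spec$fragment_range[1] < 2L || spec$fragment_range[2] < spec$fragment_range[1])
    stop("fragment_range must be an increasing range with minimum >= 2")
  # packing feasibility: a hard-core process cannot exceed ~0.5 packing
  max_dens <- 0.5 / (pi * (spec$nucleus_min_sep_um / 2)^2) * 1e6  # cells/mm^2
  if (max(spec$nuclear_density) > max_dens)
    stop(sprintf("nuclear density infeasible for min separation %g um (max ~%.0f cells/mm^2)",
                 spec$nucleus_min_sep_um, max_dens))
  structure(spec, class = "scene_spec")
}

# analytic zone truth: matrix of region codes (0 background, REGION_LEGEND)
scene_zone_truth <- function(spec) {
  nr <- spec$size_px[1]; nc <- spec$size_px[2]
  upp <- spec$um_per_px
  y <- ((seq_len(nr)) - 0.5) * upp
  x <- ((seq_len(nc)) - 0.5) * upp
  Y <- matrix(y, nr, nc)
  X <- matrix(x, nr, nc, byrow = TRUE)
  code <- matrix(0L, nr, nc)
  epi_lo <- spec$margin_um; epi_hi <- spec$margin_um + spec$epidermis_um
  tissue <- Y >= epi_lo
  epider <- tissue & Y < epi_hi
  dermis <- Y >= epi_hi
  code[dermis] <- 5L
  if (spec$infiltrate_r_um > 0) {
    cy <- epi_hi + (nr * upp - epi_hi) / 2
    cx <- nc * upp / 2
    dd <- sqrt((X - cx)^2 + (Y - cy)^2) - spec$infiltrate_r_um
    code[dermis & dd <= 0] <- 2L
    code[dermis & dd > 0 & dd <= spec$d1_um] <- 3L
    code[dermis & dd > spec$d1_um & dd <= spec$d2_um] <- 4L
  }
  code[epider] <- 1L
  code
}

#' Generate a synthetic IHC sample with ground truth
#'
#' Builds the zone partition analytically, places nuclei by a hard-core
#' point process at zone densities, plants mast cells in the two
#' morphologies, composes true H and T concentration maps, and renders the
#' RGB image through the Beer-Lambert forward model with Gaussian pixel
#' noise. Deterministic given `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @param sample_id identifier stored in the image.
#' @return A list with elements `image` (a [calibrated_image()]) and
#'   `truth`: `zones` ([label_mask()]), `nuclei` and `mc` data frames,
#'   true `H` and `T` maps, and `realized` (per-zone planted counts and
#'   targets, including any packing shortfall).
#' @export
generate_sample <- function(spec = scene_spec(), sample_id = "synthetic") {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  nr <- spec$size_px[1]; nc <- spec$size_px[2]
  upp <- spec$um_per_px
  px_area_mm2 <- upp^2 * 1e-6
  code <- scene_zone_truth(spec)
  zone_names <- c("EPIDERMIS", "CTCL", "P1", "P2", "DERMIS_OTHER")
  zone_idx <- lapply(1:5, function(k) which(code == k))
  zone_area <- vapply(zone_idx, length, integer(1)) * px_area_mm2

  H <- matrix(0, nr, nc)
  Tm <- matrix(0, nr, nc)
  H[code > 0L] <- spec$stroma_h

  # --- mast cells (placed first; their nuclei count toward zone totals)
  mc_target <- vapply(2:5, function(zi) {
    dens <- spec$mc_density[zone_names[zi]]
    if (is.na(dens)) dens <- 0
    lambda <- dens * zone_area[zi]
    if (spec$mc_count_mode == "poisson") rpois(1, lambda)
    else as.integer(round(lambda))
  }, integer(1))
  mc_pts <- place_hardcore_zones(mc_target, zone_idx[2:5], nr, upp,
                                 spec$mc_min_sep_um, nc * upp, nr * upp)
  realized_mc <- vapply(mc_pts, nrow, integer(1))
  mc <- do.call(rbind, lapply(1:4, function(j)
    if (nrow(mc_pts[[j]])) data.frame(mc_pts[[j]], zone = zone_names[j + 1L])
    else NULL))
  if (is.null(mc))
    mc <- data.frame(x_um = numeric(), y_um = numeric(), zone = character())
  nmc <- nrow(mc)
  if (nmc) {
    deg <- runif(nmc) < spec$frac_degranulated
    mc$state <- ifelse(deg, "DEGRANULATED", "NON_DEGRANULATED")
    mc$fragments <- 1L
    # non-degranulated: one compact ellipse body each
    ni <- which(!deg)
    if (length(ni)) {
      Tm <- paint_ellipses(Tm, mc$x_um[ni], mc$y_um[ni],
                           runif(length(ni), spec$mc_body_axes_um[1], spec$mc_body_axes_um[2]) / 2,
                           runif(length(ni), spec$mc_body_axes_um[1], spec$mc_body_axes_um[2]) / 2,
                           runif(length(ni), 0, pi),
                           spec$t_amp * runif(length(ni), 0.9, 1.1), upp)
    }
    # degranulated: central remnant plus satellite granules, all circles,
    # painted in one batch
    di <- which(deg)
    if (length(di)) {
      rs <- runif(length(di), spec$remnant_diam_um[1], spec$remnant_diam_um[2]) / 2
      k <- sample(spec$fragment_range[1]:spec$fragment_range[2],
                  length(di), replace = TRUE) - 1L
      mc$fragments[di] <- k + 1L
      rep_i <- rep(seq_along(di), k)
      gs <- runif(length(rep_i), spec$granule_diam_um[1], spec$granule_diam_um[2]) / 2
      rmin <- pmax(spec$satellite_radius_um[1], rs[rep_i] + gs + 1)
      rad <- rmin + runif(length(rep_i)) *
        pmax(spec$satellite_radius_um[2] - rmin, 0.5)
      ang <- runif(length(rep_i), 0, 2 * pi)
      Tm <- paint_disks(Tm,
                        c(mc$x_um[di], mc$x_um[di][rep_i] + rad * cos(ang)),
                        c(mc$y_um[di], mc$y_um[di][rep_i] + rad * sin(ang)),
                        c(rs, gs),
                        spec$t_amp * runif(length(di) + length(rep_i), 0.9, 1.1),
                        upp)
    }
  } else {
    mc$state <- character(0)
    mc$fragments <- integer(0)
  }

  # --- nuclei (mast-cell positions occupy nucleus slots in their zone)
  zone_dens <- vapply(zone_names, function(zn) switch(zn,
    EPIDERMIS = spec$nuclear_density[["EPIDERMIS"]],
    CTCL = spec$nuclear_density[["CTCL"]],
    spec$nuclear_density[["DERMIS"]]), numeric(1))
  nuc_target <- as.integer(round(zone_dens * zone_area))
  already <- vapply(zone_names, function(zn) sum(mc$zone == zn), integer(1))
  nuc_pts <- place_hardcore_zones(pmax(0L, nuc_target - already), zone_idx,
                                  nr, upp, spec$nucleus_min_sep_um,
                                  nc * upp, nr * upp,
                                  seed_x = mc$x_um, seed_y = mc$y_um)
  nuc_placed <- vapply(nuc_pts, nrow, integer(1)) + already
  nuclei <- do.call(rbind, c(
    list(if (nrow(mc)) data.frame(x_um = mc$x_um, y_um = mc$y_um,
                                  zone = mc$zone) else NULL),
    lapply(1:5, function(j)
      if (nrow(nuc_pts[[j]])) data.frame(nuc_pts[[j]], zone = zone_names[j])
      else NULL)))
  if (is.null(nuclei))
    nuclei <- data.frame(x_um = numeric(), y_um = numeric(), zone = character())
  if (nrow(nuclei)) {
    nn <- nrow(nuclei)
    H <- paint_disks(H, nuclei$x_um, nuclei$y_um,
                     runif(nn, spec$nucleus_diam_um[1], spec$nucleus_diam_um[2]) / 2,
                     spec$h_amp * runif(nn, 0.8, 1.2), upp)
  }

  image <- render_ihc(H, Tm, spec$stains, noise_sd = spec$noise_sd,
                      um_per_px = upp, sample_id = sample_id)
  realized <- data.frame(
    zone = c(zone_names, paste0("MC_", zone_names[2:5])),
    target = c(nuc_target, mc_target),
    placed = c(nuc_placed, realized_mc))
  list(image = image,
       truth = list(zones = label_mask(code, REGION_LEGEND),
                    nuclei = nuclei, mc = mc, H = H, T = Tm,
                    realized = realized))
}

#' Render an IHC image from concentration maps
#'
#' Beer-Lambert forward model, the exact inverse of
#' [rgb_to_od()] + [deconvolve()]:
#' `pixel_c = (I0_c + 1) * 10^-(H h_c + T t_c) - 1`, plus optional Gaussian
#' noise and 8-bit quantisation.
#'
#' @param H,T_map non-negative concentration matrices of equal shape.
#' @param stains a [stain_model()].
#' @param noise_sd Gaussian noise standard deviation in intensity units.
#' @param um_per_px calibration for the output image.
#' @param sample_id identifier.
#' @param quantize round to 8-bit integers (default); `FALSE` keeps the
#'   continuous float path.
#' @return A [calibrated_image()].
#' @export
render_ihc <- function(H, T_map, stains = default_stain_model(),
                       noise_sd = 0, um_per_px = 0.275,
                       sample_id = "synthetic", quantize = TRUE) {
  stopifnot(all(dim(H) == dim(T_map)), min(H) >= 0, min(T_map) >= 0)
  h <- stains$hematoxylin; a <- stains$aec; I0 <- stains$background
  px <- array(0, c(dim(H), 3L))
  for (ch in 1:3) {
    v <- (I0[ch] + 1) * 10^(-(H * h[ch] + T_map * a[ch])) - 1
    if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
    if (quantize) v <- round(v)
    px[, , ch] <- pmin(pmax(v, 0), 255)
  }
  calibrated_image(px, um_per_px = um_per_px, sample_id = sample_id)
}

#' Synthetic field of nuclei only
#'
#' A uniform dermis-like field with `n` planted nuclei at a given density,
#' for validating nuclear segmentation against known positions.
#'
#' @param n number of nuclei.
#' @param density_mm2 nuclear density (cells/mm^2), fixing the field size.
#' @param um_per_px calibration.
#' @param noise_sd pixel noise (8-bit units).
#' @param seed RNG seed.
#' @param min_sep_um hard-core separation.
#' @param spec_args named list of [scene_spec()] overrides for morphology.
#' @return List: `image`, `positions` (data frame `x_um`, `y_um`),
#'   `dermis` (all-TRUE mask), `um_per_px`.
#' @export
generate_nucleus_field <- function(n = 540, density_mm2 = 1500,
                                   um_per_px = 1, noise_sd = 5, seed = 1L,
                                   min_sep_um = 4, spec_args = list()) {
  spec <- do.call(scene_spec, modifyList(
    list(seed = as.integer(seed), noise_sd = noise_sd,
         nucleus_min_sep_um = min_sep_um,
         nuclear_density = c(EPIDERMIS = density_mm2, CTCL = density_mm2,
                             DERMIS = density_mm2)), spec_args))
  set.seed(spec$seed)
  side_um <- sqrt(n / density_mm2 * 1e6)
  npx <- ceiling(side_um / um_per_px)
  H <- matrix(0, npx, npx)
  H[] <- spec$stroma_h
  pts <- place_hardcore_zones(n, list(seq_len(npx * npx)), npx, um_per_px,
                              min_sep_um, npx * um_per_px,
                              npx * um_per_px)[[1]]
  np <- nrow(pts)
  H <- paint_disks(H, pts$x_um, pts$y_um,
                   runif(np, spec$nucleus_diam_um[1], spec$nucleus_diam_um[2]) / 2,
                   spec$h_amp * runif(np, 0.8, 1.2), um_per_px)
  img <- render_ihc(H, matrix(0, npx, npx), spec$stains, noise_sd,
                    um_per_px, "nucleus_field")
  list(image = img, positions = pts,
       dermis = matrix(TRUE, npx, npx), um_per_px = um_per_px)
}

#' Synthetic field of mast cells only
#'
#' Plants exactly `n` mast cells on a jittered grid (spacing well above the
#' clustering radius), a fixed fraction degranulated, for validating
#' detection and degranulation classification. The `well_separated` regime
#' uses large compact bodies (area >= 80 um^2) and fragment clusters of at
#' least 4 pieces of at most 15 um^2 each; the `default` regime uses the
#' standard morphology ranges of [scene_spec()].
#'
#' @param n number of mast cells.
#' @param frac_degranulated fraction planted degranulated.
#' @param um_per_px calibration.
#' @param spacing_um grid spacing between cells.
#' @param noise_sd pixel noise (8-bit units).
#' @param regime `"default"` or `"well_separated"`.
#' @param seed RNG seed.
#' @return List: `image`, `mc` (data frame `x_um`, `y_um`, `state`,
#'   `fragments`), `dermis`, `um_per_px`.
#' @export
generate_mc_field <- function(n = 200, frac_degranulated = 0.4,
                              um_per_px = 0.5, spacing_um = 35,
                              noise_sd = 5,
                              regime = c("default", "well_separated"),
                              seed = 1L) {
  regime <- match.arg(regime)
  spec <- scene_spec(seed = as.integer(seed), noise_sd = noise_sd)
  if (regime == "well_separated") {
    spec$mc_body_axes_um <- c(11, 14)     # area >= pi*11^2/4 ~ 95 um^2
    spec$remnant_diam_um <- c(3, 4)       # each piece <= 15 um^2
    spec$granule_diam_um <- c(2.5, 4)
    spec$fragment_range <- c(4L, 6L)
  }
  set.seed(spec$seed)
  ncols <- ceiling(sqrt(n))
  nrows <- ceiling(n / ncols)
  margin <- 20
  side_x <- margin * 2 + ncols * spacing_um
  side_y <- margin * 2 + nrows * spacing_um
  npx_r <- ceiling(side_y / um_per_px); npx_c <- ceiling(side_x / um_per_px)
  Tm <- matrix(0, npx_r, npx_c)
  H <- matrix(spec$stroma_h, npx_r, npx_c)
  jit <- (spacing_um - 22) / 2   # keep >= 22 um between neighbouring extents
  ks <- seq_len(n) - 1L
  gx <- margin + (ks %% ncols + 0.5) * spacing_um +
    runif(n, -max(jit, 0), max(jit, 0))
  gy <- margin + (ks %/% ncols + 0.5) * spacing_um +
    runif(n, -max(jit, 0), max(jit, 0))
  deg <- runif(n) < frac_degranulated
  frags <- rep(1L, n)
  ni <- which(!deg)
  if (length(ni))
    Tm <- paint_ellipses(Tm, gx[ni], gy[ni],
                         runif(length(ni), spec$mc_body_axes_um[1], spec$mc_body_axes_um[2]) / 2,
                         runif(length(ni), spec$mc_body_axes_um[1], spec$mc_body_axes_um[2]) / 2,
                         runif(length(ni), 0, pi),
                         spec$t_amp * runif(length(ni), 0.9, 1.1), um_per_px)
  di <- which(deg)
  if (length(di)) {
    rs <- runif(length(di), spec$remnant_diam_um[1], spec$remnant_diam_um[2]) / 2
    k <- sample(spec$fragment_range[1]:spec$fragment_range[2],
                length(di), replace = TRUE) - 1L
    frags[di] <- k + 1L
    rep_i <- rep(seq_along(di), k)
    gs <- runif(length(rep_i), spec$granule_diam_um[1], spec$granule_diam_um[2]) / 2
    rmin <- pmax(spec$satellite_radius_um[1], rs[rep_i] + gs + 1)
    rad <- rmin + runif(length(rep_i)) * pmax(spec$satellite_radius_um[2] - rmin, 0.5)
    ang <- runif(length(rep_i), 0, 2 * pi)
    Tm <- paint_disks(Tm,
                      c(gx[di], gx[di][rep_i] + rad * cos(ang)),
                      c(gy[di], gy[di][rep_i] + rad * sin(ang)),
                      c(rs, gs),
                      spec$t_amp * runif(length(di) + length(rep_i), 0.9, 1.1),
                      um_per_px)
  }
  # a nucleus under each mast cell
  H <- paint_disks(H, gx, gy,
                   runif(n, spec$nucleus_diam_um[1], spec$nucleus_diam_um[2]) / 2,
                   spec$h_amp * runif(n, 0.8, 1.2), um_per_px)
  img <- render_ihc(H, Tm, spec$stains, noise_sd, um_per_px, "mc_field")
  list(image = img,
       mc = data.frame(x_um = gx, y_um = gy,
                       state = ifelse(deg, "DEGRANULATED", "NON_DEGRANULATED"),
                       fragments = frags),
       dermis = matrix(TRUE, npx_r, npx_c), um_per_px = um_per_px)
}

#' Generate a synthetic cohort on disk
#'
#' Writes `n_samples` rendered IHC images plus a manifest CSV. The cohort
#' plants the qualitative structure reported for cutaneous T-cell lymphoma:
#' mast-cell density is equal in the infiltrate and the inner proximity
#' band and drops in the outer band, and early-stage samples carry higher
#' mast-cell densities than advanced-stage samples.
#'
#' @param dir output directory (created if needed).
#' @param n_samples cohort size.
#' @param n_early number of early-stage (IA/IB) samples; the rest are
#'   advanced (IIA/IIB).
#' @param base_early,base_advanced base mast-cell density (MC/mm^2) of the
#'   two stage groups.
#' @param multipliers zone multipliers applied to the base density, named
#'   `CTCL`, `P1`, `P2`, `DERMIS_OTHER`.
#' @param seed cohort seed; sample `i` uses `seed * 1000 + i`.
#' @param spec_args named list of [scene_spec()] overrides.
#' @return The manifest data frame (also written to `manifest.csv`):
#'   `sample_id`, `image_path`, `group`, `stage`.
#' @export
synth_cohort <- function(dir, n_samples = 20L, n_early = 10L,
                         base_early = 300, base_advanced = 180,
                         multipliers = c(CTCL = 1, P1 = 1, P2 = 0.5,
                                         DERMIS_OTHER = 0.4),
                         seed = 1L, spec_args = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(n_samples), function(i) {
    early <- i <= n_early
    stage <- if (early) c("IA", "IB")[1 + (i %% 2)]
             else c("IIA", "IIB")[1 + (i %% 2)]
    base <- if (early) base_early else base_advanced
    args <- modifyList(list(
      mc_density = setNames(base * as.numeric(multipliers), names(multipliers)),
      seed = as.integer(seed) * 1000L + i), spec_args)
    smp <- generate_sample(do.call(scene_spec, args),
                           sample_id = sprintf("S%02d", i))
    path <- file.path(dir, sprintf("S%02d.tif", i))
    write_calibrated_image(smp$image, path)
    data.frame(sample_id = sprintf("S%02d", i), image_path = path,
               group = "MF", stage = stage)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}
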