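# 3x3 median filter via a 19-comparator sorting network on shifted copies
# (replicated borders); much faster than a generic rank filter.
median3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- function(d) pmin(pmax(seq_len(nr) + d, 1L), nr)
  ci <- function(d) pmin(pmax(seq_len(nc) + d, 1L), nc)
  p <- list()
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    p[[k]] <- m[ri(dr), ci(dc)]
  }
  sw <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  net <- list(c(2,3),c(5,6),c(8,9),c(1,2),c(4,5),c(7,8),c(2,3),c(5,6),
              c(8,9),c(1,4),c(6,9),c(5,8),c(4,7),c(2,5),c(3,6),c(5,8),
              c(5,3),c(7,5),c(5,3))
  for (s in net) sw(s[1], s[2])
  p[[5]]
}

# Convex-hull area of a pixel component, by scanline rasterisation of the
# hull polygon (pixel count inside the hull, so solidity <= 1 by
# construction).
convex_hull_px <- function(rows, cols) {
  n <- length(rows)
  if (n <= 3L) return(n)
  hp <- chull(cols, rows)
  hx <- cols[hp]; hy <- rows[hp]
  m <- length(hx)
  total <- 0L
  for (r in seq(min(hy), max(hy))) {
    xs <- numeric(0)
    for (e in seq_len(m)) {
      x1 <- hx[e]; y1 <- hy[e]
      x2 <- hx[if (e == m) 1L else e + 1L]; y2 <- hy[if (e == m) 1L else e + 1L]
      if (y1 == y2) {
        if (y1 == r) xs <- c(xs, x1, x2)
      } else if (r >= min(y1, y2) && r <= max(y1, y2)) {
        xs <- c(xs, x1 + (r - y1) * (x2 - x1) / (y2 - y1))
      }
    }
    if (length(xs))
      total <- total + (floor(max(xs)) - ceiling(min(xs)) + 1L)
  }
  max(total, n)
}

#' Detect tryptase-positive blobs
#'
#' Connected components (8-connectivity) of the thresholded tryptase map
#' inside the dermis, after median smoothing. The threshold is Otsu on
#' in-dermis T values floored at `mc_od_floor`; components smaller than
#' `mc_a_noise_um2` are discarded as noise.
#'
#' @param T_map tryptase concentration matrix (non-negative OD).
#' @param dermis dermis mask.
#' @param config a [run_config()].
#' @param um_per_px calibration.
#' @param tau_T optional explicit OD threshold overriding the Otsu rule.
#' @return Data frame of blobs: `blob_id`, `row`, `col`, `x_um`, `y_um`,
#'   `area_um2`, `solidity`.
#' @export
detect_tryptase_blobs <- function(T_map, dermis, config = run_config(),
                                  um_per_px = config$um_per_px, tau_T = NULL) {
  dermis <- as_binary_matrix(dermis)
  stopifnot(all(dim(T_map) == dim(dermis)))
  empty <- data.frame(blob_id = integer(), row = numeric(), col = numeric(),
                      x_um = numeric(), y_um = numeric(),
                      area_um2 = numeric(), solidity = numeric())
  if (!any(dermis) || max(T_map) <= 0) return(empty)
  Ts <- T_map
  med_px <- floor(config$mc_median_um / um_per_px)
  if (med_px == 1L) {
    Ts <- median3x3(Ts)
  } else if (med_px > 1L) {
    mx <- max(Ts)
    Ts <- imageData(medianFilter(Image(Ts / mx), med_px)) * mx
  }
  thr <- if (!is.null(tau_T)) tau_T
         else max(otsu_vec(Ts[dermis]), config$mc_od_floor)
  fg <- Ts >= thr & dermis
  if (!any(fg)) return(empty)
  lab <- label8(fg)
  idx <- which(lab > 0L)
  l <- lab[idx]
  nr <- nrow(lab)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  area_px <- tabulate(l)
  keep <- which(area_px * um_per_px^2 >= config$mc_a_noise_um2)
  if (!length(keep)) return(empty)
  ord <- order(l)
  l_s <- l[ord]; rr_s <- rr[ord]; cc_s <- cc[ord]
  ends <- cumsum(area_px)
  starts <- c(1L, head(ends, -1L) + 1L)
  nb <- length(keep)
  row_c <- as.vector(rowsum(as.numeric(rr), l))[keep] / area_px[keep]
  col_c <- as.vector(rowsum(as.numeric(cc), l))[keep] / area_px[keep]
  sol <- vapply(keep, function(k) {
    sel <- starts[k]:ends[k]
    min(1, length(sel) / convex_hull_px(rr_s[sel], cc_s[sel]))
  }, numeric(1))
  data.frame(blob_id = seq_len(nb), row = row_c, col = col_c,
             x_um = (col_c - 0.5) * um_per_px,
             y_um = (row_c - 0.5) * um_per_px,
             area_um2 = area_px[keep] * um_per_px^2,
             solidity = sol)
}

#' Single-linkage clustering of blobs
#'
#' Two blobs belong to one cluster iff they are connected by a chain of
#' centroid distances each at most `r_link_um` (single linkage).
#'
#' @param blobs data frame from [detect_tryptase_blobs()].
#' @param r_link_um linkage radius in micrometres.
#' @return Integer vector of cluster ids, one per blob.
#' @export
cluster_blobs <- function(blobs, r_link_um = 12) {
  if (r_link_um <= 0) stop("r_link_um must be positive")
  n <- nrow(blobs)
  if (n == 0L) return(integer())
  if (n == 1L) return(1L)
  hc <- hclust(dist(cbind(blobs$x_um, blobs$y_um)), method = "single")
  unname(cutree(hc, h = r_link_um))
}

#' Classify a blob cluster as degranulated or non-degranulated
#'
#' A mast cell is non-degranulated iff it is a single blob that is both
#' large (area at least `mc_a_body_um2`) and compact (solidity at least
#' `mc_s_min`); any fragmented cluster, and any single blob failing the
#' size or compactness test, is degranulated. Clusters with total area
#' below `mc_a_min_um2` are discarded as debris (return `NA`).
#'
#' @param areas_um2 blob areas of the cluster members.
#' @param solidities blob solidities of the cluster members.
#' @param config a [run_config()].
#' @return `"NON_DEGRANULATED"`, `"DEGRANULATED"`, or `NA_character_` for a
#'   discarded cluster.
#' @export
classify_degranulation <- function(areas_um2, solidities,
                                   config = run_config()) {
  if (sum(areas_um2) < config$mc_a_min_um2) return(NA_character_)
  if (length(areas_um2) == 1L &&
      areas_um2 >= config$mc_a_body_um2 &&
      solidities >= config$mc_s_min) "NON_DEGRANULATED" else "DEGRANULATED"
}

#' Assemble mast-cell records from blobs
#'
#' Clusters blobs, applies the degranulation rule, and returns one record
#' per retained cluster with an area-weighted centroid.
#'
#' @param blobs data frame from [detect_tryptase_blobs()].
#' @param config a [run_config()].
#' @return Data frame of class `mc_records`: `cluster_id`, `x_um`, `y_um`,
#'   `row`, `col`, `area_um2`, `fragments`, `state`.
#' @export
make_mc_records <- function(blobs, config = run_config()) {
  empty <- data.frame(cluster_id = integer(), x_um = numeric(),
                      y_um = numeric(), row = numeric(), col = numeric(),
                      area_um2 = numeric(), fragments = integer(),
                      state = character())
  if (nrow(blobs) == 0L) return(empty)
  cl <- cluster_blobs(blobs, config$mc_r_link_um)
  recs <- lapply(sort(unique(cl)), function(k) {
    b <- blobs[cl == k, , drop = FALSE]
    st <- classify_degranulation(b$area_um2, b$solidity, config)
    if (is.na(st)) return(NULL)
    w <- b$area_um2 / sum(b$area_um2)
    data.frame(cluster_id = k,
               x_um = sum(w * b$x_um), y_um = sum(w * b$y_um),
               row = sum(w * b$row), col = sum(w * b$col),
               area_um2 = sum(b$area_um2),
               fragments = nrow(b), state = st)
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs)) return(empty)
  recs$cluster_id <- seq_len(nrow(recs))
  recs
}

#' Assign each mast-cell record to a region
#'
#' The region is the one containing the record's centroid pixel. Records in
#' the epidermis or outside any labelled region are retained but flagged
#' `excluded = TRUE` and do not enter the metrics.
#'
#' @param records data frame from [make_mc_records()].
#' @param regions a `region_set` from [proximity_bands()].
#' @return `records` with columns `region` and `excluded` added.
#' @export
assign_regions <- function(records, regions) {
  stopifnot(inherits(regions, "label_mask"))
  if (nrow(records) == 0L) {
    records$region <- character()
    records$excluded <- logical()
    return(records)
  }
  lab <- regions$labels
  ri <- pmin(pmax(round(records$row), 1), nrow(lab))
  ci <- pmin(pmax(round(records$col), 1), ncol(lab))
  code <- lab[cbind(ri, ci)]
  records$region <- ifelse(code == 0L, NA_character_,
                           unname(regions$legend[as.character(code)]))
  records$excluded <- is.na(records$region) | records$region == "EPIDERMIS"
  records
}

#' Detect and classify mast cells on the tryptase map
#'
#' Convenience wrapper: blob detection, single-linkage clustering,
#' degranulation classification, and region assignment.
#'
#' @inheritParams detect_tryptase_blobs
#' @param regions a `region_set`; when `NULL` the records carry no region.
#' @return `mc_records` data frame (see [make_mc_records()]), with region
#'   labels when `regions` is given.
#' @export
detect_mast_cells <- function(T_map, dermis, regions = NULL,
                              config = run_config(),
                              um_per_px = config$um_per_px, tau_T = NULL) {
  blobs <- detect_tryptase_blobs(T_map, dermis, config, um_per_px, tau_T)
  recs <- make_mc_records(blobs, config)
  if (!is.null(regions)) recs <- assign_regions(recs, regions)
  recs
}
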