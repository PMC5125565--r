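# --- shared low-level helpers -------------------------------------------

# Otsu threshold on a numeric vector (256-bin histogram between min and max).
otsu_vec <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- as.numeric(tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(h); w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(between)]
}

# 8-connected labeling: 4-connected bwlabel plus union of diagonal contacts.
label8 <- function(mask) {
  lab <- imageData(bwlabel(Image(mask * 1)))
  n <- max(lab)
  if (n < 2L) { storage.mode(lab) <- "integer"; return(lab) }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]),  as.vector(lab[-nr, -1])))  # up-right
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  storage.mode(out) <- "integer"
  out
}

# Areas (px) and centroids (fractional row/col) of labelled components.
component_stats <- function(lab) {
  idx <- which(lab > 0L)
  if (!length(idx))
    return(data.frame(label = integer(), area_px = integer(),
                      row = numeric(), col = numeric()))
  l <- lab[idx]
  nr <- nrow(lab)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  area <- tabulate(l)
  keep <- which(area > 0L)
  data.frame(label = keep,
             area_px = area[keep],
             row = as.vector(rowsum(as.numeric(rr), l)[, 1] / area[keep]),
             col = as.vector(rowsum(as.numeric(cc), l)[, 1] / area[keep]))
}

# Greedy enforcement of a minimum centroid separation: components are
# visited in decreasing weight order and dropped when within `min_sep_px`
# of an already accepted centroid.
enforce_min_separation <- function(stats, min_sep_px, weight = stats$area_px) {
  n <- nrow(stats)
  if (n < 2L) return(stats)
  ord <- order(-weight)
  acc_r <- numeric(n); acc_c <- numeric(n); nacc <- 0L
  keep <- logical(n)
  for (i in ord) {
    if (nacc > 0L) {
      d2 <- (acc_r[seq_len(nacc)] - stats$row[i])^2 +
        (acc_c[seq_len(nacc)] - stats$col[i])^2
      if (min(d2) < min_sep_px^2) next
    }
    keep[i] <- TRUE
    nacc <- nacc + 1L
    acc_r[nacc] <- stats$row[i]; acc_c[nacc] <- stats$col[i]
  }
  stats[keep, , drop = FALSE]
}

as_binary_matrix <- function(mask) {
  if (inherits(mask, "label_mask")) mask <- mask$labels
  if (inherits(mask, "Image")) mask <- imageData(mask)
  mask > 0
}

# --- nuclei detection ----------------------------------------------------

#' Set of detected cell centroids
#'
#' @param centroids data frame with columns `row`, `col` (fractional pixel
#'   coordinates) and `x_um`, `y_um` (physical, x along columns, y along
#'   rows).
#' @param mask_name name of the mask the cells were detected in.
#' @param um_per_px calibration.
#' @return An object of class `cell_set` with elements `centroids`, `count`,
#'   `mask_name`, `um_per_px`.
#' @export
cell_set <- function(centroids, mask_name = "dermis", um_per_px = NA_real_) {
  stopifnot(is.data.frame(centroids))
  structure(list(centroids = centroids, count = nrow(centroids),
                 mask_name = mask_name, um_per_px = um_per_px),
            class = "cell_set")
}

#' @export
print.cell_set <- function(x, ...) {
  cat(sprintf("<cell_set> %d cells in '%s'\n", x$count, x$mask_name))
  invisible(x)
}

#' Detect nucleated cells on the hematoxylin map
#'
#' Nuclear segmentation: Gaussian smoothing, Otsu threshold on in-mask
#' values (floored at an absolute OD), hole filling, watershed splitting of
#' touching nuclei on the Euclidean distance map, an equivalent-diameter
#' size gate, and a minimum centroid separation. Only centroids whose pixel
#' lies in the dermis mask are returned ("total cells", mast-cell nuclei
#' included).
#'
#' @param H hematoxylin concentration matrix (non-negative OD).
#' @param dermis dermis mask (logical matrix, [label_mask()], or anything
#'   coercible with `> 0`).
#' @param config a [run_config()].
#' @param um_per_px calibration (um/pixel).
#' @return A [cell_set()].
#' @export
detect_nuclei <- function(H, dermis, config = run_config(),
                          um_per_px = config$um_per_px) {
  dermis <- as_binary_matrix(dermis)
  stopifnot(all(dim(H) == dim(dermis)))
  empty <- cell_set(data.frame(row = numeric(), col = numeric(),
                               x_um = numeric(), y_um = numeric()),
                    "dermis", um_per_px)
  if (!any(dermis) || max(H) <= 0) return(empty)
  sig_px <- config$nuc_sigma_um / um_per_px
  Hs <- if (sig_px >= 0.5) imageData(gblur(Image(H), sigma = sig_px)) else H
  thr <- max(otsu_vec(Hs[dermis]), config$nuc_od_floor)
  fg <- Hs >= thr
  if (!any(fg)) return(empty)
  fg <- imageData(fillHull(Image(fg * 1))) > 0
  dm <- distmap(Image(fg * 1))
  ws <- imageData(watershed(dm, tolerance = max(0.1, config$nuc_ws_tol_um / um_per_px),
                            ext = 1L))
  st <- component_stats(ws)
  if (!nrow(st)) return(empty)
  eq_d <- 2 * sqrt(st$area_px * um_per_px^2 / pi)
  st <- st[eq_d >= config$nuc_d_min_um & eq_d <= config$nuc_d_max_um, ,
           drop = FALSE]
  if (!nrow(st)) return(empty)
  st <- enforce_min_separation(st, config$nuc_min_sep_um / um_per_px)
  inmask <- dermis[cbind(pmin(pmax(round(st$row), 1), nrow(dermis)),
                         pmin(pmax(round(st$col), 1), ncol(dermis)))]
  st <- st[inmask, , drop = FALSE]
  cent <- data.frame(row = st$row, col = st$col,
                     x_um = (st$col - 0.5) * um_per_px,
                     y_um = (st$row - 0.5) * um_per_px)
  cell_set(cent, "dermis", um_per_px)
}
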