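#' Stain model for two-stain brightfield IHC
#'
#' Unit optical-density vectors for the hematoxylin counterstain and the red
#' AEC chromogen of the tryptase stain, plus the per-channel background
#' intensity of the scanner.
#'
#' @param hematoxylin,aec numeric 3-vectors of RGB optical densities; they
#'   are normalised to unit Euclidean length.
#' @param background per-channel background intensity I0 (default pure white).
#' @return An object of class `stain_model` with unit vectors `hematoxylin`,
#'   `aec` and `background`.
#' @export
stain_model <- function(hematoxylin, aec, background = c(255, 255, 255)) {
  norm3 <- function(v) {
    if (length(v) != 3L || !all(is.finite(v))) stop("stain vector must be a finite 3-vector")
    n <- sqrt(sum(v^2))
    if (n == 0) stop("stain vector must be non-zero")
    v / n
  }
  h <- norm3(hematoxylin); a <- norm3(aec)
  ang <- acos(min(1, max(-1, sum(h * a)))) * 180 / pi
  if (ang < 5)
    stop(sprintf("stain vectors 'hematoxylin' and 'AEC' are near-collinear (%.2f deg < 5 deg)", ang))
  if (any(background < 1) || any(background > 255))
    stop("background intensity must lie in [1, 255] per channel")
  structure(list(hematoxylin = h, aec = a, background = as.numeric(background)),
            class = "stain_model")
}

#' Default hematoxylin / AEC stain model
#'
#' Literature RGB optical-density directions for hematoxylin and AEC as used
#' in standard two-stain color-deconvolution vector sets, normalised to unit
#' length. Scanners vary; override via [stain_model()] when single-stain
#' calibration patches are available.
#'
#' @return A [stain_model()].
#' @export
default_stain_model <- function() {
  stain_model(hematoxylin = c(0.650, 0.704, 0.286),
              aec         = c(0.2743, 0.6796, 0.6803))
}

#' RGB to optical density
#'
#' Beer-Lambert transform `OD_c = -log10((p_c + 1) / (I0_c + 1))` per
#' channel, with a +1 intensity offset so that fully absorbing pixels stay
#' finite. Pixels brighter than the background are clipped to OD 0.
#'
#' @param image a [calibrated_image()] or an `h x w x 3` array in `[0,255]`.
#' @param I0 per-channel background intensity in `[1, 255]`.
#' @return `h x w x 3` array of non-negative optical densities, with
#'   attribute `um_per_px` when the input was calibrated.
#' @export
rgb_to_od <- function(image, I0 = c(255, 255, 255)) {
  if (any(I0 < 1) || any(I0 > 255)) stop("I0 must lie in [1, 255] per channel")
  upp <- NULL
  px <- image
  if (inherits(image, "calibrated_image")) {
    px <- image$pixels
    upp <- image$um_per_px
  }
  od <- px
  for (ch in 1:3)
    od[, , ch] <- -log10((px[, , ch] + 1) / (I0[ch] + 1))
  od[od < 0] <- 0
  attr(od, "um_per_px") <- upp
  od
}

#' Color deconvolution into hematoxylin and AEC concentration maps
#'
#' Per pixel, the OD vector is decomposed in the basis formed by the two
#' stain vectors plus their unit cross product (the residual direction);
#' because the basis has full rank this is the least-squares projection onto
#' the stain plane. Negative concentrations are clipped to zero and the
#' clipped fraction recorded.
#'
#' @param od `h x w x 3` optical-density array from [rgb_to_od()].
#' @param stains a [stain_model()].
#' @return An object of class `concentration_maps`: matrices `H` and `T`
#'   (non-negative OD units), `residual_rms` (RMS norm of the OD component
#'   orthogonal to the stain plane), `clipped_frac`, and `um_per_px`.
#' @export
deconvolve <- function(od, stains = default_stain_model()) {
  stopifnot(inherits(stains, "stain_model"))
  h <- stains$hematoxylin; a <- stains$aec
  r <- c(h[2] * a[3] - h[3] * a[2],
         h[3] * a[1] - h[1] * a[3],
         h[1] * a[2] - h[2] * a[1])
  rn <- sqrt(sum(r^2))
  if (rn < sin(5 * pi / 180))
    stop("stain vectors 'hematoxylin' and 'AEC' are near-collinear")
  r <- r / rn
  M <- cbind(h, a, r)
  dm <- dim(od)
  flat <- matrix(od, ncol = 3L)
  conc <- flat %*% t(solve(M))
  neg <- conc[, 1:2] < 0
  clipped_frac <- mean(neg)
  conc[, 1:2][neg] <- 0
  H <- matrix(conc[, 1], dm[1], dm[2])
  T <- matrix(conc[, 2], dm[1], dm[2])
  structure(list(H = H, T = T,
                 residual_rms = sqrt(mean(conc[, 3]^2)),
                 clipped_frac = clipped_frac,
                 um_per_px = attr(od, "um_per_px")),
            class = "concentration_maps")
}

#' @export
print.concentration_maps <- function(x, ...) {
  cat(sprintf("<concentration_maps> %d x %d px; max H %.3f, max T %.3f, residual RMS %.4f, clipped %.2f%%\n",
              nrow(x$H), ncol(x$H), max(x$H), max(x$T),
              x$residual_rms, 100 * x$clipped_frac))
  invisible(x)
}
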