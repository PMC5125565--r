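#' Per-sample, per-region mast-cell metrics
#'
#' Tallies, for each of the regions CTCL, P1, P2: area, total nucleated
#' cells, mast-cell count, mast cells per mm^2, mast cells as percent of
#' total cells, and degranulated mast cells as percent of all mast cells.
#' Ratios with a zero denominator are `NA` (undefined, not zero).
#'
#' @param cells a [cell_set()] of nucleated-cell centroids.
#' @param records `mc_records` with region labels (see [assign_regions()]).
#' @param regions a `region_set` from [proximity_bands()].
#' @param sample_id,group,stage metadata copied into the rows.
#' @return Data frame of class `sample_metrics`, one row per region, with
#'   columns `sample_id, group, stage, region, area_mm2, total_cells,
#'   mc_count, degranulated_count, mc_per_mm2, mc_pct_of_cells,
#'   pct_degranulated`.
#' @export
compute_sample_metrics <- function(cells, records, regions,
                                   sample_id = "sample",
                                   group = NA_character_,
                                   stage = NA_character_) {
  stopifnot(inherits(regions, "label_mask"))
  areas <- region_areas(regions)
  lab <- regions$labels
  cell_code <- if (cells$count > 0) {
    ri <- pmin(pmax(round(cells$centroids$row), 1), nrow(lab))
    ci <- pmin(pmax(round(cells$centroids$col), 1), ncol(lab))
    lab[cbind(ri, ci)]
  } else integer()
  code_of <- setNames(as.integer(names(regions$legend)), unname(regions$legend))
  rows <- lapply(c("CTCL", "P1", "P2"), function(rg) {
    area <- unname(areas[rg])
    total <- sum(cell_code == code_of[rg])
    rec <- records[!is.na(records$region) & records$region == rg &
                     !records$excluded, , drop = FALSE]
    mc <- nrow(rec)
    deg <- sum(rec$state == "DEGRANULATED")
    if (area <= 0)
      message("region ", rg, " has zero area for sample ", sample_id,
              "; densities undefined")
    data.frame(sample_id = sample_id, group = group, stage = stage,
               region = rg,
               area_mm2 = area,
               total_cells = total,
               mc_count = mc,
               degranulated_count = deg,
               mc_per_mm2 = if (area > 0) mc / area else NA_real_,
               mc_pct_of_cells = if (total > 0) 100 * mc / total else NA_real_,
               pct_degranulated = if (mc > 0) 100 * deg / mc else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sample_metrics", class(out))
  out
}

#' Median and range
#'
#' @param values non-empty numeric vector of finite values.
#' @return Named numeric vector `c(median, min, max)`; the median of an
#'   even-length vector is the mean of the two middle order statistics.
#' @export
median_and_range <- function(values) {
  if (!length(values) || !all(is.finite(values)))
    stop("`values` must be a non-empty vector of finite numbers")
  c(median = median(values), min = min(values), max = max(values))
}

test_result <- function(method, statistic, p_value, n, exact) {
  structure(list(method = method, statistic = unname(statistic),
                 p_value = unname(p_value), n = n, exact = exact),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %g, p = %.4g (%s), n = %s\n", x$method,
              x$statistic, x$p_value, if (x$exact) "exact" else "approximate",
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided test on paired differences. The statistic is
#' `W = min(W+, W-)` with mid-ranks for tied absolute differences. Zero
#' differences are dropped (classic convention) or ranked and retained
#' (Pratt). The p-value is exact (sign enumeration) for up to 20 non-zero
#' untied differences and a tie-corrected, continuity-corrected normal
#' approximation otherwise.
#'
#' @param x paired differences, or first measurement when `y` is given.
#' @param y optional second measurement; differences are `x - y`.
#' @param zero_method `"drop"` or `"pratt"`.
#' @return A `test_result` with fields `method`, `statistic` (W), `p_value`,
#'   `n` (pairs used), `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, zero_method = c("drop", "pratt")) {
  zero_method <- match.arg(zero_method)
  d <- if (is.null(y)) x else x - y
  if (!length(d) || !all(is.finite(d))) stop("need at least one finite pair")
  nz <- d != 0
  n_zero <- sum(!nz)
  if (n_zero > 0)
    message(n_zero, " zero difference(s) ",
            if (zero_method == "drop") "dropped" else "retained (Pratt)")
  if (!any(nz))
    return(test_result("Wilcoxon signed-rank", 0, 1, 0L, TRUE))
  if (zero_method == "drop") {
    dd <- d[nz]
    r <- rank(abs(dd))
    Wp <- sum(r[dd > 0]); Wm <- sum(r[dd < 0])
    n <- length(dd)
    ties <- anyDuplicated(r) > 0
    exact <- n <= 20 && !ties
    p <- suppressWarnings(
      wilcox.test(dd, exact = exact, correct = TRUE)$p.value)
  } else {
    # Pratt: rank |d| including zeros, drop zero ranks from W+/W-,
    # normal approximation with reduced mean/variance
    r <- rank(abs(d))
    Wp <- sum(r[d > 0]); Wm <- sum(r[d < 0])
    n <- length(d); n0 <- n_zero
    mu <- (n * (n + 1) - n0 * (n0 + 1)) / 4
    ties_tab <- table(r)
    sig2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
      sum(ties_tab^3 - ties_tab) / 48
    exact <- FALSE
    z <- (Wp - mu - sign(Wp - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    n <- sum(nz)
  }
  test_result("Wilcoxon signed-rank", min(Wp, Wm), p,
              if (zero_method == "drop") n else sum(nz), exact)
}

#' Mann-Whitney U test
#'
#' Two-sided unpaired rank-sum test. The statistic is `U = min(U_A, U_B)`
#' with mid-ranks for ties. The p-value is exact (enumeration of group
#' labelings) when the combined sample size is at most 12 and there are no
#' ties, and a tie-corrected, continuity-corrected normal approximation
#' otherwise.
#'
#' @param a,b numeric vectors, both non-empty.
#' @return A `test_result` with fields `method`, `statistic` (U), `p_value`,
#'   `n` (the two group sizes), `exact`.
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b) || !all(is.finite(c(a, b))))
    stop("both groups must be non-empty and finite")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  Ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  Ub <- na * nb - Ua
  ties <- anyDuplicated(r) > 0
  exact <- (na + nb) <= 12 && !ties
  p <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  test_result("Mann-Whitney U", min(Ua, Ub), p, c(na, nb), exact)
}

#' Parse a contrast specification string
#'
#' Two forms are understood:
#' * `"paired:<regionA>:<regionB>[:<metric>]"` — within-sample comparison
#'   of a metric between two regions (Wilcoxon signed-rank);
#' * `"group:<col>=<v1|v2>:<col>=<v3|v4>[:<region>][:<metric>]"` —
#'   between-group comparison of a metric in one region (Mann-Whitney U).
#'
#' The default metric is `mc_per_mm2` and the default region `CTCL`.
#'
#' @param text contrast string.
#' @return A named list describing the contrast.
#' @export
parse_contrast <- function(text) {
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  metrics <- c("mc_per_mm2", "mc_pct_of_cells", "pct_degranulated",
               "mc_count", "total_cells")
  if (parts[1] == "paired") {
    if (length(parts) < 3L) stop("paired contrast needs two regions")
    metric <- if (length(parts) >= 4L) parts[4] else "mc_per_mm2"
    list(type = "paired", a = parts[2], b = parts[3], metric = metric)
  } else if (parts[1] == "group") {
    if (length(parts) < 3L) stop("group contrast needs two group definitions")
    parse_side <- function(s) {
      kv <- strsplit(s, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L) stop("group side must be <column>=<v1|v2|...>")
      list(by = kv[1], values = strsplit(kv[2], "|", fixed = TRUE)[[1]])
    }
    a <- parse_side(parts[2]); b <- parse_side(parts[3])
    rest <- if (length(parts) > 3L) parts[4:length(parts)] else character()
    region <- "CTCL"; metric <- "mc_per_mm2"
    for (p in rest) if (p %in% metrics) metric <- p else region <- p
    list(type = "group", a = a, b = b, region = region, metric = metric)
  } else stop("unknown contrast type: ", parts[1])
}

#' Cohort comparison
#'
#' Dispatches a contrast over a cohort table (one row per sample and
#' region, as assembled by [run_cohort()]): paired region contrasts use the
#' Wilcoxon signed-rank test on within-sample differences, group contrasts
#' the Mann-Whitney U test. Significance is declared when `p < alpha`
#' (strictly less, two-sided).
#'
#' @param table cohort data frame with columns `sample_id`, `region`,
#'   metadata columns, and metric columns.
#' @param contrast a string for [parse_contrast()] or its parsed list.
#' @param alpha significance level.
#' @param zero_method passed to [wilcoxon_signed_rank()].
#' @return A `test_result` with an added `significant` flag and `contrast`.
#' @export
cohort_compare <- function(table, contrast, alpha = 0.05,
                           zero_method = "drop") {
  if (is.character(contrast)) contrast <- parse_contrast(contrast)
  if (contrast$type == "paired") {
    a <- table[table$region == contrast$a, c("sample_id", contrast$metric)]
    b <- table[table$region == contrast$b, c("sample_id", contrast$metric)]
    m <- merge(a, b, by = "sample_id", suffixes = c("_a", "_b"))
    va <- m[[paste0(contrast$metric, "_a")]]
    vb <- m[[paste0(contrast$metric, "_b")]]
    ok <- is.finite(va) & is.finite(vb)
    if (sum(ok) < 1L) stop("contrast has no complete pairs")
    res <- wilcoxon_signed_rank(va[ok], vb[ok], zero_method = zero_method)
  } else {
    rows <- table[table$region == contrast$region, , drop = FALSE]
    va <- rows[[contrast$metric]][rows[[contrast$a$by]] %in% contrast$a$values]
    vb <- rows[[contrast$metric]][rows[[contrast$b$by]] %in% contrast$b$values]
    va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
    if (length(va) < 1L || length(vb) < 1L)
      stop("each contrast group needs at least one sample")
    res <- mann_whitney_u(va, vb)
  }
  res$significant <- res$p_value < alpha
  res$contrast <- contrast
  res
}
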