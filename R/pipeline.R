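#' Run the full analysis pipeline on one sample
#'
#' Stain separation, nuclear segmentation, Parzen density mapping,
#' infiltrate extraction, proximity-band construction, mast-cell detection
#' with degranulation classification, and per-region metrics. Optional
#' override masks replace the epidermis heuristic and/or the automatic
#' infiltrate extraction (the programmatic equivalent of manual
#' correction).
#'
#' @param image a [calibrated_image()] or an image file path.
#' @param config a [run_config()].
#' @param stains a [stain_model()].
#' @param sample_id,group,stage metadata for the metrics rows; `sample_id`
#'   defaults to the image's.
#' @param epidermis_override,ctcl_override optional masks (logical matrix,
#'   [label_mask()], or mask file path).
#' @param out_dir when given, masks, per-cell and per-mast-cell CSVs, the
#'   metrics CSV and a run log are written there.
#' @return A list of class `sample_run`: `metrics`, `regions`, `records`,
#'   `cells`, `density`, `conc`, `log`.
#' @export
run_sample <- function(image, config = run_config(),
                       stains = default_stain_model(),
                       sample_id = NULL, group = NA_character_,
                       stage = NA_character_,
                       epidermis_override = NULL, ctcl_override = NULL,
                       out_dir = NULL) {
  stage_name <- "image_io"
  res <- tryCatch({
    if (is.character(image))
      image <- load_calibrated_image(image, default_um_per_px = config$um_per_px)
    stopifnot(inherits(image, "calibrated_image"))
    if (is.null(sample_id)) sample_id <- image$sample_id
    if (is.character(epidermis_override))
      epidermis_override <- read_region_mask(epidermis_override)
    if (is.character(ctcl_override))
      ctcl_override <- read_region_mask(ctcl_override)
    upp <- image$um_per_px

    stage_name <- "stain_separation"
    od <- rgb_to_od(image, I0 = stains$background)
    conc <- deconvolve(od, stains)

    stage_name <- "region_model"
    tissue <- tissue_mask(od, config, upp)
    if (!any(tissue)) warning("no tissue found in sample ", sample_id)
    epid <- suppressWarnings(
      epidermis_mask(conc$H, tissue, config, upp, override = epidermis_override))
    dermis <- tissue & !epid

    stage_name <- "nuclei_detection"
    cells <- detect_nuclei(conc$H, dermis, config, upp)

    stage_name <- "region_model"
    dens <- parzen_density(cells, dim(conc$H), upp,
                           sigma_um = config$parzen_sigma_um,
                           decim = config$parzen_decim)
    ctcl <- extract_infiltrate(dens, dermis, config, upp,
                               override = ctcl_override)
    if (!any(ctcl)) warning("empty infiltrate mask in sample ", sample_id)
    regions <- suppressMessages(
      proximity_bands(ctcl, epid, tissue, upp, config$d1_um, config$d2_um))

    stage_name <- "mast_cell_detection"
    records <- detect_mast_cells(conc$T, dermis, regions, config, upp)

    stage_name <- "metrics_stats"
    metrics <- suppressMessages(
      compute_sample_metrics(cells, records, regions, sample_id, group, stage))

    log <- list(sample_id = sample_id, um_per_px = upp,
                image_dim = dim(image$pixels)[1:2],
                n_cells = cells$count, n_mc = nrow(records),
                residual_rms = conc$residual_rms,
                clipped_frac = conc$clipped_frac,
                config = unclass(config),
                stains = list(hematoxylin = stains$hematoxylin,
                              aec = stains$aec,
                              background = stains$background),
                package_version = as.character(utils::packageVersion("mcquant")))
    structure(list(metrics = metrics, regions = regions, records = records,
                   cells = cells, density = dens, conc = conc, log = log),
              class = "sample_run")
  }, error = function(e) {
    stop("pipeline stage '", stage_name, "' failed for sample ",
         if (is.null(sample_id)) "<unknown>" else sample_id, ": ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    pre <- file.path(out_dir, res$log$sample_id)
    write_region_mask(res$regions, paste0(pre, "_regions.tif"))
    write.csv(res$cells$centroids, paste0(pre, "_cells.csv"), row.names = FALSE)
    write.csv(res$records, paste0(pre, "_mc.csv"), row.names = FALSE)
    write_metrics_table(res$metrics, paste0(pre, "_metrics.csv"))
    yaml::write_yaml(res$log, paste0(pre, "_run.yaml"))
  }
  res
}

#' @export
print.sample_run <- function(x, ...) {
  cat(sprintf("<sample_run> %s: %d cells, %d mast cells\n",
              x$log$sample_id, x$log$n_cells, nrow(x$records)))
  print(x$metrics[, c("region", "area_mm2", "total_cells", "mc_count",
                      "mc_per_mm2", "mc_pct_of_cells", "pct_degranulated")])
  invisible(x)
}

#' Run the pipeline over a cohort and compare groups
#'
#' Per-sample runs are independent; the assembled cohort table is sorted by
#' sample id and region so the result does not depend on manifest order.
#' Samples whose image cannot be read are skipped with a recorded error and
#' the run continues.
#'
#' @param manifest data frame or CSV path with columns `sample_id`,
#'   `image_path`, optional `group`, `stage`, `epidermis_mask`, `ctcl_mask`.
#' @param config a [run_config()].
#' @param stains a [stain_model()].
#' @param contrasts character vector of contrast strings for
#'   [parse_contrast()], or `NULL` for the table only.
#' @param out_dir optional output directory for the cohort table and test
#'   results.
#' @return A list of class `cohort_run`: `table` (one row per sample and
#'   region), `tests` (list of `test_result`), `errors` (data frame of
#'   skipped samples).
#' @export
run_cohort <- function(manifest, config = run_config(),
                       stains = default_stain_model(), contrasts = NULL,
                       out_dir = NULL) {
  if (is.character(manifest)) manifest <- read.csv(manifest)
  need <- c("sample_id", "image_path")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  errors <- list(); rows <- list()
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    res <- tryCatch({
      if (!file.exists(m$image_path)) stop("file not found: ", m$image_path)
      epi <- if (!is.null(m$epidermis_mask) && !is.na(m$epidermis_mask) &&
                 nzchar(m$epidermis_mask)) m$epidermis_mask else NULL
      ctc <- if (!is.null(m$ctcl_mask) && !is.na(m$ctcl_mask) &&
                 nzchar(m$ctcl_mask)) m$ctcl_mask else NULL
      suppressWarnings(run_sample(
        m$image_path, config, stains, sample_id = m$sample_id,
        group = if ("group" %in% names(m)) m$group else NA_character_,
        stage = if ("stage" %in% names(m)) m$stage else NA_character_,
        epidermis_override = epi, ctcl_override = ctc))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("sample ", m$sample_id, " skipped: ", conditionMessage(res))
      errors[[length(errors) + 1L]] <-
        data.frame(sample_id = m$sample_id, error = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res$metrics
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    compute_empty_cohort_table()
  ord <- order(table$sample_id, match(table$region, c("CTCL", "P1", "P2")))
  table <- table[ord, , drop = FALSE]
  rownames(table) <- NULL
  tests <- lapply(contrasts, function(ct)
    cohort_compare(table, ct, alpha = config$alpha,
                   zero_method = config$zero_method))
  errors <- if (length(errors)) do.call(rbind, errors)
            else data.frame(sample_id = character(), error = character())
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_metrics_table(table, file.path(out_dir, "cohort_metrics.csv"))
    if (length(tests)) {
      tdf <- do.call(rbind, lapply(seq_along(tests), function(k) {
        t <- tests[[k]]
        data.frame(contrast = contrasts[k], method = t$method,
                   statistic = t$statistic, p_value = t$p_value,
                   n = paste(t$n, collapse = "/"), exact = t$exact,
                   significant = t$significant)
      }))
      write.csv(tdf, file.path(out_dir, "cohort_tests.csv"), row.names = FALSE)
    }
  }
  structure(list(table = table, tests = tests, errors = errors),
            class = "cohort_run")
}

compute_empty_cohort_table <- function() {
  data.frame(sample_id = character(), group = character(),
             stage = character(), region = character(),
             area_mm2 = numeric(), total_cells = integer(),
             mc_count = integer(), degranulated_count = integer(),
             mc_per_mm2 = numeric(), mc_pct_of_cells = numeric(),
             pct_degranulated = numeric())
}

#' Run a fully synthetic planted cohort in memory
#'
#' Generates the standard validation cohort (early-stage samples with a
#' higher mast-cell density than advanced-stage samples; infiltrate and
#' inner band equal, outer band lower), runs the full pipeline on each
#' rendered image without touching disk, and applies the two standard
#' contrasts: paired P1 vs P2 (Wilcoxon signed-rank) and early vs advanced
#' stage in the infiltrate (Mann-Whitney U).
#'
#' @param seed replicate seed; sample `i` uses `seed * 1000 + i`.
#' @param n_samples,n_early cohort composition.
#' @param base_early,base_advanced,multipliers mast-cell densities as in
#'   [synth_cohort()].
#' @param config a [run_config()]; the default matches the generator's
#'   calibration and decimates the density grid by 2 for speed.
#' @param spec_args named list of [scene_spec()] overrides.
#' @return A list: `table` (cohort metrics), `p_paired`, `p_group`, and the
#'   two `test_result`s.
#' @export
run_synthetic_cohort <- function(seed, n_samples = 20L, n_early = 10L,
                                 base_early = 300, base_advanced = 180,
                                 multipliers = c(CTCL = 1, P1 = 1, P2 = 0.5,
                                                 DERMIS_OTHER = 0.4),
                                 config = run_config(um_per_px = 2,
                                                     parzen_decim = 2L),
                                 spec_args = list()) {
  rows <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    early <- i <= n_early
    base <- if (early) base_early else base_advanced
    args <- modifyList(list(
      mc_density = setNames(base * as.numeric(multipliers), names(multipliers)),
      seed = as.integer(seed) * 1000L + i), spec_args)
    smp <- generate_sample(do.call(scene_spec, args),
                           sample_id = sprintf("S%02d", i))
    res <- suppressWarnings(run_sample(
      smp$image, config,
      stage = if (early) c("IA", "IB")[1 + (i %% 2)]
              else c("IIA", "IIB")[1 + (i %% 2)],
      group = "MF"))
    rows[[i]] <- res$metrics
  }
  table <- do.call(rbind, rows)
  t_paired <- cohort_compare(table, "paired:P1:P2", alpha = config$alpha)
  t_group <- cohort_compare(table, "group:stage=IA|IB:stage=IIA|IIB",
                            alpha = config$alpha)
  list(table = table, p_paired = t_paired$p_value, p_group = t_group$p_value,
       test_paired = t_paired, test_group = t_group)
}

#' Cohort summary: median and range per group and region
#'
#' Descriptive statistics in the layout of per-region cohort tables:
#' median (range) of each metric per grouping level and region. No
#' multiple-testing correction is applied anywhere in the package; p-values
#' from [cohort_compare()] are raw.
#'
#' @param table cohort table from [run_cohort()].
#' @param by grouping column (e.g. `"group"` or `"stage"`).
#' @param metric metric column to summarise.
#' @return Data frame: `by` level, `region`, `n`, `median`, `min`, `max`.
#' @export
summarize_cohort <- function(table, by = "group", metric = "mc_per_mm2") {
  lv <- unique(table[[by]])
  out <- list()
  for (g in lv) for (rg in unique(table$region)) {
    v <- table[[metric]][table[[by]] %in% g & table$region == rg]
    v <- v[is.finite(v)]
    if (!length(v)) next
    mr <- median_and_range(v)
    out[[length(out) + 1L]] <- data.frame(
      group = g, region = rg, n = length(v),
      median = unname(mr["median"]), min = unname(mr["min"]),
      max = unname(mr["max"]))
  }
  names(out) <- NULL
  do.call(rbind, out)
}
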