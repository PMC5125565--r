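test_that("calibrated images round-trip through TIFF and PNG with calibration", {
  px <- array(sample(0:255, 30 * 20 * 3, replace = TRUE), c(30, 20, 3))
  img <- calibrated_image(px, um_per_px = 0.5, sample_id = "rt")

  tf <- withr::local_tempfile(fileext = ".tif")
  write_calibrated_image(img, tf)
  back <- load_calibrated_image(tf)
  expect_equal(back$pixels, img$pixels)
  expect_equal(back$um_per_px, 0.5)          # from the sidecar

  pf <- withr::local_tempfile(fileext = ".png")
  write_calibrated_image(img, pf)
  back2 <- load_calibrated_image(pf)
  expect_equal(back2$pixels, img$pixels)
  expect_equal(back2$um_per_px, 0.5, tolerance = 1e-6)  # from the dpi field

  # explicit argument beats embedded metadata
  expect_equal(load_calibrated_image(tf, um_per_px = 0.9)$um_per_px, 0.9)
})

test_that("calibration falls back to the 20x default when nothing is embedded", {
  tf <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(runif(10 * 10 * 3), c(10, 10, 3)), tf)
  expect_equal(load_calibrated_image(tf)$um_per_px, 0.275)
  expect_equal(load_calibrated_image(tf, default_um_per_px = 2)$um_per_px, 2)
})

test_that("greyscale images are promoted to RGB and bad inputs error", {
  tf <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(25), 5, 5), tf)
  img <- load_calibrated_image(tf)
  expect_equal(dim(img$pixels), c(5L, 5L, 3L))
  expect_equal(img$pixels[, , 1], img$pixels[, , 3])

  expect_error(load_calibrated_image(file.path(tempdir(), "nope.tif")),
               "not found")
  bad <- withr::local_tempfile(fileext = ".tif")
  writeLines("not a tiff", bad)
  expect_error(load_calibrated_image(bad), "unreadable")
  expect_error(load_calibrated_image(tf, um_per_px = -1), "positive")
  expect_error(calibrated_image(array(300, c(2, 2, 3))), "255")
})

test_that("label masks round-trip bit-exactly with their legend", {
  lab <- matrix(sample(c(0L, 1L, 2L), 60, replace = TRUE), 6, 10)
  m <- label_mask(lab, c("1" = "CTCL", "2" = "P1"))
  tf <- withr::local_tempfile(fileext = ".tif")
  write_region_mask(m, tf)
  back <- read_region_mask(tf)
  expect_identical(back$labels, m$labels)
  expect_equal(back$legend, m$legend)

  zero <- label_mask(matrix(0L, 4, 4), c("1" = "CTCL"))
  write_region_mask(zero, tf)
  expect_identical(read_region_mask(tf)$labels, zero$labels)

  expect_error(label_mask(matrix(3L, 2, 2), c("1" = "CTCL")), "legend")
})

test_that("metrics tables are sorted, complete, and use empty undefined fields", {
  rows <- data.frame(
    sample_id = c("B", "B", "B", "A", "A", "A"),
    group = "MF", stage = "IA",
    region = c("P2", "CTCL", "P1", "P1", "CTCL", "P2"),
    area_mm2 = 0.05, total_cells = 400L, mc_count = c(10L, 10L, 10L, 10L, 10L, 0L),
    degranulated_count = 4L,
    mc_per_mm2 = 200, mc_pct_of_cells = 2.5,
    pct_degranulated = c(40, 40, 40, 40, 40, NA))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_metrics_table(rows, tf)
  txt <- readLines(tf)
  expect_length(txt, 7L)                       # header + 6 rows
  got <- read.csv(tf)
  expect_equal(got$sample_id, rep(c("A", "B"), each = 3))
  expect_equal(got$region, rep(c("CTCL", "P1", "P2"), 2))
  expect_true(is.na(got$pct_degranulated[got$sample_id == "A" &
                                           got$region == "P2"]))
  expect_true(grepl(",$", txt[4]))             # undefined written as empty field

  write_metrics_table(rows[0, ], tf)
  expect_length(readLines(tf), 1L)             # header-only, not an error
})

test_that("run configuration validates physical constraints and round-trips", {
  expect_error(run_config(d1_um = 60, d2_um = 30), "d1 < d2")
  expect_error(run_config(alpha = 1.2), "alpha")
  expect_error(run_config(parzen_sigma_um = -5), "positive")
  cfg <- run_config(um_per_px = 2, rho_min = 3500)
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, tf)
  back <- read_run_config(tf)
  expect_equal(unclass(back), unclass(cfg))
  writeLines("bogus_key: 1", tf)
  expect_error(read_run_config(tf), "unknown config keys")
})
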