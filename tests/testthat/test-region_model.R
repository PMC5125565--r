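test_that("tissue mask recovers a disc area and removes speckle", {
  upp <- 4
  n <- 320                       # 1.28 mm field at 4 um/px
  xy <- (seq_len(n) - 0.5) * upp
  D <- outer(xy - 640, xy - 640, function(a, b) sqrt(a^2 + b^2))
  od <- array(0, c(n, n, 3))
  od[, , 1][D <= 564.2] <- 0.3   # disc of ~1 mm^2
  od[, , 1][5, 5] <- 0.3         # isolated speck
  m <- tissue_mask(od, run_config(um_per_px = upp), upp)
  area_mm2 <- sum(m) * upp^2 * 1e-6
  expect_equal(area_mm2, 1, tolerance = 0.02)
  expect_false(m[5, 5])          # speck removed by the minimum-area filter
  expect_equal(sum(tissue_mask(array(0, c(20, 20, 3)),
                               run_config(um_per_px = upp), upp)), 0)
})

test_that("Parzen density conserves mass and matches the closed-form peak", {
  upp <- 2; n <- 240; sigma <- 25
  cells <- data.frame(row = 120.5, col = 120.5)
  dm <- parzen_density(cells, c(n, n), upp, sigma_um = sigma)
  px_area_mm2 <- upp^2 * 1e-6
  expect_equal(sum(dm$values) * px_area_mm2, 1, tolerance = 0.01)
  peak_expected <- 1e6 / (2 * pi * sigma^2)   # ~254.6 cells/mm^2
  expect_equal(max(dm$values), peak_expected, tolerance = 0.01 * peak_expected)

  # superposition: two cells equal the sum of their single-cell maps
  c2 <- data.frame(row = c(80.5, 160.5), col = c(100.5, 150.5))
  both <- parzen_density(c2, c(n, n), upp, sigma)$values
  one <- parzen_density(c2[1, ], c(n, n), upp, sigma)$values +
    parzen_density(c2[2, ], c(n, n), upp, sigma)$values
  expect_lt(max(abs(both - one)), 1e-9)

  empty <- parzen_density(data.frame(row = numeric(), col = numeric()),
                          c(50, 50), upp, sigma)
  expect_equal(max(empty$values), 0)
})

test_that("mass conservation holds across random cell sets", {
  set.seed(31)
  upp <- 2; n <- 220; sigma <- 25
  margin <- ceiling(3 * sigma / upp)
  for (rep in 1:20) {
    k <- sample(3:25, 1)
    cells <- data.frame(row = runif(k, margin, n - margin),
                        col = runif(k, margin, n - margin))
    dm <- parzen_density(cells, c(n, n), upp, sigma)
    expect_equal(sum(dm$values) * upp^2 * 1e-6, k, tolerance = 0.01 * k)
  }
})

test_that("decimated density evaluation approximates the full grid", {
  set.seed(13)
  upp <- 2; n <- 200
  cells <- data.frame(row = runif(30, 50, 150), col = runif(30, 50, 150))
  full <- parzen_density(cells, c(n, n), upp, 25, decim = 1)$values
  dec <- parzen_density(cells, c(n, n), upp, 25, decim = 2)$values
  expect_equal(dim(dec), c(n, n))
  expect_lt(max(abs(dec - full)) / max(full), 0.05)
})

test_that("infiltrate extraction thresholds the density map with overrides", {
  upp <- 2; n <- 200
  xy <- (seq_len(n) - 0.5) * upp
  D <- outer(xy - 200, xy - 200, function(a, b) sqrt(a^2 + b^2))
  dens <- matrix(1500, n, n); dens[D <= 120] <- 8000
  dermis <- matrix(TRUE, n, n)
  cfg <- run_config(um_per_px = upp)
  m <- extract_infiltrate(structure(list(values = dens), class = "density_map"),
                          dermis, cfg, upp)
  truth <- D <= 120
  expect_gte(sum(m & truth) / sum(m | truth), 0.9)
  expect_equal(sum(extract_infiltrate(
    structure(list(values = matrix(3000, n, n)), class = "density_map"),
    dermis, cfg, upp)), 0)
  ov <- matrix(FALSE, n, n); ov[1:5, 1:5] <- TRUE
  expect_identical(extract_infiltrate(dens, dermis, cfg, upp, override = ov), ov)
  expect_error(extract_infiltrate(dens, dermis, cfg, upp,
                                  override = matrix(TRUE, 2, 2)), "shape")
})

test_that("proximity bands match analytic annulus areas within 2%", {
  upp <- 1; n <- 400
  xy <- (seq_len(n) - 0.5) * upp
  D <- outer(xy - 200, xy - 200, function(a, b) sqrt(a^2 + b^2))
  ctcl <- D <= 100
  tissue <- matrix(TRUE, n, n)
  epid <- matrix(FALSE, n, n)
  rs <- proximity_bands(ctcl, epid, tissue, upp, d1 = 30, d2 = 60)
  a <- region_areas(rs) * 1e6    # um^2
  expect_equal(unname(a["P1"]), pi * (130^2 - 100^2), tolerance = 0.02)
  expect_equal(unname(a["P2"]), pi * (160^2 - 130^2), tolerance = 0.02)

  # pointwise band-distance contract (half-open intervals, pixel slack)
  dist_um <- as.matrix(EBImage::distmap(EBImage::Image(1 - ctcl * 1))) * upp
  half_diag <- upp * sqrt(2) / 2
  expect_true(all(dist_um[rs$labels == 3L] <= 30 + half_diag))
  expect_true(all(dist_um[rs$labels == 3L] > 0))
  expect_true(all(dist_um[rs$labels == 4L] > 30 - half_diag))
  expect_true(all(dist_um[rs$labels == 4L] <= 60 + half_diag))
})

test_that("the region partition is disjoint, tissue-bounded, and prioritised", {
  smp <- generate_sample(scene_spec(seed = 21))
  cfg <- run_config(um_per_px = 2, parzen_decim = 2L)
  res <- suppressWarnings(run_sample(smp$image, cfg))
  lab <- res$regions$labels
  expect_true(all(lab %in% 0:5))
  od <- rgb_to_od(smp$image)
  tissue <- tissue_mask(od, cfg, 2)
  expect_true(all(tissue[lab > 0L]))           # union within tissue
  expect_false(any(lab == 3L & res$regions$labels == 1L))  # exclusive labels
  # P1/P2 never overlap epidermis or infiltrate by construction
  expect_equal(sum(lab == 1L & lab == 2L), 0L)
})

test_that("empty infiltrates give empty bands and a message", {
  tissue <- matrix(TRUE, 50, 50)
  expect_message(
    rs <- proximity_bands(matrix(FALSE, 50, 50), matrix(FALSE, 50, 50),
                          tissue, 1, 30, 60),
    "empty")
  expect_equal(sum(rs$labels %in% c(2L, 3L, 4L)), 0L)
  expect_equal(sum(rs$labels == 5L), 2500L)
  expect_error(proximity_bands(matrix(FALSE, 5, 5), matrix(FALSE, 5, 5),
                               matrix(TRUE, 5, 5), 1, 60, 30), "d1 < d2")
})

test_that("the epidermis heuristic finds the planted band and honours overrides", {
  smp <- generate_sample(scene_spec(seed = 33))
  conc <- deconvolve(rgb_to_od(smp$image))
  cfg <- run_config(um_per_px = 2)
  tissue <- tissue_mask(rgb_to_od(smp$image), cfg, 2)
  epi <- epidermis_mask(conc$H, tissue, cfg, 2)
  truth <- smp$truth$zones$labels == 1L
  expect_gte(sum(epi & truth) / sum(epi | truth), 0.8)

  ov <- matrix(FALSE, nrow(tissue), ncol(tissue)); ov[1:10, ] <- TRUE
  expect_identical(epidermis_mask(conc$H, tissue, cfg, 2, override = ov), ov)
  expect_error(epidermis_mask(conc$H, tissue, cfg, 2,
                              override = matrix(TRUE, 3, 3)), "shape")

  # a tissue slab with uniform faint H has no epidermal band
  flatH <- matrix(0.05, 100, 100)
  flat_tissue <- matrix(FALSE, 100, 100); flat_tissue[20:90, ] <- TRUE
  expect_warning(e2 <- epidermis_mask(flatH, flat_tissue, cfg, 2), "epidermis")
  expect_equal(sum(e2), 0)
})
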