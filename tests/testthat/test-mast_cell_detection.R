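test_that("a planted compact mast-cell body yields one blob of the right area", {
  upp <- 0.5
  Tm <- matrix(0, 120, 120)
  Tm <- mcquant:::paint_disks(Tm, x_um = 30, y_um = 30, r_um = 6,
                              value = 0.9, um_per_px = upp)
  blobs <- detect_tryptase_blobs(Tm, matrix(TRUE, 120, 120),
                                 run_config(um_per_px = upp), upp)
  expect_equal(nrow(blobs), 1L)
  expect_equal(blobs$area_um2, pi * 36, tolerance = 0.1)
  expect_gte(blobs$solidity, 0.9)
  expect_lt(abs(blobs$x_um - 30), 1)

  none <- detect_tryptase_blobs(matrix(0, 50, 50), matrix(TRUE, 50, 50),
                                run_config(um_per_px = upp), upp)
  expect_equal(nrow(none), 0L)
})

test_that("sub-noise specks are discarded by the area gate", {
  upp <- 0.275                     # 1 px = 0.0756 um^2
  Tm <- matrix(0, 60, 60)
  Tm[30, 30] <- 0.9
  cfg <- run_config(um_per_px = upp, mc_median_um = 0)  # no smoothing
  blobs <- detect_tryptase_blobs(Tm, matrix(TRUE, 60, 60), cfg, upp)
  expect_equal(nrow(blobs), 0L)
})

test_that("single-linkage clustering matches a transitive-closure oracle", {
  mkblobs <- function(x, y) data.frame(x_um = x, y_um = y)
  # chain transitivity: 0, 10, 20 um with r_link = 12 forms one cluster
  expect_equal(length(unique(cluster_blobs(mkblobs(c(0, 10, 20), c(0, 0, 0)),
                                           12))), 1L)
  expect_equal(length(unique(cluster_blobs(mkblobs(c(0, 3, 5), c(0, 4, 0)),
                                           12))), 1L)
  expect_equal(length(unique(cluster_blobs(mkblobs(c(0, 40), c(0, 0)), 12))),
               2L)
  set.seed(77)
  for (rep in 1:25) {
    k <- sample(2:12, 1)
    x <- runif(k, 0, 60); y <- runif(k, 0, 60)
    got <- cluster_blobs(mkblobs(x, y), 12)
    want <- single_linkage_oracle(x, y, 12)
    # same partition up to relabeling
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(v) length(unique(v))) == 1))
  }
})

test_that("the degranulation rule follows the compact-blob definition", {
  cfg <- run_config()
  expect_equal(classify_degranulation(110, 0.93, cfg), "NON_DEGRANULATED")
  expect_equal(classify_degranulation(rep(15, 6), rep(0.9, 6), cfg),
               "DEGRANULATED")                    # fragmented cluster
  expect_equal(classify_degranulation(110, 0.5, cfg), "DEGRANULATED")
  expect_equal(classify_degranulation(30, 0.95, cfg), "DEGRANULATED")
  expect_true(is.na(classify_degranulation(c(5, 5), c(1, 1), cfg)))  # debris
})

test_that("records aggregate clusters with area-weighted centroids", {
  blobs <- data.frame(
    blob_id = 1:3,
    row = c(10, 10, 100), col = c(10, 30, 100),
    x_um = c(5, 15, 50), y_um = c(5, 5, 50),
    area_um2 = c(30, 10, 100), solidity = c(0.9, 0.9, 0.95))
  recs <- make_mc_records(blobs, run_config(um_per_px = 0.5))
  recs <- recs[order(recs$x_um), ]
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$fragments, c(2L, 1L))
  expect_equal(recs$state, c("DEGRANULATED", "NON_DEGRANULATED"))
  expect_equal(recs$x_um[1], (30 * 5 + 10 * 15) / 40)
})

test_that("region assignment uses the centroid pixel and flags exclusions", {
  lab <- matrix(0L, 40, 40)
  lab[1:8, ] <- 1L      # epidermis
  lab[15:25, 15:25] <- 2L
  lab[30:40, ] <- 3L
  rs <- label_mask(lab, mcquant:::REGION_LEGEND)
  attr(rs, "um_per_px") <- 1
  recs <- data.frame(cluster_id = 1:4,
                     row = c(20, 35, 4, 12), col = c(20, 5, 4, 2),
                     x_um = 0, y_um = 0, area_um2 = 50, fragments = 1L,
                     state = "NON_DEGRANULATED")
  out <- assign_regions(recs, rs)
  expect_equal(out$region, c("CTCL", "P1", "EPIDERMIS", NA))
  expect_equal(out$excluded, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("detection and classification are invariant under translation and rotation", {
  upp <- 0.5
  base <- matrix(0, 200, 200)
  # one compact body and one fragmented cluster
  base <- mcquant:::paint_disks(base, x_um = c(30, 70, 64, 76, 70),
                                y_um = c(30, 70, 70, 70, 63),
                                r_um = c(5.5, 2, 1.2, 1.2, 1.2),
                                value = 0.9, um_per_px = upp)
  cfg <- run_config(um_per_px = upp)
  dermis <- matrix(TRUE, 200, 200)
  summarise <- function(m) {
    r <- detect_mast_cells(m, dermis, NULL, cfg, upp)
    r <- r[order(r$state), ]
    list(n = nrow(r), states = r$state, areas = r$area_um2,
         frags = r$fragments)
  }
  ref <- summarise(base)
  shifted <- matrix(0, 200, 200)
  shifted[15:200, 15:200] <- base[1:186, 1:186]
  rot <- t(base)[, 200:1]            # 90-degree rotation
  expect_equal(summarise(shifted)[c("n", "states", "frags")],
               ref[c("n", "states", "frags")])
  expect_equal(summarise(rot), ref)
})
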