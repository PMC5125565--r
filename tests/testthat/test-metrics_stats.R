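mk_region_set <- function(um_per_px = 10) {
  lab <- matrix(0L, 50, 50)
  lab[1:20, 1:25] <- 2L      # CTCL: 500 px = 0.05 mm^2 at 10 um/px
  lab[25:34, 1:20] <- 3L     # P1
  lab[40:49, 1:20] <- 4L     # P2
  rs <- label_mask(lab, mcquant:::REGION_LEGEND)
  attr(rs, "um_per_px") <- um_per_px
  attr(rs, "d1_um") <- 30; attr(rs, "d2_um") <- 60
  class(rs) <- c("region_set", class(rs))
  rs
}

test_that("sample metrics implement the density and percentage definitions", {
  rs <- mk_region_set()
  set.seed(1)
  # 400 cells in CTCL, 50 in P1, none in P2
  cells <- cell_set(data.frame(
    row = c(runif(400, 1, 20), runif(50, 25, 34)),
    col = c(runif(400, 1, 25), runif(50, 1, 20)),
    x_um = 0, y_um = 0), um_per_px = 10)
  recs <- data.frame(cluster_id = 1:12,
                     row = c(rep(10, 10), 30, 30), col = c(seq(2, 20, 2), 5, 10),
                     x_um = 0, y_um = 0, area_um2 = 80, fragments = 1L,
                     state = c(rep("DEGRANULATED", 4),
                               rep("NON_DEGRANULATED", 6),
                               "NON_DEGRANULATED", "NON_DEGRANULATED"),
                     region = c(rep("CTCL", 10), "P1", "P1"),
                     excluded = FALSE)
  m <- suppressMessages(compute_sample_metrics(cells, recs, rs, "s1"))
  ctcl <- m[m$region == "CTCL", ]
  expect_equal(ctcl$area_mm2, 0.05)
  expect_equal(ctcl$mc_count, 10L)
  expect_equal(ctcl$mc_per_mm2, 200)
  expect_equal(ctcl$total_cells, 400L)
  expect_equal(ctcl$mc_pct_of_cells, 2.5)
  expect_equal(ctcl$pct_degranulated, 40)
  p2 <- m[m$region == "P2", ]
  expect_equal(p2$mc_count, 0L)
  expect_true(is.na(p2$pct_degranulated))    # undefined, not zero
  expect_true(is.na(p2$mc_pct_of_cells))
  expect_true(all(m$mc_pct_of_cells <= 100, na.rm = TRUE))
})

test_that("median and range follow the order-statistic conventions", {
  expect_equal(median_and_range(c(3, 1, 2)), c(median = 2, min = 1, max = 3))
  expect_equal(median_and_range(c(1, 2, 3, 4)),
               c(median = 2.5, min = 1, max = 4))
  expect_equal(median_and_range(5), c(median = 5, min = 5, max = 5))
  expect_error(median_and_range(numeric()), "non-empty")
  expect_error(median_and_range(c(1, NA)), "finite")
})

test_that("signed-rank test matches its stated conventions and examples", {
  r <- wilcoxon_signed_rank(c(1.2, 2.5, 0.7, 3.1, 1.9))
  expect_equal(r$p_value, 0.0625)
  expect_true(r$exact)
  expect_equal(r$statistic, 0)               # W- = 0 for all-positive
  r2 <- wilcoxon_signed_rank(c(1, -1))
  expect_equal(r2$statistic, 1.5)            # mid-ranks under ties
  expect_equal(r2$p_value, 1)
  expect_false(r2$exact)                     # tie forces the normal path
  expect_message(r3 <- wilcoxon_signed_rank(c(0, 0, 0)), "zero")
  expect_equal(r3$p_value, 1)
  r4 <- suppressMessages(wilcoxon_signed_rank(c(0, 1.5, -0.5, 2)))
  expect_equal(r4$n, 3L)                     # zero dropped
  r5 <- suppressMessages(
    wilcoxon_signed_rank(c(0, 1.5, -0.5, 2), zero_method = "pratt"))
  expect_true(r5$p_value > 0 && r5$p_value <= 1)
})

test_that("signed-rank p-values equal full sign enumeration for n <= 8", {
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    d <- round(runif(n, 0.5, 10), 3) * sample(c(-1, 1), n, replace = TRUE)
    while (anyDuplicated(abs(d))) d <- d + runif(n, 0, 1e-3)
    got <- wilcoxon_signed_rank(d)
    expect_true(got$exact)
    expect_equal(got$p_value, wsr_enum_oracle(d), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U matches its examples and the labeling enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_true(r$exact)
  r2 <- mann_whitney_u(c(1, 2), c(1, 2))
  expect_equal(r2$p_value, 1)
  set.seed(23)
  for (rep in 1:30) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- runif(na); b <- runif(nb, 0, 1.5)
    got <- mann_whitney_u(a, b)
    expect_true(got$exact)
    expect_equal(got$p_value, mwu_enum_oracle(a, b), tolerance = 1e-12)
    # two-sided symmetry under group relabeling
    swapped <- mann_whitney_u(b, a)
    expect_equal(swapped$p_value, got$p_value)
    expect_equal(swapped$statistic, got$statistic)
  }
})

test_that("p-values stay in (0, 1] across random inputs", {
  set.seed(5)
  for (rep in 1:40) {
    d <- rnorm(sample(2:25, 1))
    expect_true(wilcoxon_signed_rank(d)$p_value > 0)
    expect_lte(wilcoxon_signed_rank(d)$p_value, 1)
    a <- rnorm(sample(2:15, 1)); b <- rnorm(sample(2:15, 1), 0.5)
    p <- mann_whitney_u(a, b)$p_value
    expect_true(p > 0 && p <= 1)
  }
})

test_that("cohort contrasts dispatch to the right test with strict alpha", {
  tab <- data.frame(
    sample_id = rep(sprintf("s%02d", 1:6), each = 3),
    stage = rep(c("IA", "IA", "IA", "IIB", "IIB", "IIB"), each = 3),
    region = rep(c("CTCL", "P1", "P2"), 6),
    mc_per_mm2 = c(t(cbind(c(300, 320, 310, 150, 140, 160),
                           c(290, 330, 300, 160, 150, 155),
                           c(150, 180, 170, 80, 75, 90)))))
  paired <- cohort_compare(tab, "paired:P1:P2")
  expect_match(paired$method, "Wilcoxon")
  expect_equal(paired$n, 6L)
  grp <- cohort_compare(tab, "group:stage=IA:stage=IIA|IIB")
  expect_match(grp$method, "Mann-Whitney")
  expect_equal(grp$n, c(3L, 3L))

  # exactly p = alpha is reported as not significant ("less than 0.05")
  r <- cohort_compare(tab[tab$sample_id %in% sprintf("s%02d", 1:5), ],
                      "paired:P1:P2", alpha = 0.0625)
  expect_equal(r$p_value, 0.0625)
  expect_false(r$significant)
  expect_error(cohort_compare(tab, "group:stage=IA:stage=XX"), "at least one")
  expect_error(parse_contrast("nonsense:a:b"), "unknown contrast")
})
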