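test_that("degenerate regions return the equal-area circle", {
  e1 <- fit_region_ellipse(5, 5, pixel_size = 2)
  expect_equal(e1$major, 2 * sqrt(4 / pi))
  expect_equal(e1$minor, e1$major)
  # collinear run of pixels
  e2 <- fit_region_ellipse(rep(3, 2), 4:5, pixel_size = 1)
  expect_equal(e2$major, 2 * sqrt(2 / pi))
  e3 <- fit_region_ellipse(rep(2, 7), 1:7, pixel_size = 1)
  expect_equal(e3$major, e3$minor)
})

test_that("a digital disk fits a circle of the right diameter", {
  lab <- draw_disks(50, 50, matrix(c(25.5, 25.5), 1), 20)
  w <- which(lab == 1L, arr.ind = TRUE)
  e <- fit_region_ellipse(w[, 1], w[, 2], pixel_size = 1)
  expect_equal(e$major, 40, tolerance = 1 / 40)   # +/- 1 px discretization
  expect_equal(e$minor, 40, tolerance = 1 / 40)
  expect_true(is.finite(e$orientation))
})

test_that("a 2:1 digital ellipse recovers its axis ratio and orientation", {
  rowg <- matrix(seq_len(80), 80, 80)
  colg <- matrix(seq_len(80), 80, 80, byrow = TRUE)
  inside <- ((colg - 40.5) / 30)^2 + ((rowg - 40.5) / 15)^2 <= 1
  w <- which(inside, arr.ind = TRUE)
  e <- fit_region_ellipse(w[, 1], w[, 2], pixel_size = 1)
  expect_equal(e$major / e$minor, 2, tolerance = 0.02)
  expect_equal(abs(e$orientation), 0, tolerance = 0.02)  # major axis horizontal
  # equal-area contract
  expect_equal(pi * e$major * e$minor / 4, nrow(w), tolerance = 1e-12)
})

test_that("every fitted ellipse satisfies the equal-area property", {
  set.seed(53)
  for (i in 1:30) {
    n <- sample(1:60, 1)
    rows <- sample(1:40, n, replace = TRUE)
    cols <- sample(1:40, n, replace = TRUE)
    keep <- !duplicated(cbind(rows, cols))
    rows <- rows[keep]; cols <- cols[keep]
    ps <- runif(1, 0.5, 4)
    e <- fit_region_ellipse(rows, cols, pixel_size = ps)
    area <- length(rows) * ps^2
    expect_equal(pi * e$major * e$minor / 4, area, tolerance = 0.005)
    expect_lte(e$minor, e$major + 1e-12)
  }
})

test_that("the area filter keeps exactly the in-range components", {
  # areas 5, 100, 6000 nm^2 at 1 nm/px -> one survivor
  m <- matrix(0L, 110, 120)
  m[1, 1:5] <- 1L                               # 5 px = 5 nm^2
  m[20:29, 20:29] <- 2L                         # 100 nm^2
  m[41:100, 41:140 - 40] <- 3L                  # 6000 nm^2
  lm <- labeled_mask(m)
  got <- measure_fibrils(lm, pixel_size = 1)
  expect_equal(nrow(got), 1)
  expect_equal(got$area_nm2, 100)
  expect_equal(measure_fibrils(labeled_mask(matrix(0L, 5, 5)), 1),
               measure_fibrils(lm, 1, min_area = 7000, max_area = 8000))
})

test_that("the survivor set matches a brute-force pixel-count filter", {
  set.seed(61)
  cfgs <- list(c(ps = 1.5, lo = 10, hi = 5000), c(ps = 3, lo = 50, hi = 900))
  for (cf in cfgs) {
    fg <- matrix(runif(96 * 96) < 0.35, 96, 96)
    lm <- label_components(binary_mask(fg))
    got <- measure_fibrils(lm, cf["ps"], min_area = cf["lo"], max_area = cf["hi"])
    sizes <- table(factor(lm$labels[lm$labels > 0], levels = seq_len(lm$n)))
    want <- which(as.integer(sizes) * cf["ps"]^2 >= cf["lo"] &
                  as.integer(sizes) * cf["ps"]^2 <= cf["hi"])
    expect_equal(got$label, as.integer(want))
  }
})

test_that("raising min_area or lowering max_area never adds survivors", {
  set.seed(67)
  fg <- matrix(runif(64 * 64) < 0.4, 64, 64)
  lm <- label_components(binary_mask(fg))
  n_base <- nrow(measure_fibrils(lm, 1, min_area = 5, max_area = 2000))
  expect_gte(n_base, nrow(measure_fibrils(lm, 1, min_area = 20, max_area = 2000)))
  expect_gte(n_base, nrow(measure_fibrils(lm, 1, min_area = 5, max_area = 300)))
})

test_that("doubling pixel size quadruples areas and doubles diameters", {
  set.seed(71)
  fg <- matrix(runif(48 * 48) < 0.3, 48, 48)
  lm <- label_components(binary_mask(fg))
  a <- measure_fibrils(lm, 1, min_area = 0.1, max_area = Inf)
  b <- measure_fibrils(lm, 2, min_area = 0.4, max_area = Inf)
  expect_equal(b$area_nm2, 4 * a$area_nm2)
  expect_equal(b$diameter_nm, 2 * a$diameter_nm)
  expect_equal(b$major_nm, 2 * a$major_nm)
})

test_that("border-touching instances are measured unless excluded", {
  m <- matrix(0L, 20, 20)
  m[1:5, 1:5] <- 1L     # touches border
  m[10:14, 10:14] <- 2L
  lm <- labeled_mask(m)
  expect_equal(nrow(measure_fibrils(lm, 1)), 2)
  kept <- measure_fibrils(lm, 1, exclude_border = TRUE)
  expect_equal(kept$label, 2L)
})

test_that("diameter histogram counts and fractions follow the binning rules", {
  s <- summarize_fibrils(tibble::tibble(diameter_nm = c(15, 15, 25)))
  expect_equal(s$histogram$count[1:2], c(2, 1))
  expect_equal(s$histogram$fraction[1:2], c(2 / 3, 1 / 3))
  expect_equal(sum(s$histogram$fraction), 1)

  # closed upper edge: exactly 150 lands in [140, 150]
  s150 <- summarize_fibrils(tibble::tibble(diameter_nm = 150))
  expect_equal(s150$histogram$count[14], 1)
  # bin edges are left-closed: 20 belongs to [20, 30)
  s20 <- summarize_fibrils(tibble::tibble(diameter_nm = 20))
  expect_equal(s20$histogram$count[2], 1)

  # out-of-range diameters stay in n and the mean but not the histogram
  sx <- summarize_fibrils(tibble::tibble(diameter_nm = c(5, 60, 200)))
  expect_equal(sx$n_fibrils, 3)
  expect_equal(sum(sx$histogram$count), 1)
  expect_equal(sx$mean_diameter, mean(c(5, 60, 200)))

  s0 <- summarize_fibrils(tibble::tibble(diameter_nm = numeric()))
  expect_equal(s0$n_fibrils, 0)
  expect_equal(sum(s0$histogram$fraction), 0)
})

test_that("histogramming 1000 sampled diameters matches direct tabulation", {
  set.seed(73)
  d <- rnorm(3000, 60, 10)
  d <- d[d > 10 & d < 150][1:1000]
  s <- summarize_fibrils(tibble::tibble(diameter_nm = d))
  # direct tabulation oracle with the same edge conventions
  want <- sapply(seq(10, 140, 10), function(lo) {
    hi <- lo + 10
    if (hi == 150) sum(d >= lo & d <= hi) else sum(d >= lo & d < hi)
  })
  expect_equal(s$histogram$count, as.integer(want))
  expect_equal(s$histogram$fraction, want / sum(want))
})

test_that("tidy/glance/autoplot surfaces work for fibril stats", {
  s <- summarize_fibrils(tibble::tibble(diameter_nm = c(30, 45, 60)))
  expect_s3_class(tidy(s), "tbl_df")
  expect_equal(nrow(tidy(s)), 14)
  g <- glance(s)
  expect_equal(g$n_fibrils, 3)
  expect_s3_class(autoplot(s), "ggplot")
})
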