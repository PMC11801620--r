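rand_mask <- function(nr = 32, nc = 32, p = 0.3) {
  binary_mask(matrix(runif(nr * nc) < p, nr, nc))
}

test_that("consensus is the pixel-wise 2-of-3 majority", {
  set.seed(81)
  m <- rand_mask()
  un <- consensus_mask(list(m, m, m), pixel_size = 1)
  expect_identical(un$mask$pixels, m$pixels)  # unanimity
  expect_equal(un$mask$provenance, "consensus")

  # a pixel marked by exactly one reviewer is background
  a <- binary_mask(matrix(FALSE, 4, 4)); a$pixels[2, 2] <- TRUE
  b <- binary_mask(matrix(FALSE, 4, 4))
  out <- consensus_mask(list(a, b, b), pixel_size = 1)
  expect_false(any(out$mask$pixels))

  for (i in 1:10) {
    trio <- purrr::map(1:3, ~ rand_mask())
    got <- consensus_mask(trio, pixel_size = 1)$mask$pixels
    votes <- trio[[1]]$pixels + trio[[2]]$pixels + trio[[3]]$pixels
    expect_identical(got, votes >= 2)
    # bounded by intersection and union of the inputs
    expect_true(all(got[trio[[1]]$pixels & trio[[2]]$pixels & trio[[3]]$pixels]))
    expect_false(any(got[votes == 0]))
  }
  expect_error(consensus_mask(list(m, m), 1), "exactly 3")
  expect_error(consensus_mask(list(m, m, rand_mask(8, 8)), 1), "dimensions")
})

test_that("consensus applies the same area filter as measurement to n_gt", {
  m <- matrix(FALSE, 30, 30)
  m[2:11, 2:11] <- TRUE      # 100 px
  m[20, 20] <- TRUE          # 1 px speck
  bm <- binary_mask(m)
  gt <- consensus_mask(list(bm, bm, bm), pixel_size = 1,
                       min_area = 10, max_area = 5000)
  expect_equal(gt$n_gt, 1)   # the speck is filtered out
  gt2 <- consensus_mask(list(bm, bm, bm), pixel_size = 1,
                        min_area = 0.5, max_area = 5000)
  expect_equal(gt2$n_gt, 2)
})

test_that("iou follows its definition and basic properties", {
  a <- matrix(FALSE, 10, 10); a[1:5, 1:5] <- TRUE
  expect_equal(iou(a, a), 1)
  b <- matrix(FALSE, 10, 10); b[6:10, 6:10] <- TRUE
  expect_equal(iou(a, b), 0)
  expect_error(iou(b & !b, b & !b), "empty")
  # |a| = |b| = 100, overlap 50 -> 1/3
  x <- seq_len(100); y <- 51:150
  expect_equal(iou(x, y), 1 / 3)
  set.seed(83)
  for (i in 1:20) {
    p <- matrix(runif(64) < 0.5, 8, 8); q <- matrix(runif(64) < 0.5, 8, 8)
    if (!any(p | q)) next
    v <- iou(p, q)
    expect_identical(v, iou(q, p))
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v == 1, identical(p, q))
  }
})

test_that("matching a prediction to itself is all true positives", {
  set.seed(87)
  lab <- draw_disks(48, 48, cbind(runif(5, 8, 40), runif(5, 8, 40)), rep(4, 5))
  lm <- label_components(binary_mask(lab > 0))
  res <- match_fibrils(lm, lm)
  expect_equal(res$tp, lm$n)
  expect_equal(res$fp, 0)
  expect_equal(res$pairs$iou, rep(1, lm$n))
})

test_that("a prediction overlapping nothing is a false positive", {
  pred <- matrix(0L, 20, 20); pred[2:4, 2:4] <- 1L
  gt <- matrix(0L, 20, 20); gt[10:14, 10:14] <- 1L
  res <- match_fibrils(labeled_mask(pred), labeled_mask(gt))
  expect_equal(res$tp, 0)
  expect_equal(res$fp, 1)
  expect_equal(nrow(res$pairs), 0)
})

test_that("tp + fp always equals the number of predictions", {
  set.seed(89)
  for (i in 1:10) {
    pred <- label_components(rand_mask(24, 24, 0.35))
    gt <- label_components(rand_mask(24, 24, 0.35))
    res <- match_fibrils(pred, gt)
    expect_equal(res$tp + res$fp, pred$n)
    expect_lte(nrow(res$pairs), min(pred$n, gt$n))
    expect_false(any(duplicated(res$pairs$pred_label)))
    expect_false(any(duplicated(res$pairs$gt_label)))
  }
})

test_that("raising the IoU threshold never increases TP", {
  set.seed(91)
  pred <- label_components(rand_mask(32, 32, 0.4))
  gt <- label_components(rand_mask(32, 32, 0.4))
  tps <- purrr::map_int(seq(0.05, 0.95, by = 0.1),
                        ~ match_fibrils(pred, gt, .x)$tp)
  expect_true(all(diff(tps) <= 0))
})

test_that("greedy matching equals exhaustive assignment on perturbed copies", {
  set.seed(93)
  for (i in 1:25) {
    n <- sample(2:4, 1)
    centers <- cbind(runif(n, 6, 26), runif(n, 6, 26))
    gt_lab <- draw_disks(32, 32, centers, runif(n, 2.5, 4))
    shift <- matrix(sample(-2:2, 2 * n, replace = TRUE), n, 2)
    pred_lab <- draw_disks(32, 32, centers + shift, runif(n, 2.5, 4))
    if (!all(seq_len(n) %in% gt_lab) || !all(seq_len(n) %in% pred_lab)) {
      next  # a disk got overdrawn
    }
    got <- match_fibrils(labeled_mask(pred_lab), labeled_mask(gt_lab))
    want <- exhaustive_match(pred_lab, gt_lab)
    expect_equal(got$tp, want$tp)
    expect_equal(got$fp, want$fp)
  }
})

test_that("precision, recall and F1 reproduce the worked examples", {
  expect_equal(round(precision(416, 6), 3), 0.986)
  expect_equal(round(precision(10661, 2327), 3), 0.821)
  expect_equal(precision(0, 5), 0)
  expect_equal(round(recall(679, 1174), 3), 0.578)
  expect_equal(round(recall(10661, 13860), 3), 0.769)
  expect_equal(recall(50, 50), 1)
  expect_equal(round(f1_score(0.821, 0.769), 3), 0.794)
  expect_equal(round(f1_score(precision(416, 6), recall(416, 475)), 3), 0.928)
  for (x in c(0.1, 0.5, 0.9)) expect_equal(f1_score(x, x), x)
  expect_error(precision(0, 0), "undefined")
  expect_error(recall(3, 0), "undefined")
  expect_error(f1_score(0, 0), "undefined")
})

test_that("F1 is symmetric and bounded by the geometric and arithmetic means", {
  set.seed(97)
  p <- runif(50, 0.01, 1); r <- runif(50, 0.01, 1)
  f <- purrr::map2_dbl(p, r, f1_score)
  expect_equal(f, purrr::map2_dbl(r, p, f1_score))
  expect_true(all(f <= sqrt(p * r) + 1e-12))
  expect_true(all(sqrt(p * r) <= (p + r) / 2 + 1e-12))
  expect_true(all(f >= pmin(p, r) - 1e-12 & f <= pmax(p, r) + 1e-12))
})

test_that("percent error matches its formula", {
  expect_equal(round(percent_error(1204, 1356), 2), 11.21)
  expect_equal(round(percent_error(798, 1174), 2), 32.03)
  expect_equal(percent_error(77, 77), 0)
  expect_error(percent_error(5, 0), "zero")
})

test_that("parity R2 uses identity-line residuals by default", {
  truth <- c(10, 20, 30, 40, 50)
  expect_equal(parity_r2(truth, truth), 1)
  set.seed(101)
  noisy <- truth + rnorm(5, 0, 8)
  want <- 1 - sum((noisy - truth)^2) / sum((noisy - mean(noisy))^2)
  expect_equal(parity_r2(noisy, truth), want)
  expect_lt(parity_r2(noisy, truth), 1)
  # least-squares mode is the squared correlation
  expect_equal(parity_r2(noisy, truth, method = "fit"), cor(noisy, truth)^2)
  expect_error(parity_r2(1:3, 1:4), "equal length")
  expect_error(parity_r2(c(2, 2, 2), 1:3), "constant")
  # pooled distribution-mode input is just a longer vector pair
  fr_a <- c(0.2, 0.5, 0.3); fr_b <- c(0.25, 0.45, 0.3)
  expect_silent(parity_r2(c(fr_a, fr_b), c(fr_b, fr_a)))
})

test_that("a perfect prediction scores P = R = F1 = 1 end to end", {
  sim <- simulate_micrograph(sim_config(n_fibrils = 12, seed = 19))
  tmask <- sim$truth$mask
  gt <- consensus_mask(list(tmask, tmask, tmask), pixel_size = 2)
  rep <- evaluate_segmentation(list(label_components(tmask)), list(gt),
                               pixel_size = 2)
  expect_equal(rep$combined$precision, 1)
  expect_equal(rep$combined$recall, 1)
  expect_equal(rep$combined$f1, 1)
  expect_equal(rep$per_image$percent_error_count, 0)
  expect_equal(rep$per_image$percent_error_diameter, 0)
})

test_that("the combined row pools counts rather than averaging metrics", {
  set.seed(103)
  sims <- purrr::map(1:2, ~ simulate_micrograph(
    sim_config(n_fibrils = 8 + 4 * .x, seed = 200 + .x)))
  gts <- purrr::map(sims, ~ consensus_mask(
    list(.x$truth$mask, .x$truth$mask, .x$truth$mask), pixel_size = 2))
  # degrade one prediction: drop a fibril from image 2
  pred1 <- label_components(sims[[1]]$truth$mask)
  lab2 <- sims[[2]]$truth$labels$labels
  lab2[lab2 == 1L] <- 0L
  lab2[lab2 > 0L] <- match(lab2[lab2 > 0L], sort(unique(lab2[lab2 > 0L])))
  pred2 <- labeled_mask(lab2)
  rep <- evaluate_segmentation(list(pred1, pred2), gts, pixel_size = 2)
  expect_equal(rep$combined$tp, sum(rep$per_image$tp))
  expect_equal(rep$combined$n_gt, sum(rep$per_image$n_gt))
  expect_equal(rep$combined$precision,
               precision(sum(rep$per_image$tp), sum(rep$per_image$fp)))
  expect_equal(rep$combined$recall, sum(rep$per_image$tp) / rep$combined$n_gt)
  # combined F1 comes from pooled P and R, not from per-image means
  expect_equal(rep$combined$f1,
               f1_score(rep$combined$precision, rep$combined$recall))
  g <- glance(rep)
  expect_named(g, c("n_gt", "n_pred", "tp", "fp", "precision", "recall",
                    "f1", "r2_size", "r2_count", "r2_distribution"))
  expect_s3_class(autoplot(rep), "ggplot")
  expect_equal(nrow(tidy(rep)), 3)
})
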