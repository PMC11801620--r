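#' Consensus ground truth from three reviewer masks
#'
#' Pixel-wise 2-of-3 majority vote over exactly three reviewer annotations
#' of the same image: a pixel is consensus fibril when at least two
#' reviewers marked it, which removes single-reviewer outlier strokes.
#' Instances are labeled from the consensus mask and filtered with the same
#' area rule as fibril measurement, so the ground-truth count `n_gt` is
#' commensurable with measured counts.
#'
#' @param masks list of exactly 3 shape-matched [binary_mask] objects.
#' @param pixel_size nm per pixel, used for the instance area filter.
#' @param min_area,max_area instance area bounds in nm^2 (defaults 10, 5000).
#' @param connectivity instance connectivity (default 8).
#' @return An object of class `consensus_gt`: consensus `mask`
#'   ([binary_mask], provenance `"consensus"`), area-filtered `instances`
#'   ([labeled_mask]), and `n_gt`.
#' @export
consensus_mask <- function(masks, pixel_size, min_area = 10, max_area = 5000,
                           connectivity = 8L) {
  if (length(masks) != 3) {
    stop("consensus requires exactly 3 reviewer masks", call. = FALSE)
  }
  px <- purrr::map(masks, "pixels")
  check_same_shape(px[[1]], px[[2]], "reviewer masks")
  check_same_shape(px[[1]], px[[3]], "reviewer masks")
  votes <- px[[1]] + px[[2]] + px[[3]]
  cons <- binary_mask(votes >= 2, provenance = "consensus",
                      image_id = masks[[1]]$image_id)
  inst <- filter_instances(label_components(cons, connectivity), pixel_size,
                           min_area, max_area)
  structure(list(image_id = cons$image_id, mask = cons, instances = inst,
                 n_gt = inst$n),
            class = "consensus_gt")
}

#' @export
print.consensus_gt <- function(x, ...) {
  cat(sprintf("<consensus_gt> %s: %d ground-truth fibrils\n",
              x$image_id, x$n_gt))
  invisible(x)
}

#' Drop instances outside an area range, relabeling survivors
#'
#' @param lm a [labeled_mask].
#' @param pixel_size nm per pixel.
#' @param min_area,max_area surviving area range in nm^2.
#' @return A [labeled_mask] whose surviving instances are renumbered 1..K
#'   in their original label order.
#' @export
filter_instances <- function(lm, pixel_size, min_area = 10, max_area = 5000) {
  stopifnot(inherits(lm, "labeled_mask"), pixel_size > 0)
  if (lm$n == 0L) return(lm)
  sizes <- tabulate(lm$labels[lm$labels > 0L], nbins = lm$n)
  areas <- sizes * pixel_size^2
  keep <- which(areas >= min_area & areas <= max_area)
  remap <- integer(lm$n)
  remap[keep] <- seq_along(keep)
  new_labels <- matrix(0L, nrow(lm$labels), ncol(lm$labels))
  pos <- lm$labels > 0L
  new_labels[pos] <- remap[lm$labels[pos]]
  labeled_mask(new_labels, image_id = lm$image_id)
}

#' Intersection over union of two pixel sets
#'
#' @param a,b logical matrices (shape-matched) or integer vectors of pixel
#'   indices.
#' @return `|a intersect b| / |a union b|`; both-empty input is an error.
#' @export
iou <- function(a, b) {
  if (is.matrix(a)) {
    check_same_shape(a, b, "masks")
    inter <- sum(a & b)
    uni <- sum(a | b)
  } else {
    inter <- length(intersect(a, b))
    uni <- length(union(a, b))
  }
  if (uni == 0) stop("IoU of two empty sets is undefined", call. = FALSE)
  inter / uni
}

#' Match predicted fibrils to ground truth by IoU
#'
#' Computes the IoU of every overlapping (predicted, ground-truth) instance
#' pair and assigns pairs greedily in descending IoU order, each predicted
#' and each ground-truth instance used at most once (ties broken by
#' predicted then ground-truth label, so matching is deterministic). A
#' predicted fibril whose assigned IoU meets `iou_threshold` is a true
#' positive; all other predictions -- below-threshold or unassigned -- are
#' false positives, so `tp + fp` equals the number of predictions. The
#' default threshold 0.33 is deliberately looser than the conventional 0.5:
#' ambiguous fibril rims can change an instance's area severalfold without
#' the detection being wrong.
#'
#' @param pred a [labeled_mask] of predicted instances (area-filter it
#'   first with [filter_instances] if comparing counts to a consensus).
#' @param gt a `consensus_gt` or a [labeled_mask] of ground-truth instances.
#' @param iou_threshold true-positive cut on IoU (default 0.33).
#' @return An object of class `match_result`: `pairs` tibble (`pred_label`,
#'   `gt_label`, `iou` of assigned pairs), `tp`, `fp`, `n_pred`, `n_gt`,
#'   `iou_threshold`.
#' @export
match_fibrils <- function(pred, gt, iou_threshold = 0.33) {
  gt_lm <- if (inherits(gt, "consensus_gt")) gt$instances else gt
  stopifnot(inherits(pred, "labeled_mask"), inherits(gt_lm, "labeled_mask"))
  check_same_shape(pred$labels, gt_lm$labels, "prediction and ground truth")
  np <- pred$n; ng <- gt_lm$n

  pairs <- tibble::tibble(pred_label = integer(), gt_label = integer(),
                          iou = numeric())
  if (np > 0L && ng > 0L) {
    size_p <- tabulate(pred$labels[pred$labels > 0L], nbins = np)
    size_g <- tabulate(gt_lm$labels[gt_lm$labels > 0L], nbins = ng)
    both <- pred$labels > 0L & gt_lm$labels > 0L
    if (any(both)) {
      p <- pred$labels[both]; g <- gt_lm$labels[both]
      key <- (as.numeric(g) - 1) * np + p
      cnt <- table(key)
      k <- as.numeric(names(cnt))
      pl <- as.integer((k - 1) %% np + 1)
      gl <- as.integer((k - 1) %/% np + 1)
      inter <- as.integer(cnt)
      cand <- tibble::tibble(
        pred_label = pl, gt_label = gl,
        iou = inter / (size_p[pl] + size_g[gl] - inter)
      ) |>
        dplyr::arrange(dplyr::desc(.data$iou), .data$pred_label, .data$gt_label)
      used_p <- logical(np); used_g <- logical(ng)
      take <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        pi <- cand$pred_label[i]; gi <- cand$gt_label[i]
        if (!used_p[pi] && !used_g[gi]) {
          take[i] <- TRUE
          used_p[pi] <- TRUE
          used_g[gi] <- TRUE
        }
      }
      pairs <- cand[take, ]
    }
  }
  tp <- sum(pairs$iou >= iou_threshold)
  structure(list(pairs = pairs, tp = tp, fp = np - tp, n_pred = np, n_gt = ng,
                 iou_threshold = iou_threshold),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d predictions vs %d GT: TP = %d, FP = %d (IoU >= %.2f)\n",
              x$n_pred, x$n_gt, x$tp, x$fp, x$iou_threshold))
  invisible(x)
}

#' Detection metrics
#'
#' `precision()` is TP / (TP + FP), the fraction of predicted fibrils that
#' are correct; `recall()` is TP / N_GT, the fraction of ground-truth
#' fibrils recovered; `f1_score()` is their harmonic mean
#' 2PR / (P + R).
#'
#' @param tp,fp true/false positive counts.
#' @param n_gt number of ground-truth fibrils.
#' @param p,r precision and recall.
#' @return A fraction in `[0, 1]`.
#' @examples
#' precision(416, 6)           # 0.986
#' recall(679, 1174)           # 0.578
#' f1_score(0.821, 0.769)      # 0.794
#' @export
precision <- function(tp, fp) {
  if (any(tp + fp < 1)) stop("precision undefined with no predictions", call. = FALSE)
  tp / (tp + fp)
}

#' @rdname precision
#' @export
recall <- function(tp, n_gt) {
  if (any(n_gt < 1)) stop("recall undefined with empty ground truth", call. = FALSE)
  tp / n_gt
}

#' @rdname precision
#' @export
f1_score <- function(p, r) {
  if (any(p + r <= 0)) stop("F1 undefined when precision + recall = 0", call. = FALSE)
  2 * p * r / (p + r)
}

#' Absolute percent error against a reference value
#'
#' @param measured measured value(s).
#' @param truth nonzero reference value(s).
#' @return `100 * |measured - truth| / truth`.
#' @examples
#' percent_error(1204, 1356)  # 11.21
#' @export
percent_error <- function(measured, truth) {
  if (any(truth == 0)) stop("percent error undefined for zero truth", call. = FALSE)
  100 * abs(measured - truth) / truth
}

#' Parity-plot coefficient of determination
#'
#' Agreement of measured values with ground truth judged against the
#' identity line y = x: `1 - sum((y - x)^2) / sum((y - mean(y))^2)`. This
#' is the R^2 of a parity plot whose reference line is truth itself (the
#' default); `method = "fit"` instead reports the squared Pearson
#' correlation, the R^2 of a fitted least-squares line.
#'
#' @param measured,truth equal-length numeric vectors, n >= 2.
#' @param method `"identity"` (default) or `"fit"`.
#' @return Dimensionless R^2 (can be negative for `"identity"` when
#'   disagreement exceeds the measured spread).
#' @export
parity_r2 <- function(measured, truth, method = c("identity", "fit")) {
  method <- match.arg(method)
  if (length(measured) != length(truth)) {
    stop("`measured` and `truth` must have equal length", call. = FALSE)
  }
  if (length(measured) < 2) stop("need at least 2 points", call. = FALSE)
  if (sd(measured) == 0) stop("`measured` is constant", call. = FALSE)
  if (method == "identity") {
    1 - sum((measured - truth)^2) / sum((measured - mean(measured))^2)
  } else {
    stats::cor(measured, truth)^2
  }
}

#' Full detection and morphometry evaluation report
#'
#' For each image: IoU-matches area-filtered predicted instances against
#' the consensus ground truth, then reports instance counts, TP/FP,
#' precision, recall, F1, and percent errors of fibril count and mean
#' diameter. A pooled `combined` row sums TP, FP and N_GT across images
#' (pooling counts, not averaging per-image metrics). With two or more
#' images, parity R^2 values are computed for mean fibril size and fibril
#' count (one point per image) and for the size distribution (one point
#' per 10-nm histogram bin per image, as in-range fractions).
#'
#' @param preds list of predicted [labeled_mask] (unfiltered; the area
#'   filter is applied here) or [binary_mask] objects.
#' @param gts list of `consensus_gt` objects, paired 1:1 with `preds`.
#' @param pixel_size nm per pixel.
#' @param iou_threshold IoU cut for true positives (default 0.33).
#' @param min_area,max_area area filter in nm^2 (defaults 10, 5000).
#' @return An object of class `eval_report`: `per_image` tibble, `combined`
#'   one-row tibble, `r2` one-row tibble (`r2_size`, `r2_count`,
#'   `r2_distribution`), and the settings used.
#' @export
evaluate_segmentation <- function(preds, gts, pixel_size,
                                  iou_threshold = 0.33,
                                  min_area = 10, max_area = 5000) {
  stopifnot(length(preds) == length(gts), length(preds) >= 1)
  rows <- purrr::map2(preds, gts, function(pr, gt, ...) {
    stopifnot(inherits(gt, "consensus_gt"))
    if (inherits(pr, "binary_mask")) pr <- label_components(pr)
    pr <- filter_instances(pr, pixel_size, min_area, max_area)
    mres <- match_fibrils(pr, gt, iou_threshold)
    meas_p <- measure_fibrils(pr, pixel_size, min_area, max_area)
    meas_g <- measure_fibrils(gt$instances, pixel_size, min_area, max_area)
    p <- precision(mres$tp, mres$fp)
    r <- recall(mres$tp, gt$n_gt)
    dp <- mean(meas_p$diameter_nm)
    dg <- mean(meas_g$diameter_nm)
    tibble::tibble(
      image_id = gt$image_id,
      n_gt = gt$n_gt, n_pred = pr$n, tp = mres$tp, fp = mres$fp,
      precision = p, recall = r, f1 = f1_score(p, r),
      mean_diameter_pred = dp, mean_diameter_gt = dg,
      percent_error_count = percent_error(pr$n, gt$n_gt),
      percent_error_diameter = percent_error(dp, dg),
      frac_pred = list(summarize_fibrils(meas_p)$histogram$fraction),
      frac_gt = list(summarize_fibrils(meas_g)$histogram$fraction)
    )
  })
  per_image <- dplyr::bind_rows(rows)

  tp <- sum(per_image$tp); fp <- sum(per_image$fp); ngt <- sum(per_image$n_gt)
  p <- precision(tp, fp); r <- recall(tp, ngt)
  combined <- tibble::tibble(
    image_id = "combined", n_gt = ngt, n_pred = sum(per_image$n_pred),
    tp = tp, fp = fp, precision = p, recall = r, f1 = f1_score(p, r),
    percent_error_count = percent_error(sum(per_image$n_pred), ngt)
  )

  r2 <- tibble::tibble(r2_size = NA_real_, r2_count = NA_real_,
                       r2_distribution = NA_real_)
  if (nrow(per_image) >= 2) {
    r2$r2_size <- parity_r2(per_image$mean_diameter_pred,
                            per_image$mean_diameter_gt)
    r2$r2_count <- parity_r2(per_image$n_pred, per_image$n_gt)
    r2$r2_distribution <- parity_r2(100 * unlist(per_image$frac_pred),
                                    100 * unlist(per_image$frac_gt))
  }
  per_image$frac_pred <- NULL
  per_image$frac_gt <- NULL

  structure(list(per_image = per_image, combined = combined, r2 = r2,
                 settings = list(pixel_size = pixel_size,
                                 iou_threshold = iou_threshold,
                                 min_area = min_area, max_area = max_area)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(dplyr::bind_rows(x$per_image, x$combined))
  cat(sprintf("parity R2: size %.3f, count %.3f, distribution %.3f\n",
              x$r2$r2_size, x$r2$r2_count, x$r2$r2_distribution))
  invisible(x)
}

#' @describeIn evaluate_segmentation per-image rows plus the pooled
#'   combined row as one tibble.
#' @param x an `eval_report`.
#' @param ... unused.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  dplyr::bind_rows(x$per_image, x$combined)
}

#' @describeIn evaluate_segmentation one-row tibble: pooled counts, pooled
#'   metrics, parity R^2 values.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  dplyr::bind_cols(x$combined[, c("n_gt", "n_pred", "tp", "fp",
                                  "precision", "recall", "f1")], x$r2)
}

#' @describeIn evaluate_segmentation per-image fibril-count parity plot
#'   against the identity (ground-truth) line.
#' @param object an `eval_report`.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  pi <- object$per_image
  lim <- range(c(pi$n_gt, pi$n_pred), 0)
  ggplot2::ggplot(pi, ggplot2::aes(x = .data$n_gt, y = .data$n_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_fixed(xlim = lim, ylim = lim) +
    ggplot2::labs(x = "ground-truth fibril count", y = "predicted fibril count",
                  title = sprintf("count parity, R² = %.3f",
                                  object$r2$r2_count)) +
    ggplot2::theme_minimal()
}
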