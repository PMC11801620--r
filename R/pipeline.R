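#' Pipeline run configuration
#'
#' One structured object holding every tunable of the workflow, with the
#' canonical defaults: 8 trees, 80/20 pixel split, Canny thresholds
#' 100/200, Gaussian feature sigmas 1 and 3, a 3x3 median window, 7x7
#' post-classification blur thresholded at 100, the 10-5000 nm^2 area
#' filter, 14 diameter bins of 10 nm over 10-150 nm, and the 0.33 IoU
#' matching cut. `pixel_size` has no default: the nm-per-pixel calibration
#' must come from the instrument metadata.
#'
#' @param pixel_size nm per pixel; required before running any stage.
#' @param features a [feature_config].
#' @param n_trees,holdout_fraction,seed classifier training parameters.
#' @param mask_selection_seed seed for the random choice of one reviewer
#'   mask per training image when several are supplied.
#' @param blur_kernel,blur_sigma,threshold post-processing parameters.
#' @param postprocess_input `"class"` or `"prob"`; see
#'   [smooth_and_threshold].
#' @param min_area,max_area instance area filter in nm^2.
#' @param exclude_border drop border-touching fibrils when measuring.
#' @param iou_threshold evaluation matching cut.
#' @return A named list of class `fibril_config`.
#' @export
fibril_config <- function(pixel_size = NULL, features = feature_config(),
                        n_trees = 8L, holdout_fraction = 0.2, seed = 1L,
                        mask_selection_seed = 1L, blur_kernel = 7L,
                        blur_sigma = 1.1, threshold = 100,
                        postprocess_input = "class", min_area = 10,
                        max_area = 5000, exclude_border = FALSE,
                        iou_threshold = 0.33) {
  structure(as.list(environment()), class = "fibril_config")
}

require_pixel_size <- function(config) {
  if (is.null(config$pixel_size)) {
    stop("config$pixel_size is not set; supply the nm/px calibration",
         call. = FALSE)
  }
  config$pixel_size
}

#' Read / write a run configuration as YAML
#'
#' @param config a [fibril_config].
#' @param path YAML file path.
#' @return `write_fibril_config` returns `path` invisibly; `read_fibril_config`
#'   returns a [fibril_config].
#' @export
write_fibril_config <- function(config, path) {
  stopifnot(inherits(config, "fibril_config"))
  lst <- unclass(config)
  lst$features <- unclass(lst$features)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_fibril_config
#' @export
read_fibril_config <- function(path) {
  lst <- yaml::read_yaml(path)
  feats <- do.call(feature_config, lst$features %||% list())
  lst$features <- NULL
  do.call(fibril_config, c(lst, list(features = feats)))
}

# pick one reviewer mask per image when several are given (seeded), as the
# training protocol prescribes; single masks pass through
select_training_masks <- function(masks, seed) {
  withr::with_seed(seed, {
    purrr::map(masks, function(m) {
      if (inherits(m, "binary_mask")) return(m)
      m[[sample.int(length(m), 1)]]
    })
  })
}

#' Train a fibril classifier from annotated micrographs
#'
#' End-to-end training stage: when several reviewer masks are supplied per
#' image, one is chosen at random (seeded) per image; features are
#' extracted with the configured filter bank and the random forest is
#' fitted on a seeded 80/20 pixel split.
#'
#' @param images list of [micrograph] objects.
#' @param masks list parallel to `images`; each element a [binary_mask] or
#'   a list of reviewer [binary_mask]s to choose from.
#' @param config a [fibril_config].
#' @return A `fibril_classifier`.
#' @export
fibril_train <- function(images, masks, config = fibril_config()) {
  stopifnot(length(images) == length(masks), length(images) >= 1)
  chosen <- select_training_masks(masks, config$mask_selection_seed)
  stacks <- purrr::map(images, extract_features, cfg = config$features)
  train_classifier(stacks, chosen, n_trees = config$n_trees,
                   holdout_fraction = config$holdout_fraction,
                   seed = config$seed, cfg = config$features)
}

#' Segment micrographs with a trained classifier
#'
#' Extracts features, classifies every pixel, and cleans the raw class map
#' with the configured blur + threshold.
#'
#' @param clf a `fibril_classifier`.
#' @param images list of [micrograph] objects.
#' @param config a [fibril_config].
#' @return A list of [binary_mask] segmentations, one per image.
#' @export
fibril_segment <- function(clf, images, config = fibril_config()) {
  if (inherits(images, "micrograph")) images <- list(images)
  purrr::map(images, function(m) {
    cm <- predict_classmap(clf, extract_features(m, cfg = clf$feature_config))
    smooth_and_threshold(cm, kernel_size = config$blur_kernel,
                         sigma = config$blur_sigma,
                         threshold = config$threshold,
                         input = config$postprocess_input)
  })
}

#' Quantify fibrils in segmentation masks
#'
#' Labels instances, applies the area filter, fits equal-area ellipses and
#' summarizes diameters per image.
#'
#' @param masks list of [binary_mask] (or [labeled_mask]) segmentations.
#' @param config a [fibril_config] with `pixel_size` set.
#' @return A list with `fibrils` (per-fibril tibble across images) and
#'   `summary` (per-image tibble: count, mean and sd diameter, and the 14
#'   bin counts as `bin_10_20` ... `bin_140_150`).
#' @export
fibril_quantify <- function(masks, config = fibril_config()) {
  ps <- require_pixel_size(config)
  if (inherits(masks, "binary_mask") || inherits(masks, "labeled_mask")) {
    masks <- list(masks)
  }
  per_image <- purrr::map(masks, function(mk) {
    lm <- if (inherits(mk, "labeled_mask")) mk else label_components(mk)
    measure_fibrils(lm, ps, min_area = config$min_area,
                    max_area = config$max_area,
                    exclude_border = config$exclude_border)
  })
  fibrils <- dplyr::bind_rows(per_image)
  summary <- purrr::map_dfr(per_image, function(f) {
    s <- summarize_fibrils(f)
    bins <- setNames(as.list(s$histogram$count),
                     sprintf("bin_%d_%d", s$histogram$bin_lo, s$histogram$bin_hi))
    tibble::tibble(image_id = if (nrow(f)) f$image_id[1] else NA_character_,
                   n_fibrils = s$n_fibrils,
                   mean_diameter_nm = s$mean_diameter,
                   sd_diameter_nm = s$sd_diameter, !!!bins)
  })
  list(fibrils = fibrils, summary = summary)
}

#' Evaluate segmentations against reviewer consensus ground truth
#'
#' Builds the 2-of-3 consensus for each image from its reviewer masks and
#' runs the full IoU-matched evaluation.
#'
#' @param pred_masks list of predicted [binary_mask] segmentations.
#' @param reviewer_masks list parallel to `pred_masks`; each element a list
#'   of exactly 3 reviewer [binary_mask]s.
#' @param config a [fibril_config] with `pixel_size` set.
#' @return An `eval_report`; see [evaluate_segmentation].
#' @export
fibril_evaluate <- function(pred_masks, reviewer_masks, config = fibril_config()) {
  ps <- require_pixel_size(config)
  stopifnot(length(pred_masks) == length(reviewer_masks))
  gts <- purrr::map(reviewer_masks, consensus_mask, pixel_size = ps,
                    min_area = config$min_area, max_area = config$max_area)
  evaluate_segmentation(pred_masks, gts, pixel_size = ps,
                        iou_threshold = config$iou_threshold,
                        min_area = config$min_area,
                        max_area = config$max_area)
}
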