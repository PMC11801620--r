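#' Train the random-forest pixel classifier
#'
#' Pools per-pixel feature rows from the training images, splits them
#' randomly into a training portion and a holdout portion (80/20 by
#' default; the split is over pixels pooled across images, not over
#' images), and fits a random forest with `n_trees` trees (default 8) to
#' predict fibril vs background. Holdout pixel accuracy is recorded in the
#' model metadata. Tree construction beyond `n_trees` uses the ranger
#' defaults (unlimited depth, sqrt(p) candidate features per split,
#' bootstrap resampling), frozen into the metadata. All randomness is
#' governed by `seed`.
#'
#' @param stacks list of [extract_features] stacks of the training images.
#' @param masks list of [binary_mask] annotations, paired 1:1 with `stacks`.
#' @param n_trees number of decision trees (default 8).
#' @param holdout_fraction fraction of pixels withheld for the accuracy
#'   estimate (default 0.2).
#' @param seed integer seed controlling the pixel split and forest fitting.
#' @param cfg the [feature_config] the stacks were built with; persisted so
#'   prediction always reuses the training schema.
#' @return An object of class `fibril_classifier`.
#' @export
train_classifier <- function(stacks, masks, n_trees = 8L,
                             holdout_fraction = 0.2, seed = 1L,
                             cfg = feature_config()) {
  if (inherits(stacks, "feature_stack")) stacks <- list(stacks)
  if (inherits(masks, "binary_mask")) masks <- list(masks)
  stopifnot(length(stacks) >= 1, n_trees >= 1,
            holdout_fraction >= 0, holdout_fraction < 1)
  tab <- stack_to_table(stacks, masks)
  if (dplyr::n_distinct(tab$label) < 2) {
    stop("training masks must contain both fibril and background pixels",
         call. = FALSE)
  }
  schema <- stacks[[1]]$channel_names
  n <- nrow(tab)
  idx_holdout <- withr::with_seed(seed,
    sample.int(n, size = floor(holdout_fraction * n)))
  train_tab <- if (length(idx_holdout)) tab[-idx_holdout, ] else tab
  hold_tab <- tab[idx_holdout, ]

  forest <- ranger::ranger(
    dependent.variable.name = "label",
    data = train_tab[, c(schema, "label")],
    num.trees = n_trees,
    importance = "impurity",
    seed = seed,
    num.threads = 1
  )

  holdout_accuracy <- NA_real_
  if (nrow(hold_tab)) {
    pred <- predict_votes(forest, hold_tab[, schema, drop = FALSE], schema)
    holdout_accuracy <- mean((pred >= 0.5) == (hold_tab$label == "fibril"))
  }

  structure(list(
    forest = forest,
    feature_schema = schema,
    n_trees = as.integer(n_trees),
    feature_config = cfg,
    metadata = list(
      image_ids = purrr::map_chr(stacks, "image_id"),
      seed = as.integer(seed),
      holdout_fraction = holdout_fraction,
      holdout_accuracy = holdout_accuracy,
      n_pixels = n,
      class_counts = table(tab$label),
      ranger_defaults = list(mtry = forest$mtry,
                             min_node_size = forest$min.node.size,
                             replace = TRUE),
      format = "fibrilseg-classifier-1"
    )
  ), class = "fibril_classifier")
}

# fraction of trees voting fibril, per row of a feature data frame
predict_votes <- function(forest, newdata, schema) {
  votes <- predict(forest, data = newdata[, schema, drop = FALSE],
                   predict.all = TRUE, num.threads = 1)$predictions
  fibril_idx <- match("fibril", forest$forest$levels)
  rowMeans(votes == fibril_idx)
}

#' @export
print.fibril_classifier <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(paste0("<fibril_classifier> %d trees on %d channels; trained on %s",
                     " (%d px), holdout accuracy %.3f\n"),
              x$n_trees, length(x$feature_schema),
              paste(md$image_ids, collapse = ", "), md$n_pixels,
              md$holdout_accuracy))
  invisible(x)
}

#' @describeIn train_classifier per-channel impurity importance as a tibble.
#' @param x a `fibril_classifier`.
#' @param ... unused.
#' @method tidy fibril_classifier
#' @export
tidy.fibril_classifier <- function(x, ...) {
  imp <- x$forest$variable.importance
  tibble::tibble(channel = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @describeIn train_classifier one-row model summary (trees, pixels,
#'   holdout accuracy).
#' @method glance fibril_classifier
#' @export
glance.fibril_classifier <- function(x, ...) {
  md <- x$metadata
  tibble::tibble(
    n_trees = x$n_trees,
    n_channels = length(x$feature_schema),
    n_images = length(md$image_ids),
    n_pixels = md$n_pixels,
    holdout_fraction = md$holdout_fraction,
    holdout_accuracy = md$holdout_accuracy,
    seed = md$seed
  )
}

#' Classify every pixel of a feature stack
#'
#' Deterministic given a fitted classifier: the fibril probability of a
#' pixel is the fraction of trees voting fibril, and the hard class is
#' probability >= 0.5 (an exact 4-4 tie of the default 8 trees counts as
#' fibril; the rule is fixed so repeated predictions are identical).
#'
#' @param clf a `fibril_classifier` from [train_classifier].
#' @param stack a `feature_stack` with the classifier's channel schema.
#' @return An object of class `class_map`: `image_id`, logical matrix
#'   `fibril`, numeric matrix `prob` in `[0, 1]`.
#' @export
predict_classmap <- function(clf, stack) {
  stopifnot(inherits(clf, "fibril_classifier"), inherits(stack, "feature_stack"))
  if (!identical(stack$channel_names, clf$feature_schema)) {
    stop("feature schema mismatch between classifier and stack", call. = FALSE)
  }
  nr <- nrow(stack$channels[[1]]); nc <- ncol(stack$channels[[1]])
  tab <- stack_to_table(stack)
  prob <- predict_votes(clf$forest, tab, clf$feature_schema)
  prob_m <- matrix(prob, nr, nc, byrow = TRUE)
  structure(list(image_id = stack$image_id,
                 fibril = prob_m >= 0.5,
                 prob = prob_m),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  cat(sprintf("<class_map> %s: %d x %d px, %.1f%% fibril\n",
              x$image_id, nrow(x$fibril), ncol(x$fibril),
              100 * mean(x$fibril)))
  invisible(x)
}

#' Persist / reload a fitted classifier
#'
#' The artifact bundles the forest state, the ordered feature schema, the
#' filter-bank configuration and the training metadata under a version tag,
#' so a reloaded model predicts identically and cannot silently be applied
#' to a mismatched feature stack.
#'
#' @param clf a `fibril_classifier`.
#' @param path file path for the model artifact (RDS).
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   returns the classifier.
#' @export
save_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "fibril_classifier"))
  saveRDS(clf, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  clf <- readRDS(path)
  if (!inherits(clf, "fibril_classifier") ||
      !identical(clf$metadata$format, "fibrilseg-classifier-1")) {
    stop("not a fibrilseg classifier artifact: ", path, call. = FALSE)
  }
  clf
}
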