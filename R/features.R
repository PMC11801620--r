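#' Filter-bank configuration
#'
#' Parameters of the per-pixel feature extraction. The channel list is
#' closed and ordered: raw intensity, Canny edge map, Roberts, Sobel,
#' Scharr and Prewitt gradient magnitudes, Gaussian smoothing at each
#' `gaussian_sigmas` value, and a square median filter. The same
#' configuration object must be used for training and prediction; it is
#' stored inside every fitted classifier for that reason.
#'
#' @param canny_low,canny_high Canny hysteresis thresholds on the 0-255
#'   Sobel magnitude scale (defaults 100 / 200).
#' @param canny_scale value coded for Canny edge pixels; 255 keeps the
#'   channel on the common 0-255 scale (set 1 for a 0/1 coding).
#' @param gaussian_sigmas Gaussian smoothing sigmas in pixels, one channel
#'   each (defaults 1 and 3).
#' @param median_size side of the square median window in pixels; the
#'   default 3 gives the classic 3x3 median.
#' @return A named list of class `feature_config`.
#' @export
feature_config <- function(canny_low = 100, canny_high = 200,
                           canny_scale = 255, gaussian_sigmas = c(1, 3),
                           median_size = 3L) {
  stopifnot(canny_low > 0, canny_high >= canny_low,
            all(gaussian_sigmas > 0), median_size == 3L)
  structure(list(canny_low = canny_low, canny_high = canny_high,
                 canny_scale = canny_scale,
                 gaussian_sigmas = as.numeric(gaussian_sigmas),
                 median_size = as.integer(median_size)),
            class = "feature_config")
}

feature_channel_names <- function(cfg) {
  c("raw", "canny", "roberts", "sobel", "scharr", "prewitt",
    paste0("gaussian_s", format(cfg$gaussian_sigmas, trim = TRUE)),
    paste0("median", cfg$median_size))
}

#' Extract the per-pixel feature stack of a micrograph
#'
#' Applies the closed filter bank to a micrograph and returns one response
#' grid per channel, all shape-matched to the input and in a fixed order so
#' training and prediction see identical feature schemas. Edge filters are
#' gradient magnitudes (hence non-negative); convolution borders use
#' reflect padding.
#'
#' @param m a [micrograph].
#' @param cfg a [feature_config].
#' @return An object of class `feature_stack`: `image_id`, named list
#'   `channels`, and `channel_names` in channel order.
#' @examples
#' m <- micrograph(matrix(100, 16, 16), pixel_size = 1)
#' fs <- extract_features(m)
#' fs$channel_names
#' max(abs(fs$channels$sobel))  # constant image: no gradient
#' @export
extract_features <- function(m, cfg = feature_config()) {
  stopifnot(inherits(m, "micrograph"), inherits(cfg, "feature_config"))
  x <- m$pixels
  channels <- list(
    raw = x,
    canny = canny_edges(x, cfg$canny_low, cfg$canny_high) / 255 * cfg$canny_scale,
    roberts = roberts_magnitude(x),
    sobel = gradient_magnitude(x, kern$sobel_x),
    scharr = gradient_magnitude(x, kern$scharr_x),
    prewitt = gradient_magnitude(x, kern$prewitt_x)
  )
  for (s in cfg$gaussian_sigmas) {
    channels[[paste0("gaussian_s", format(s, trim = TRUE))]] <-
      gaussian_smooth(x, s)
  }
  channels[[paste0("median", cfg$median_size)]] <- median_filter3(x)
  nms <- feature_channel_names(cfg)
  stopifnot(identical(names(channels), nms))
  structure(list(image_id = m$image_id, channels = channels,
                 channel_names = nms),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> %s: %d x %d px, %d channels (%s)\n",
              x$image_id, nrow(x$channels[[1]]), ncol(x$channels[[1]]),
              length(x$channels), paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' Flatten feature stacks into a per-pixel table
#'
#' One row per pixel, one column per channel, rows ordered deterministically
#' by image, then row-major pixel scan (row by row, left to right). When the
#' paired class masks are supplied a `label` factor column
#' (background/fibril) is appended -- the shape the classifier trains on.
#'
#' @param stacks a `feature_stack` or list of them.
#' @param masks optional [binary_mask] (or list), paired 1:1 with `stacks`.
#' @return A [tibble::tibble] with columns `image_id`, `row`, `col`, one
#'   numeric column per channel, and `label` when masks are given.
#' @export
stack_to_table <- function(stacks, masks = NULL) {
  if (inherits(stacks, "feature_stack")) stacks <- list(stacks)
  if (inherits(masks, "binary_mask")) masks <- list(masks)
  if (!is.null(masks) && length(masks) != length(stacks)) {
    stop("`masks` must pair 1:1 with `stacks`", call. = FALSE)
  }
  schema <- stacks[[1]]$channel_names
  parts <- purrr::map2(stacks, seq_along(stacks), function(fs, i) {
    stopifnot(identical(fs$channel_names, schema))
    nr <- nrow(fs$channels[[1]]); nc <- ncol(fs$channels[[1]])
    # row-major scan: transpose so fast index runs along columns
    tab <- purrr::map(fs$channels, ~ as.vector(t(.x)))
    out <- tibble::tibble(
      image_id = fs$image_id,
      row = rep(seq_len(nr), each = nc),
      col = rep(seq_len(nc), times = nr),
      !!!tab
    )
    if (!is.null(masks)) {
      mk <- masks[[i]]
      check_same_shape(fs$channels[[1]], mk$pixels, "feature stack and mask")
      out$label <- factor(ifelse(as.vector(t(mk$pixels)), "fibril", "background"),
                          levels = c("background", "fibril"))
    }
    out
  })
  dplyr::bind_rows(parts)
}
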