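#' Moment-based equal-area ellipse of a pixel region
#'
#' Fits the ImageJ-style ellipse to one connected region: the ellipse
#' shares the region's centroid and the orientation of its second central
#' moments, its axis ratio comes from the moment eigenvalues (with the 1/12
#' per-pixel variance of a unit square added, as ImageJ does), and both
#' axes are rescaled so the ellipse area pi * major * minor / 4 equals the
#' region's pixel area exactly. Degenerate regions -- a single pixel, or
#' collinear pixels with no second transverse moment -- return the
#' equal-area circle.
#'
#' @param rows,cols integer pixel coordinates of one region.
#' @param pixel_size nm per pixel; axis lengths are returned in nm.
#' @return list with `major`, `minor` (full axis lengths, nm; minor <=
#'   major), `orientation` (radians, major axis vs the column axis), and
#'   `centroid_row`, `centroid_col` (pixel units).
#' @examples
#' # a single pixel at 2 nm/px: forced to the equal-area circle
#' fit_region_ellipse(5, 5, pixel_size = 2)$major == 2 * sqrt(4 / pi)
#' @export
fit_region_ellipse <- function(rows, cols, pixel_size = 1) {
  n <- length(rows)
  stopifnot(n >= 1, length(cols) == n, pixel_size > 0)
  cr <- mean(rows); cc <- mean(cols)
  dr <- rows - cr; dc <- cols - cc

  circle <- function() {
    d <- 2 * sqrt(n / pi) * pixel_size
    list(major = d, minor = d, orientation = 0,
         centroid_row = cr, centroid_col = cc)
  }
  if (n < 3) return(circle())

  m20r <- mean(dc^2); m02r <- mean(dr^2); m11 <- mean(dc * dr)
  common_r <- sqrt((m20r - m02r)^2 + 4 * m11^2)
  lambda2_raw <- (m20r + m02r - common_r) / 2
  if (lambda2_raw <= 1e-10) return(circle())

  # ImageJ adds the 1/12 within-pixel variance before extracting axes
  m20 <- m20r + 1 / 12; m02 <- m02r + 1 / 12
  common <- sqrt((m20 - m02)^2 + 4 * m11^2)
  l1 <- (m20 + m02 + common) / 2
  l2 <- (m20 + m02 - common) / 2
  a0 <- 2 * sqrt(l1)  # semi-axes of the uniform ellipse with these moments
  b0 <- 2 * sqrt(l2)
  s <- sqrt(n / (pi * a0 * b0))  # rescale so pi*a*b = pixel area
  theta <- 0.5 * atan2(2 * m11, m20 - m02)
  list(major = 2 * a0 * s * pixel_size,
       minor = 2 * b0 * s * pixel_size,
       orientation = theta,
       centroid_row = cr, centroid_col = cc)
}

#' Measure fibril instances with area filtering
#'
#' Converts a labeled mask into one measurement row per surviving fibril:
#' pixel count, calibrated area, centroid, fitted equal-area ellipse, and
#' diameter taken as the ellipse minor axis (robust to fibrils sectioned
#' obliquely, which elongate the major axis only). Instances whose area
#' falls below `min_area` or above `max_area` (defaults 10 and 5000 nm^2)
#' are discarded as background specks and merged clumps. Instances touching
#' the image border are kept by default.
#'
#' @param lm a [labeled_mask].
#' @param pixel_size nm per pixel (> 0).
#' @param min_area,max_area surviving area range in nm^2.
#' @param exclude_border drop instances touching the image edge
#'   (default `FALSE`).
#' @return A tibble, one row per surviving fibril: `image_id`, `label`,
#'   `pixel_count`, `area_nm2`, `centroid_row`, `centroid_col`, `major_nm`,
#'   `minor_nm`, `orientation`, `diameter_nm`.
#' @export
measure_fibrils <- function(lm, pixel_size, min_area = 10, max_area = 5000,
                            exclude_border = FALSE) {
  stopifnot(inherits(lm, "labeled_mask"))
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be positive", call. = FALSE)
  }
  empty <- tibble::tibble(
    image_id = character(), label = integer(), pixel_count = integer(),
    area_nm2 = numeric(), centroid_row = numeric(), centroid_col = numeric(),
    major_nm = numeric(), minor_nm = numeric(), orientation = numeric(),
    diameter_nm = numeric()
  )
  if (lm$n == 0L) return(empty)
  nr <- nrow(lm$labels); nc <- ncol(lm$labels)
  w <- which(lm$labels > 0L)
  lab <- lm$labels[w]
  ri <- ((w - 1L) %% nr) + 1L
  ci <- ((w - 1L) %/% nr) + 1L
  by_lab <- split(seq_along(w), lab)

  rows <- purrr::imap(by_lab, function(idx, lb) {
    r <- ri[idx]; cl <- ci[idx]
    npx <- length(idx)
    area <- npx * pixel_size^2
    if (area < min_area || area > max_area) return(NULL)
    if (exclude_border && (any(r == 1L | r == nr | cl == 1L | cl == nc))) {
      return(NULL)
    }
    e <- fit_region_ellipse(r, cl, pixel_size = pixel_size)
    tibble::tibble(
      image_id = lm$image_id, label = as.integer(lb), pixel_count = npx,
      area_nm2 = area, centroid_row = e$centroid_row,
      centroid_col = e$centroid_col, major_nm = e$major, minor_nm = e$minor,
      orientation = e$orientation, diameter_nm = e$minor
    )
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (!nrow(out)) return(empty)
  dplyr::arrange(out, .data$label)
}

diameter_bins <- function() {
  tibble::tibble(bin_lo = seq(10, 140, by = 10), bin_hi = seq(20, 150, by = 10))
}

# bin index 1..14 for diameters in [10, 150]; NA outside. Bins are
# left-closed right-open except the last, [140, 150], which is closed.
diameter_bin_index <- function(d) {
  idx <- ifelse(d < 10 | d > 150, NA_integer_,
                pmin(floor((d - 10) / 10) + 1, 14L))
  as.integer(idx)
}

#' Summary statistics of a fibril population
#'
#' Count, mean and standard deviation of the fibril diameters, and the
#' fixed 14-bin size histogram: bins of width 10 nm spanning 10-150 nm,
#' left-closed right-open with the final bin [140, 150] closed. Diameters
#' outside 10-150 nm stay in the count and the mean (the area filter, not
#' the histogram, is the exclusion rule) but fall outside the histogram;
#' fractions are normalized by the in-range total.
#'
#' @param fibrils a measurement tibble from [measure_fibrils] (or any data
#'   frame with a `diameter_nm` column).
#' @return An object of class `fibril_stats`: `n_fibrils`, `mean_diameter`,
#'   `sd_diameter`, and a 14-row `histogram` tibble (`bin_lo`, `bin_hi`,
#'   `count`, `fraction`).
#' @examples
#' s <- summarize_fibrils(tibble::tibble(diameter_nm = c(15, 15, 25)))
#' s$histogram$count[1:2]  # 2 in [10,20), 1 in [20,30)
#' @export
summarize_fibrils <- function(fibrils) {
  d <- fibrils$diameter_nm
  bins <- diameter_bins()
  idx <- diameter_bin_index(d)
  counts <- tabulate(idx[!is.na(idx)], nbins = 14L)
  total <- sum(counts)
  bins$count <- counts
  bins$fraction <- if (total > 0) counts / total else rep(0, 14L)
  structure(list(
    n_fibrils = length(d),
    mean_diameter = if (length(d)) mean(d) else NA_real_,
    sd_diameter = if (length(d) > 1) sd(d) else NA_real_,
    histogram = bins
  ), class = "fibril_stats")
}

#' @export
print.fibril_stats <- function(x, ...) {
  cat(sprintf("<fibril_stats> n = %d, diameter %.1f +/- %.1f nm\n",
              x$n_fibrils, x$mean_diameter, x$sd_diameter))
  invisible(x)
}

#' @describeIn summarize_fibrils the 14-bin histogram as a tibble.
#' @param x a `fibril_stats` object.
#' @param ... unused.
#' @method tidy fibril_stats
#' @export
tidy.fibril_stats <- function(x, ...) x$histogram

#' @describeIn summarize_fibrils one-row summary tibble.
#' @method glance fibril_stats
#' @export
glance.fibril_stats <- function(x, ...) {
  tibble::tibble(n_fibrils = x$n_fibrils, mean_diameter = x$mean_diameter,
                 sd_diameter = x$sd_diameter,
                 n_in_histogram = sum(x$histogram$count))
}

#' @describeIn summarize_fibrils diameter-distribution bar chart.
#' @param object a `fibril_stats` object.
#' @method autoplot fibril_stats
#' @export
autoplot.fibril_stats <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                  y = .data$fraction)) +
    ggplot2::geom_col(width = 9, fill = "grey30") +
    ggplot2::scale_x_continuous(breaks = seq(10, 150, 20)) +
    ggplot2::labs(x = "fibril diameter (nm)", y = "fraction of fibrils",
                  title = sprintf("n = %d, mean %.1f nm", object$n_fibrils,
                                  object$mean_diameter)) +
    ggplot2::theme_minimal()
}
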