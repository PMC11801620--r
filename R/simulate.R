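#' Synthetic micrograph configuration
#'
#' Describes the TEM-like phantom the simulator draws: bright elliptical
#' (here circular) fibril cross-sections with a darker rim on a mid-gray
#' background, Gaussian noise, and optional blotchy staining artifacts.
#' Diameters are sampled from a normal distribution truncated to
#' `diameter_range`; the recorded "true" diameter is the full extent of
#' the disk including its dark rim, and the truth mask covers the same
#' extent, so recovered diameters are directly comparable. Defaults mimic
#' TEM cross-sections of cervix collagen: ~60 +/- 10 nm fibrils at 2 nm/px
#' on a 256 x 256 px field at moderate packing.
#'
#' @param size image height and width in pixels.
#' @param pixel_size nm per pixel.
#' @param n_fibrils number of fibrils to place.
#' @param diameter_mean,diameter_sd normal diameter distribution, nm.
#' @param diameter_range truncation bounds in nm (default 10-150).
#' @param background,interior,rim gray levels (0-255) of the field, the
#'   fibril interior, and the dark rim annulus.
#' @param rim_width rim annulus width in px.
#' @param noise_sd additive Gaussian noise standard deviation (intensity).
#' @param n_blotches number of smooth staining blotches.
#' @param blotch_radius blotch radius range in px.
#' @param blotch_strength peak intensity offset of a blotch (signed at
#'   random).
#' @param min_gap minimum edge-to-edge spacing between fibrils in px.
#' @param seed integer seed; every stochastic choice in the simulator is
#'   governed by it.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(size = c(256L, 256L), pixel_size = 2,
                       n_fibrils = 25L, diameter_mean = 60, diameter_sd = 10,
                       diameter_range = c(10, 150), background = 120,
                       interior = 170, rim = 70, rim_width = 2,
                       noise_sd = 10, n_blotches = 3L,
                       blotch_radius = c(5, 15), blotch_strength = 25,
                       min_gap = 3, seed = 1L) {
  stopifnot(all(size >= 16), pixel_size > 0, n_fibrils >= 0,
            diameter_sd >= 0, diameter_range[1] < diameter_range[2],
            rim_width >= 0, noise_sd >= 0, min_gap >= 0)
  structure(as.list(environment()), class = "sim_config")
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n + 10, mean, sd)
    out <- c(out, x[x > lo & x < hi])
  }
  out[seq_len(n)]
}

#' Simulate a TEM-like micrograph with known per-fibril truth
#'
#' Places non-overlapping fibril disks by dart throwing (uniform candidate
#' centers, rejected when closer than the sum of radii plus `min_gap`;
#' retry budget 100 candidates per requested fibril), renders bright
#' interiors with dark rims on the mid-gray background, overlays smooth
#' staining blotches, and adds Gaussian noise. The ground truth -- binary
#' mask, instance labels, and a per-fibril table of centers, diameters and
#' areas -- is recorded before noise, so it is exact. Deterministic per
#' `cfg$seed`.
#'
#' @param cfg a [sim_config].
#' @return A list with `micrograph` (a [micrograph]) and `truth`, an object
#'   of class `sim_truth`: `mask` ([binary_mask]), `labels`
#'   ([labeled_mask]), and `table` (tibble: `label`, `center_row`,
#'   `center_col`, `diameter_nm`, `area_nm2`).
#' @examples
#' sim <- simulate_micrograph(sim_config(n_fibrils = 5, seed = 7))
#' sim$truth$labels$n
#' @export
simulate_micrograph <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    nr <- cfg$size[1]; nc <- cfg$size[2]
    img <- matrix(cfg$background, nr, nc)
    labels <- matrix(0L, nr, nc)
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    diams <- numeric(0)

    # diameters are drawn up front and kept through center retries, so the
    # placed population is an unbiased sample of the truncated normal;
    # placing larger disks first keeps dense packings feasible without
    # changing the sampled population
    target <- if (cfg$n_fibrils > 0) {
      sort(rtruncnorm(cfg$n_fibrils, cfg$diameter_mean, cfg$diameter_sd,
                      cfg$diameter_range[1], cfg$diameter_range[2]),
           decreasing = TRUE)
    } else numeric(0)
    budget <- 200L
    for (d in target) {
      r_px <- d / (2 * cfg$pixel_size)
      placed <- FALSE
      if (1 + r_px < nr - r_px && 1 + r_px < nc - r_px) {
        for (try in seq_len(budget)) {
          cr <- runif(1, 1 + r_px, nr - r_px)
          cc <- runif(1, 1 + r_px, nc - r_px)
          ok <- if (length(radii)) {
            all(sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2) >=
                  radii + r_px + cfg$min_gap)
          } else TRUE
          if (ok) {
            centers <- rbind(centers, c(cr, cc))
            radii <- c(radii, r_px)
            diams <- c(diams, d)
            placed <- TRUE
            break
          }
        }
      }
      if (!placed) {
        stop("infeasible packing: placed ", length(radii), " of ",
             cfg$n_fibrils, " fibrils within the retry budget", call. = FALSE)
      }
    }

    for (i in seq_along(radii)) {
      r_px <- radii[i]
      rr <- max(1L, floor(centers[i, 1] - r_px)):min(nr, ceiling(centers[i, 1] + r_px))
      cc_ <- max(1L, floor(centers[i, 2] - r_px)):min(nc, ceiling(centers[i, 2] + r_px))
      d2 <- outer((rr - centers[i, 1])^2, (cc_ - centers[i, 2])^2, `+`)
      disk <- d2 <= r_px^2
      inner <- d2 <= max(r_px - cfg$rim_width, 0)^2
      win <- img[rr, cc_, drop = FALSE]
      win[disk & !inner] <- cfg$rim
      win[inner] <- cfg$interior
      img[rr, cc_] <- win
      lwin <- labels[rr, cc_, drop = FALSE]
      lwin[disk] <- i
      labels[rr, cc_] <- lwin
    }

    mask <- binary_mask(labels > 0L, provenance = "truth", image_id = "sim")
    lm <- labeled_mask(labels, image_id = "sim")
    truth_tab <- tibble::tibble(
      label = seq_along(radii),
      center_row = centers[, 1], center_col = centers[, 2],
      diameter_nm = diams,
      area_nm2 = pi * (diams / 2)^2
    )

    if (cfg$n_blotches > 0) {
      rowg <- matrix(seq_len(nr), nr, nc)
      colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      for (b in seq_len(cfg$n_blotches)) {
        br <- runif(1, cfg$blotch_radius[1], cfg$blotch_radius[2])
        bc <- c(runif(1, 1, nr), runif(1, 1, nc))
        amp <- sample(c(-1, 1), 1) * cfg$blotch_strength
        d2 <- (rowg - bc[1])^2 + (colg - bc[2])^2
        img <- img + amp * exp(-d2 / (2 * (br / 2)^2))
      }
    }
    if (cfg$noise_sd > 0) {
      img <- img + matrix(rnorm(nr * nc, 0, cfg$noise_sd), nr, nc)
    }
    img <- pmin(pmax(img, 0), 255)

    list(
      micrograph = micrograph(img, pixel_size = cfg$pixel_size,
                              image_id = sprintf("sim_seed%d", cfg$seed)),
      truth = structure(list(mask = mask, labels = lm, table = truth_tab),
                        class = "sim_truth")
    )
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d fibrils, mean true diameter %.1f nm\n",
              nrow(x$table),
              if (nrow(x$table)) mean(x$table$diameter_nm) else NA))
  invisible(x)
}

# shift a logical matrix by (dr, dc), filling exposed cells with FALSE
shift_logical <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- intersect(seq_len(nr), seq_len(nr) - dr)
  cs <- intersect(seq_len(nc), seq_len(nc) - dc)
  out[rs + dr, cs + dc] <- m[rs, cs]
  out
}

disk_offsets <- function(r) {
  o <- expand.grid(dr = -r:r, dc = -r:r)
  o[o$dr^2 + o$dc^2 <= r^2, , drop = FALSE]
}

# binary dilation/erosion by a disk of radius r px (zero-padded borders)
binary_morph <- function(m, r, op = c("dilate", "erode")) {
  op <- match.arg(op)
  if (r == 0) return(m)
  offs <- disk_offsets(r)
  acc <- NULL
  for (i in seq_len(nrow(offs))) {
    s <- shift_logical(m, offs$dr[i], offs$dc[i])
    acc <- if (is.null(acc)) s else if (op == "dilate") acc | s else acc & s
  }
  acc
}

#' Simulate an imperfect human reviewer annotation
#'
#' Perturbs the ground truth the way reviewers disagree in practice: each
#' fibril is independently omitted with probability `omission_prob`, and
#' surviving fibrils are dilated or eroded by a disk of radius drawn
#' uniformly from `-jitter_px..jitter_px` (negative = erode), modeling
#' differing edge definitions. Deterministic per `seed`.
#'
#' @param truth a `sim_truth` from [simulate_micrograph].
#' @param jitter_px maximum dilation/erosion radius in px (default 1).
#' @param omission_prob probability a reviewer misses a fibril entirely.
#' @param seed integer seed.
#' @param reviewer_id string used in the mask provenance.
#' @return A [binary_mask] with provenance `"reviewer:<id>"`.
#' @export
simulate_reviewer <- function(truth, jitter_px = 1L, omission_prob = 0.05,
                              seed = 1L, reviewer_id = "sim") {
  stopifnot(inherits(truth, "sim_truth"), jitter_px >= 0,
            omission_prob >= 0, omission_prob <= 1)
  lm <- truth$labels
  withr::with_seed(seed, {
    out <- matrix(FALSE, nrow(lm$labels), ncol(lm$labels))
    for (i in seq_len(lm$n)) {
      if (runif(1) < omission_prob) next
      j <- if (jitter_px > 0) sample(seq(-jitter_px, jitter_px), 1) else 0L
      inst <- lm$labels == i
      if (j > 0) inst <- binary_morph(inst, j, "dilate")
      if (j < 0) inst <- binary_morph(inst, -j, "erode")
      out <- out | inst
    }
    binary_mask(out, provenance = paste0("reviewer:", reviewer_id),
                image_id = lm$image_id)
  })
}
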