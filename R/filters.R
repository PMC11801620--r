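# Small spatial-filter toolbox on plain [row, col] matrices.
# All convolutions use edge-repeating reflect padding so image borders do not
# introduce artificial gradients; this choice is fixed package-wide.

reflect_idx <- function(n, lo, hi) {
  # edge-repeating reflection (… c b a | a b c … | … c b a), valid for
  # padding of any width relative to n
  p <- (lo - n):(hi - n) + n  # positions lo..hi, possibly outside 1..n
  q <- ((p - 1) %% (2 * n) + 2 * n) %% (2 * n)
  ifelse(q < n, q + 1, 2 * n - q)
}

pad_reflect <- function(x, top, bottom, left, right) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- reflect_idx(nr, 1L - top, nr + bottom)
  ci <- reflect_idx(nc, 1L - left, nc + right)
  x[ri, ci, drop = FALSE]
}

# 2D correlation with reflect padding; exact shifted-sum evaluation (no FFT).
conv2_reflect <- function(x, k) {
  kr <- nrow(k); kc <- ncol(k)
  top <- (kr - 1L) %/% 2L; bottom <- kr - 1L - top
  left <- (kc - 1L) %/% 2L; right <- kc - 1L - left
  p <- pad_reflect(x, top, bottom, left, right)
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (u in seq_len(kr)) {
    for (v in seq_len(kc)) {
      w <- k[u, v]
      if (w != 0) {
        out <- out + w * p[u:(u + nr - 1L), v:(v + nc - 1L), drop = FALSE]
      }
    }
  }
  out
}

gaussian_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  stopifnot(sigma > 0)
  g <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable Gaussian smoothing; kernel half-width defaults to ceil(3*sigma).
gaussian_smooth <- function(x, sigma, radius = ceiling(3 * sigma)) {
  g <- gaussian_kernel_1d(sigma, radius)
  conv2_reflect(conv2_reflect(x, matrix(g, ncol = 1)), matrix(g, nrow = 1))
}

# gradient kernels: *_x responds to intensity change along columns
kern <- list(
  sobel_x   = matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE),
  scharr_x  = matrix(c(-3, 0, 3, -10, 0, 10, -3, 0, 3), 3, 3, byrow = TRUE),
  prewitt_x = matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3, 3, byrow = TRUE),
  roberts_1 = matrix(c(1, 0, 0, -1), 2, 2, byrow = TRUE),
  roberts_2 = matrix(c(0, 1, -1, 0), 2, 2, byrow = TRUE)
)

# sqrt(Gx^2 + Gy^2) magnitude for a 3x3 x-kernel and its transpose
gradient_magnitude <- function(x, kx) {
  gx <- conv2_reflect(x, kx)
  gy <- conv2_reflect(x, t(kx))
  sqrt(gx^2 + gy^2)
}

roberts_magnitude <- function(x) {
  g1 <- conv2_reflect(x, kern$roberts_1)
  g2 <- conv2_reflect(x, kern$roberts_2)
  sqrt(g1^2 + g2^2)
}

# 3x3 median filter via Paeth's 19-comparison median-of-9 sorting network,
# evaluated with vectorized pmin/pmax over the nine shifted neighborhoods.
median_filter3 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  p <- pad_reflect(x, 1L, 1L, 1L, 1L)
  q <- vector("list", 9L)
  i <- 0L
  for (u in 1:3) for (v in 1:3) {
    i <- i + 1L
    q[[i]] <- p[u:(u + nr - 1L), v:(v + nc - 1L), drop = FALSE]
  }
  ps <- function(i, j) {
    lo <- pmin(q[[i]], q[[j]])
    q[[j]] <<- pmax(q[[i]], q[[j]])
    q[[i]] <<- lo
  }
  ps(2, 3); ps(5, 6); ps(8, 9)
  ps(1, 2); ps(4, 5); ps(7, 8)
  ps(2, 3); ps(5, 6); ps(8, 9)
  ps(1, 4); ps(6, 9); ps(5, 8)
  ps(4, 7); ps(2, 5); ps(3, 6)
  ps(5, 8); ps(5, 3); ps(7, 5)
  ps(5, 3)
  q[[5]]
}

#' Canny edge map
#'
#' Classic Canny detector on the 0-255 intensity scale: 3x3 Sobel gradients
#' (no pre-smoothing, matching the common OpenCV call), L2 gradient
#' magnitude, non-maximum suppression with the direction quantized to four
#' sectors, then double-threshold hysteresis -- weak edge pixels (magnitude
#' >= `low`) survive only in 8-connected runs that contain at least one
#' strong pixel (magnitude >= `high`).
#'
#' @param x numeric intensity matrix on the 0-255 scale.
#' @param low,high hysteresis thresholds on the Sobel gradient magnitude.
#' @return numeric matrix of the same shape with edges coded 255, rest 0.
#' @export
canny_edges <- function(x, low = 100, high = 200) {
  stopifnot(low > 0, high >= low)
  nr <- nrow(x); nc <- ncol(x)
  gx <- conv2_reflect(x, kern$sobel_x)
  gy <- conv2_reflect(x, t(kern$sobel_x))
  mag <- sqrt(gx^2 + gy^2)

  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L

  P <- matrix(-Inf, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- mag
  shift <- function(dr, dc) {
    P[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc), drop = FALSE]
  }
  # per sector, the two neighbors along the gradient direction (row axis down)
  nb <- list(
    list(c(0L, 1L), c(0L, -1L)),   # ~0 deg
    list(c(1L, 1L), c(-1L, -1L)),  # ~45 deg
    list(c(1L, 0L), c(-1L, 0L)),   # ~90 deg
    list(c(1L, -1L), c(-1L, 1L))   # ~135 deg
  )
  keep <- matrix(FALSE, nr, nc)
  for (s in 0:3) {
    sel <- sector == s
    if (!any(sel)) next
    o <- nb[[s + 1L]]
    ok <- (mag >= shift(o[[1]][1], o[[1]][2])) & (mag >= shift(o[[2]][1], o[[2]][2]))
    keep[sel] <- ok[sel]
  }

  weak <- keep & (mag >= low)
  strong <- keep & (mag >= high)
  if (!any(strong)) return(matrix(0, nr, nc))
  lab <- label_matrix(weak, connectivity = 8L)
  kept <- unique(lab[strong])
  out <- matrix(0, nr, nc)
  out[lab > 0 & matrix(lab %in% kept, nr, nc)] <- 255
  out
}
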