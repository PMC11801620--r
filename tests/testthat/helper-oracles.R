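# Independent oracles used by property-style tests. These are deliberately
# naive implementations that share no code with the package internals.

# queue-based flood fill connected-component labeling
flood_fill_label <- function(fg, connectivity = 8L) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    offs <- expand.grid(dr = -1:1, dc = -1:1)
    offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  } else {
    offs <- data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  k <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!fg[r0, c0] || lab[r0, c0] > 0L) next
    k <- k + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- k
    while (length(queue)) {
      cur <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (i in seq_len(nrow(offs))) {
        r <- cur[1] + offs$dr[i]; cc <- cur[2] + offs$dc[i]
        if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
            fg[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- k
          queue[[length(queue) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

# exhaustive maximum-total-IoU one-to-one assignment between predicted and
# ground-truth instances; TP = assigned pairs meeting the threshold
exhaustive_match <- function(pred_labels, gt_labels, threshold = 0.33) {
  np <- max(pred_labels); ng <- max(gt_labels)
  iou_mat <- matrix(0, np, ng)
  for (p in seq_len(np)) for (g in seq_len(ng)) {
    a <- which(pred_labels == p); b <- which(gt_labels == g)
    inter <- length(intersect(a, b))
    if (inter > 0) iou_mat[p, g] <- inter / length(union(a, b))
  }
  # enumerate injective partial assignments of preds to gts (NA = unassigned)
  best <- list(total = -1, tp = 0L)
  assign_rec <- function(p, used_g, total, tp) {
    if (p > np) {
      if (total > best$total + 1e-12) best <<- list(total = total, tp = tp)
      return(invisible())
    }
    assign_rec(p + 1L, used_g, total, tp)  # leave p unassigned
    for (g in seq_len(ng)) {
      if (!used_g[g] && iou_mat[p, g] > 0) {
        assign_rec(p + 1L, replace(used_g, g, TRUE), total + iou_mat[p, g],
                   tp + (iou_mat[p, g] >= threshold))
      }
    }
  }
  assign_rec(1L, logical(ng), 0, 0L)
  list(tp = best$tp, fp = np - best$tp)
}

# draw filled disks as a labeled matrix (later disks overwrite earlier)
draw_disks <- function(nr, nc, centers, radii) {
  lab <- matrix(0L, nr, nc)
  rowg <- matrix(seq_len(nr), nr, nc)
  colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_along(radii)) {
    d2 <- (rowg - centers[i, 1])^2 + (colg - centers[i, 2])^2
    lab[d2 <= radii[i]^2] <- i
  }
  lab
}

# small noise-free micrograph with perfectly separable classes: fibril
# pixels at 255 on a 0 background
separable_fixture <- function(nr = 32, nc = 32, pixel_size = 2, seed = 1) {
  lab <- withr::with_seed(seed, {
    n <- 4
    centers <- cbind(runif(n, 6, nr - 6), runif(n, 6, nc - 6))
    draw_disks(nr, nc, centers, rep(3.2, n))
  })
  img <- matrix(0, nr, nc)
  img[lab > 0] <- 255
  list(
    micrograph = micrograph(img, pixel_size = pixel_size, image_id = "sep"),
    mask = binary_mask(lab > 0, provenance = "reviewer:sep", image_id = "sep")
  )
}

expect_same_matrix <- function(a, b) expect_true(identical(a, b) || isTRUE(all.equal(a, b)))
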