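# Independent oracles used across the test files.

# Brute-force per-pixel nearest-marker classification: scalar loops, ties to
# the earlier marker in the canonical class order (same rule the package
# states, independent code path).
brute_force_classify <- function(lab, markers) {
  ord <- order(match(markers$class, c("fungiform", "filiform", "base",
                                      "background")))
  markers <- markers[ord, ]
  H <- dim(lab)[1L]; W <- dim(lab)[2L]
  codes <- c(fungiform = 1L, filiform = 2L, base = 3L, background = 0L)
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      d <- (lab[i, j, 1] - markers$L)^2 + (lab[i, j, 2] - markers$a)^2 +
        (lab[i, j, 3] - markers$b)^2
      out[i, j] <- codes[[markers$class[which.min(d)]]]
    }
  }
  out
}

# Breadth-first-search connected components labelling for small masks.
bfs_label <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  nb <- if (connectivity == 8L) {
    cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1), dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dy = c(-1, 0, 0, 1), dx = c(0, -1, 1, 0))
  }
  labels <- matrix(0L, H, W)
  k <- 0L
  # raster scan by rows so labels come out in top-most/left-most order
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] && labels[i, j] == 0L) {
      k <- k + 1L
      queue <- list(c(i, j))
      labels[i, j] <- k
      while (length(queue) > 0L) {
        p <- queue[[1L]]; queue <- queue[-1L]
        for (q in seq_len(nrow(nb))) {
          yy <- p[1L] + nb[q, 1L]; xx <- p[2L] + nb[q, 2L]
          if (yy >= 1L && yy <= H && xx >= 1L && xx <= W &&
              mask[yy, xx] && labels[yy, xx] == 0L) {
            labels[yy, xx] <- k
            queue[[length(queue) + 1L]] <- c(yy, xx)
          }
        }
      }
    }
  }
  labels
}

# Recall/precision of detected papillae against planted truth: a detection
# matches if its centroid lies within tol_px of a planted centre.
match_stats <- function(quant, truth, tol_px = 3) {
  det <- quant$papillae
  tr <- truth$papillae
  if (nrow(det) == 0L || nrow(tr) == 0L) {
    return(c(recall = as.numeric(nrow(tr) == 0L), precision = NA_real_))
  }
  D2 <- outer(det$x_px, tr$centre_x, "-")^2 +
    outer(det$y_px, tr$centre_y, "-")^2
  c(recall = mean(apply(D2, 2L, min) <= tol_px^2),
    precision = mean(apply(D2, 1L, min) <= tol_px^2))
}
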