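# Independent brute-force oracles used to cross-check the vectorised /
# EBImage-backed implementations.

# per-pixel loop confusion counts
loop_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j]; t <- truth[i, j]
      if (p == 1 && t == 1) tp <- tp + 1L
      else if (p == 1 && t == 0) fp <- fp + 1L
      else if (p == 0 && t == 1) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

# 4-connected component count by flood fill
flood_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- 0L
  for (i0 in seq_len(nrow(mask))) {
    for (j0 in seq_len(ncol(mask))) {
      if (mask[i0, j0] == 1 && lab[i0, j0] == 0) {
        n <- n + 1L
        queue <- list(c(i0, j0))
        lab[i0, j0] <- n
        while (length(queue) > 0) {
          q <- queue[[1]]; queue <- queue[-1]
          for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
            ii <- q[1] + d[1]; jj <- q[2] + d[2]
            if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
                mask[ii, jj] == 1 && lab[ii, jj] == 0) {
              lab[ii, jj] <- n
              queue[[length(queue) + 1]] <- c(ii, jj)
            }
          }
        }
      }
    }
  }
  n
}

# number of enclosed background regions (holes): background components that
# do not touch the raster border
count_holes <- function(mask) {
  bg <- 1L - mask
  lab <- matrix(0L, nrow(bg), ncol(bg))
  n <- 0L
  holes <- 0L
  for (i0 in seq_len(nrow(bg))) {
    for (j0 in seq_len(ncol(bg))) {
      if (bg[i0, j0] == 1 && lab[i0, j0] == 0) {
        n <- n + 1L
        queue <- list(c(i0, j0))
        lab[i0, j0] <- n
        touches <- FALSE
        while (length(queue) > 0) {
          q <- queue[[1]]; queue <- queue[-1]
          if (q[1] == 1 || q[1] == nrow(bg) || q[2] == 1 || q[2] == ncol(bg))
            touches <- TRUE
          for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
            ii <- q[1] + d[1]; jj <- q[2] + d[2]
            if (ii >= 1 && ii <= nrow(bg) && jj >= 1 && jj <= ncol(bg) &&
                bg[ii, jj] == 1 && lab[ii, jj] == 0) {
              lab[ii, jj] <- n
              queue[[length(queue) + 1]] <- c(ii, jj)
            }
          }
        }
        if (!touches) holes <- holes + 1L
      }
    }
  }
  holes
}

# brute-force symmetric mean boundary distance (nearest contour pixel search)
brute_boundary_distance <- function(pred, truth) {
  contour <- function(m) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    for (i in seq_len(nrow(m))) {
      for (j in seq_len(ncol(m))) {
        if (m[i, j] == 1) {
          nb <- c(
            if (i > 1) m[i - 1, j] else 0, if (i < nrow(m)) m[i + 1, j] else 0,
            if (j > 1) m[i, j - 1] else 0, if (j < ncol(m)) m[i, j + 1] else 0)
          if (any(nb == 0)) out[i, j] <- TRUE
        }
      }
    }
    which(out, arr.ind = TRUE)
  }
  cp <- contour(pred); ct <- contour(truth)
  nearest <- function(pts, ref) {
    apply(pts, 1, function(q)
      sqrt(min((ref[, 1] - q[1])^2 + (ref[, 2] - q[2])^2)))
  }
  mean(c(nearest(cp, ct), nearest(ct, cp)))
}

# small disc mask centred in an S x S raster
disc_mask <- function(S, r, cx = S / 2, cy = S / 2) {
  xs <- matrix(rep(seq_len(S), S), S, S)
  ys <- matrix(rep(seq_len(S), each = S), S, S)
  matrix(as.integer((xs - cx)^2 + (ys - cy)^2 <= r^2), S, S)
}

# shift a mask by (di, dj), zero-filling
shift_mask <- function(mask, di, dj) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  src_i <- seq_len(nrow(mask)) - di
  src_j <- seq_len(ncol(mask)) - dj
  ok_i <- src_i >= 1 & src_i <= nrow(mask)
  ok_j <- src_j >= 1 & src_j <= ncol(mask)
  out[which(ok_i), which(ok_j)] <- mask[src_i[ok_i], src_j[ok_j]]
  out
}

# tiny cached synthetic dataset shared across tests
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(synthetic_config(12, seed = 402))
    cache
  }
})
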