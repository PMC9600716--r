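# Independent oracles used across the suite. These stay deliberately naive:
# they are the ground truth the optimized implementations are checked
# against.

# O(n*m) nearest-pixel distance: explicit loop over reference pixels
brute_force_dl_distance <- function(reference, candidate) {
  d <- numeric(nrow(reference))
  for (i in seq_len(nrow(reference))) {
    d[i] <- min(sqrt((reference[i, 1] - candidate[, 1])^2 +
                     (reference[i, 2] - candidate[, 2])^2))
  }
  mean(d)
}

# globally optimal 2-means inertia by exhaustive enumeration of all
# bipartitions (n <= ~16)
exhaustive_kmeans2 <- function(X) {
  n <- nrow(X)
  sse <- function(rows) {
    if (!length(rows)) return(0)
    ctr <- colMeans(X[rows, , drop = FALSE])
    sum(sweep(X[rows, , drop = FALSE], 2, ctr)^2)
  }
  best <- Inf
  for (code in seq_len(2^(n - 1) - 1)) {   # row 1 fixed in group A
    grp <- c(0L, as.integer(intToBits(code))[seq_len(n - 1)])
    val <- sse(which(grp == 0L)) + sse(which(grp == 1L))
    if (val < best) best <- val
  }
  best
}

# per-cluster inner border: pixels of the cluster with an in-bounds
# 4-neighbor outside it (morphological border, computed pixel by pixel)
inner_border_union <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ni <- i + d[1]; nj <- j + d[2]
      if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
          labels[ni, nj] != labels[i, j]) {
        out[i, j] <- TRUE
        break
      }
    }
  }
  mask_to_pixels(out)
}

random_pixel_set <- function(n, h, w) {
  idx <- sample.int(h * w, n)
  cbind(row = (idx - 1L) %/% w, col = (idx - 1L) %% w)
}
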