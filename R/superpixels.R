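#' SLIC parameter set
#'
#' Defaults follow the study conditions: 100 target superpixels,
#' compactness 5, Gaussian pre-smoothing sigma 5 on each of L*, a*, b*.
#'
#' @param n_segments Target superpixel count (>= 1).
#' @param compactness Color/space balance weight m (> 0); larger values give
#'   more compact, grid-like superpixels, smaller values better color
#'   adherence.
#' @param sigmas Gaussian widths (pixels) applied to the L*, a*, b* planes
#'   before segmentation; recycled to length 3.
#' @param max_iters Assignment/update refinement iterations.
#' @param enforce_connectivity Absorb disconnected label fragments into a
#'   neighboring superpixel.
#' @return A list of class `"slic_params"`.
#' @export
slic_params <- function(n_segments = 100L, compactness = 5,
                        sigmas = c(5, 5, 5), max_iters = 10L,
                        enforce_connectivity = TRUE) {
  stopifnot(n_segments >= 1, compactness > 0, max_iters >= 1)
  sigmas <- rep_len(sigmas, 3L)
  stopifnot(all(is.finite(sigmas)), all(sigmas >= 0))
  structure(list(n_segments = as.integer(n_segments),
                 compactness = compactness, sigmas = sigmas,
                 max_iters = as.integer(max_iters),
                 enforce_connectivity = isTRUE(enforce_connectivity)),
            class = "slic_params")
}

# 4-connected components of a label matrix by iterative min-propagation:
# each pixel starts as its own component id and repeatedly takes the
# minimum id among same-label 4-neighbors until a fixed point.
connected_components <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  comp <- matrix(seq_len(h * w), h, w)
  repeat {
    new <- comp
    up <- labels[-1, , drop = FALSE] == labels[-h, , drop = FALSE]
    nxt <- pmin(new[-1, , drop = FALSE],
                ifelse(up, new[-h, , drop = FALSE], new[-1, , drop = FALSE]))
    prv <- pmin(new[-h, , drop = FALSE],
                ifelse(up, new[-1, , drop = FALSE], new[-h, , drop = FALSE]))
    new[-1, ] <- nxt; new[-h, ] <- pmin(new[-h, , drop = FALSE], prv)
    lf <- labels[, -1, drop = FALSE] == labels[, -w, drop = FALSE]
    nxt <- pmin(new[, -1, drop = FALSE],
                ifelse(lf, new[, -w, drop = FALSE], new[, -1, drop = FALSE]))
    prv <- pmin(new[, -w, drop = FALSE],
                ifelse(lf, new[, -1, drop = FALSE], new[, -w, drop = FALSE]))
    new[, -1] <- nxt; new[, -w] <- pmin(new[, -w, drop = FALSE], prv)
    if (identical(new, comp)) break
    comp <- new
  }
  matrix(match(comp, sort(unique(as.vector(comp)))), h, w)
}

# renumber labels to 0..n-1 in order of first appearance in a row-major
# scan (row 0 first), so outputs are reproducible across platforms
renumber_row_major <- function(labels) {
  first_seen <- unique(as.vector(t(labels)))
  matrix(match(labels, first_seen) - 1L, nrow(labels), ncol(labels))
}

#' Segment an image into SLIC superpixels
#'
#' Simple linear iterative clustering on the (pre-smoothed) L*a*b* planes:
#' cluster seeds start on a regular grid with spacing `S =
#' sqrt(area / n_segments)`, are nudged to the lowest-gradient pixel in
#' their 3x3 neighborhood, and are then refined by k-means-style iterations
#' in the joint color--coordinate space. Each pixel is assigned to the
#' nearest seed within a 2S x 2S search window under the distance
#' `sqrt(d_lab^2 + (compactness / S)^2 * d_xy^2)`; seeds move to their
#' members' means. Optionally, disconnected fragments smaller than `S^2 / 4`
#' are absorbed into the neighboring superpixel they share the longest
#' border with. Fully deterministic.
#'
#' @param stack A `channel_stack` (only the L*, a*, b* planes are used).
#' @param params A [slic_params()] object; its `sigmas` smooth the L*a*b*
#'   planes before clustering.
#' @return A `superpixel_map`: list with `labels` (integer `h x w` matrix of
#'   0-based labels, contiguous `0..n_superpixels-1`), `n_superpixels`, and
#'   `dim`.
#' @export
slic_segment <- function(stack, params = slic_params()) {
  h <- stack$dim[1]; w <- stack$dim[2]
  if (params$n_segments > h * w)
    stop("slic_segment: n_segments exceeds image area")
  sm <- gaussian_smooth(stack[c("L", "a", "b", "dim")], params$sigmas)
  L <- sm$L; A <- sm$a; B <- sm$b
  S <- sqrt(h * w / params$n_segments)

  # grid seeds at cell centers
  sr <- round(seq(S / 2, h, by = S)); sr <- sr[sr >= 1 & sr <= h]
  sc <- round(seq(S / 2, w, by = S)); sc <- sc[sc >= 1 & sc <= w]
  seeds <- as.matrix(expand.grid(r = sr, c = sc))
  n_seed <- nrow(seeds)

  # move each seed to the lowest-color-gradient pixel in its 3x3 block
  grad <- matrix(Inf, h, w)
  if (h > 2 && w > 2) {
    core_r <- 2:(h - 1); core_c <- 2:(w - 1)
    gr <- (L[core_r + 1, core_c] - L[core_r - 1, core_c])^2 +
          (A[core_r + 1, core_c] - A[core_r - 1, core_c])^2 +
          (B[core_r + 1, core_c] - B[core_r - 1, core_c])^2
    gc <- (L[core_r, core_c + 1] - L[core_r, core_c - 1])^2 +
          (A[core_r, core_c + 1] - A[core_r, core_c - 1])^2 +
          (B[core_r, core_c + 1] - B[core_r, core_c - 1])^2
    grad[core_r, core_c] <- gr + gc
  }
  for (i in seq_len(n_seed)) {
    rr <- max(1, seeds[i, 1] - 1):min(h, seeds[i, 1] + 1)
    cc <- max(1, seeds[i, 2] - 1):min(w, seeds[i, 2] + 1)
    g <- grad[rr, cc, drop = FALSE]
    if (all(is.infinite(g))) next
    best <- which(g == min(g), arr.ind = TRUE)[1, ]
    seeds[i, ] <- c(rr[best[1]], cc[best[2]])
  }
  centers <- cbind(r = as.numeric(seeds[, 1]), c = as.numeric(seeds[, 2]),
                   L = L[seeds], a = A[seeds], b = B[seeds])

  m2 <- (params$compactness / S)^2
  labels <- matrix(1L, h, w)
  for (iter in seq_len(params$max_iters)) {
    dist <- matrix(Inf, h, w)
    for (i in seq_len(n_seed)) {
      rr <- max(1, floor(centers[i, 1] - S)):min(h, ceiling(centers[i, 1] + S))
      cc <- max(1, floor(centers[i, 2] - S)):min(w, ceiling(centers[i, 2] + S))
      dlab <- (L[rr, cc] - centers[i, 3])^2 + (A[rr, cc] - centers[i, 4])^2 +
              (B[rr, cc] - centers[i, 5])^2
      dxy <- outer((rr - centers[i, 1])^2, (cc - centers[i, 2])^2, `+`)
      d <- dlab + m2 * dxy
      win <- dist[rr, cc]
      upd <- d < win
      win[upd] <- d[upd]
      dist[rr, cc] <- win
      lw <- labels[rr, cc]; lw[upd] <- i; labels[rr, cc] <- lw
    }
    rows <- matrix(seq_len(h), h, w); cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    grp <- factor(labels, levels = seq_len(n_seed))
    cnt <- as.numeric(table(grp))
    keep <- cnt > 0
    sums <- rowsum(cbind(as.vector(rows), as.vector(cols), as.vector(L),
                         as.vector(A), as.vector(B)),
                   as.vector(labels), reorder = TRUE)
    centers[keep, ] <- sums / cnt[keep]
  }

  if (params$enforce_connectivity)
    labels <- absorb_fragments(labels, threshold = S^2 / 4)
  labels <- renumber_row_major(labels)
  structure(list(labels = labels, n_superpixels = max(labels) + 1L,
                 dim = c(h, w)),
            class = "superpixel_map")
}

# enforce 4-connectivity: each label keeps its largest connected component;
# orphan fragments smaller than `threshold` pixels are reassigned to the
# neighboring label with the longest shared border, larger orphans become
# superpixels of their own
absorb_fragments <- function(labels, threshold) {
  comp <- connected_components(labels)
  sizes <- tabulate(comp)
  comp_label <- labels[match(seq_along(sizes), comp)]
  keep <- rep(FALSE, length(sizes))
  for (lb in unique(as.vector(labels))) {
    cs <- which(comp_label == lb)
    keep[cs[which.max(sizes[cs])]] <- TRUE
  }
  orphan <- which(!keep)
  if (!length(orphan)) return(labels)
  h <- nrow(labels); w <- ncol(labels)
  next_label <- max(labels) + 1L
  for (cid in orphan[order(sizes[orphan])]) {
    px <- which(comp == cid, arr.ind = TRUE)
    if (sizes[cid] >= threshold) {       # big enough to stand alone
      labels[px] <- next_label
      next_label <- next_label + 1L
      next
    }
    own <- labels[px[1, 1], px[1, 2]]
    nb_lab <- integer(0); nb_comp <- integer(0)
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      nb <- cbind(px[, 1] + d[1], px[, 2] + d[2])
      ok <- nb[, 1] >= 1 & nb[, 1] <= h & nb[, 2] >= 1 & nb[, 2] <= w
      nbi <- nb[ok, , drop = FALSE]
      nl <- labels[nbi]; nc <- comp[nbi]
      nb_lab <- c(nb_lab, nl[nl != own])
      nb_comp <- c(nb_comp, nc[nl != own])
    }
    if (length(nb_lab)) {
      tv <- table(nb_lab)
      win <- as.integer(names(tv)[which.max(tv)])
      labels[px] <- win
      comp[px] <- nb_comp[match(win, nb_lab)]  # merge into that component
    }
  }
  labels
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat("superpixel_map:", x$dim[1], "x", x$dim[2], "pixels,",
      x$n_superpixels, "superpixels\n")
  invisible(x)
}

#' Export a label map
#'
#' Writes a superpixel or cluster label matrix as a grayscale image holding
#' the raw label values (8-bit PNG for up to 256 labels, 16-bit grayscale
#' TIFF beyond that) or as a CSV with 0-based columns `row,col,label`.
#' Every format round-trips through [read_label_map()] losslessly.
#'
#' @param labels An integer label matrix, or a `superpixel_map`.
#' @param path Output path; format from extension (`.png`, `.tif`/`.tiff`
#'   or `.csv`).
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  if (inherits(labels, "superpixel_map")) labels <- labels$labels
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (max(labels) > 255L)
      stop("write_label_map: more than 256 labels; use .tif or .csv")
    png::writePNG(labels / 255, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (max(labels) > 65535L)
      stop("write_label_map: more than 65536 labels; use .csv")
    tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  } else {
    px <- which(labels >= 0, arr.ind = TRUE)
    df <- data.frame(row = px[, 1] - 1L, col = px[, 2] - 1L,
                     label = labels[px])
    df <- df[order(df$row, df$col), ]
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#'
#' @param path `.png`, `.tif`/`.tiff` or `.csv` path.
#' @return An integer label matrix.
#' @export
read_label_map <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  } else {
    df <- utils::read.csv(path)
    h <- max(df$row) + 1L; w <- max(df$col) + 1L
    m <- matrix(NA_integer_, h, w)
    m[cbind(df$row + 1L, df$col + 1L)] <- as.integer(df$label)
    m
  }
}
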