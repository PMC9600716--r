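#' Extract cluster boundaries as a demarcation-line candidate
#'
#' A pixel belongs to the boundary set iff at least one of its in-bounds
#' 4-neighbors carries a different cluster index, so both sides of every
#' interface are included and the set is symmetric in the two clusters it
#' separates. The image border itself never creates boundary pixels. A
#' constant label image yields an empty set.
#'
#' @param labels An integer cluster label matrix (e.g. from
#'   [project_to_pixels()]), or a `superpixel_map`.
#' @param k Optional cluster count recorded in the result.
#' @return A `boundary_set`: list with `k`, `pixels` (0-based `row,col`
#'   integer matrix, row-major order) and `dim`.
#' @export
extract_boundaries <- function(labels, k = NA_integer_) {
  if (inherits(labels, "superpixel_map")) {
    if (is.na(k)) k <- labels$n_superpixels
    labels <- labels$labels
  }
  h <- nrow(labels); w <- ncol(labels)
  b <- matrix(FALSE, h, w)
  dv <- labels[-1, , drop = FALSE] != labels[-h, , drop = FALSE]
  b[-1, ] <- dv; b[-h, ] <- b[-h, , drop = FALSE] | dv
  dh <- labels[, -1, drop = FALSE] != labels[, -w, drop = FALSE]
  b[, -1] <- b[, -1, drop = FALSE] | dh
  b[, -w] <- b[, -w, drop = FALSE] | dh
  structure(list(k = as.integer(k), pixels = mask_to_pixels(b),
                 dim = c(h, w)),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat("boundary_set: k =", x$k, ",", nrow(x$pixels), "pixels on a",
      x$dim[1], "x", x$dim[2], "frame\n")
  invisible(x)
}

#' Run the cluster-count sweep and extract one DL candidate per k
#'
#' For each requested cluster count k, fits a minimum-inertia k-means model
#' on the superpixel features ([kmeans_fit()]), projects cluster indices to
#' pixels and extracts the cluster boundaries. The default sweep k = 2..6
#' presents candidates at several segmentation levels; the choice among
#' them is the viewer's.
#'
#' @param features Feature matrix from [compute_features()].
#' @param sp The `superpixel_map` the features were computed on.
#' @param ks Strictly increasing cluster counts (default `2:6`), each
#'   `<= n_superpixels`.
#' @param params A [kmeans_params()] object; its `k` is overridden by each
#'   sweep value.
#' @return A `candidate_sweep`: list of `boundary_set` objects named
#'   `k<value>`, with the fitted `cluster_model`s in attribute `models` and
#'   the label images in attribute `label_images`.
#' @export
run_sweep <- function(features, sp, ks = 2:6, params = kmeans_params()) {
  ks <- as.integer(ks)
  if (any(diff(ks) <= 0)) stop("run_sweep: ks must be strictly increasing")
  if (max(ks) > sp$n_superpixels)
    stop("run_sweep: max(ks) exceeds n_superpixels")
  sets <- vector("list", length(ks))
  models <- vector("list", length(ks))
  limgs <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    p <- params; p$k <- ks[i]
    models[[i]] <- kmeans_fit(features, p)
    limgs[[i]] <- project_to_pixels(sp, models[[i]])
    sets[[i]] <- extract_boundaries(limgs[[i]], k = ks[i])
  }
  names(sets) <- names(models) <- names(limgs) <- paste0("k", ks)
  structure(sets, ks = ks, models = models, label_images = limgs,
            class = "candidate_sweep")
}

#' @export
print.candidate_sweep <- function(x, ...) {
  cat("candidate_sweep over k =", paste(attr(x, "ks"), collapse = ", "), "\n")
  for (s in x)
    cat("  k =", s$k, ":", nrow(s$pixels), "boundary pixels\n")
  invisible(x)
}

#' Write a boundary set as CSV
#'
#' @param bset A `boundary_set`.
#' @param path Output CSV path; columns `row,col`, 0-based, row-major.
#' @return `path`, invisibly.
#' @export
write_boundary_csv <- function(bset, path) {
  utils::write.csv(as.data.frame(bset$pixels), path, row.names = FALSE)
  invisible(path)
}

#' Read a boundary CSV written by [write_boundary_csv()]
#'
#' @param path CSV path with columns `row,col`.
#' @param dim Frame size `c(height, width)`.
#' @param k Optional cluster count to record.
#' @return A `boundary_set`.
#' @export
read_boundary_csv <- function(path, dim, k = NA_integer_) {
  df <- utils::read.csv(path)
  px <- cbind(row = as.integer(df$row), col = as.integer(df$col))
  structure(list(k = as.integer(k),
                 pixels = px[order(px[, 1], px[, 2]), , drop = FALSE],
                 dim = as.integer(dim)),
            class = "boundary_set")
}

#' Draw a boundary set over an image
#'
#' Paints the candidate's pixels in a single color over the input image, the
#' usual way DL candidates are presented (green by default).
#'
#' @param img An [rgb_image()] array with the boundary's frame size.
#' @param bset A `boundary_set`.
#' @param color Length-3 RGB vector in 0--255.
#' @return The overlay as an [rgb_image()] array.
#' @export
overlay_boundary <- function(img, bset, color = c(0L, 255L, 0L)) {
  img <- rgb_image(unclass(img))
  if (!all(dim(img)[1:2] == bset$dim))
    stop("overlay_boundary: image and boundary dimensions differ")
  idx <- bset$pixels + 1L
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[idx] <- color[ch]
    img[, , ch] <- pl
  }
  img
}
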