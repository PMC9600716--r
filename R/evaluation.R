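#' Canonical evaluation frame size
#'
#' Every mask and label image is resampled to a common frame before distance
#' computation so scores are comparable across images of different native
#' resolutions. Default 564 x 515 (width x height).
#'
#' @param width,height Frame size in pixels (>= 2).
#' @return A list of class `"canonical_size"` with `height` and `width`.
#' @export
canonical_size <- function(width = 564L, height = 515L) {
  stopifnot(width >= 2, height >= 2)
  structure(list(height = as.integer(height), width = as.integer(width)),
            class = "canonical_size")
}

#' Resize a mask or label image to the canonical frame
#'
#' Nearest-neighbor interpolation, so masks stay binary and label images
#' stay categorical. A mask that loses all its set pixels in a downscale
#' triggers a warning.
#'
#' @param x A logical mask or an integer label matrix.
#' @param size A [canonical_size()].
#' @return The resized matrix, same mode as the input.
#' @export
resize_to_canonical <- function(x, size = canonical_size()) {
  h_in <- nrow(x); w_in <- ncol(x)
  h <- size$height; w <- size$width
  if (h_in == h && w_in == w) return(x)
  ri <- pmin(h_in, floor((seq_len(h) - 0.5) * h_in / h) + 1L)
  ci <- pmin(w_in, floor((seq_len(w) - 0.5) * w_in / w) + 1L)
  out <- x[ri, ci, drop = FALSE]
  if (is.logical(x) && any(x) && !any(out))
    warning("resize_to_canonical: all mask pixels lost in downscale")
  out
}

# 1-D squared-distance transform d[q] = min_p (q - p)^2 + f[p]
# (Felzenszwalb--Huttenlocher lower envelope of parabolas); infinite f[p]
# entries contribute no parabola
edt_dt1 <- function(f) {
  n <- length(f)
  finite_q <- which(is.finite(f))
  if (!length(finite_q)) return(rep(Inf, n))
  v <- integer(n); z <- numeric(n + 1L); kk <- 0L
  for (q in finite_q) {
    if (kk == 0L) {
      kk <- 1L; v[1L] <- q; z[1L] <- -Inf; z[2L] <- Inf
      next
    }
    repeat {
      p <- v[kk]
      s <- ((f[q] + q * q) - (f[p] + p * p)) / (2 * q - 2 * p)
      if (s <= z[kk]) {
        kk <- kk - 1L
        if (kk == 0L) break
      } else break
    }
    kk <- kk + 1L
    v[kk] <- q
    z[kk] <- if (kk == 1L) -Inf else s
    z[kk + 1L] <- Inf
  }
  d <- numeric(n); j <- 1L
  for (q in seq_len(n)) {
    while (z[j + 1L] < q) j <- j + 1L
    d[q] <- (q - v[j])^2 + f[v[j]]
  }
  d
}

# exact squared Euclidean distance transform of a point set on a grid:
# separable application of edt_dt1 along columns then rows; input a logical
# matrix of sites, output squared distance to the nearest site (exact for
# integer grids)
edt_squared <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  g <- matrix(ifelse(mask, 0, Inf), h, w)
  for (j in seq_len(w)) if (any(mask[, j])) g[, j] <- edt_dt1(g[, j])
  out <- matrix(Inf, h, w)
  for (i in seq_len(h)) out[i, ] <- edt_dt1(g[i, ])
  out
}

#' Mean nearest-pixel Euclidean distance between two boundaries
#'
#' The performance index for a DL candidate: the Euclidean distance from
#' each pixel of the reference DL (expert-drawn) to the nearest pixel of
#' the candidate boundary, summarized over reference pixels. Note the
#' metric is directional -- reference to candidate only; extra candidate
#' pixels can only lower it.
#'
#' @param reference,candidate 0-based `row,col` pixel matrices (or
#'   `boundary_set` objects) on the same frame; both nonempty. An empty
#'   candidate means the clustering was constant ("no boundary at this k")
#'   and is an error here.
#' @param dim Frame size `c(height, width)`; taken from `boundary_set`
#'   inputs when omitted.
#' @param summary `"mean"` (default, the reported index), `"median"`, or
#'   `"max"` (directed Hausdorff).
#' @return The summarized distance in pixels.
#' @export
dl_distance <- function(reference, candidate, dim = NULL,
                        summary = c("mean", "median", "max")) {
  summary <- match.arg(summary)
  if (inherits(reference, "boundary_set")) {
    dim <- reference$dim; reference <- reference$pixels
  }
  if (inherits(candidate, "boundary_set")) {
    if (is.null(dim)) dim <- candidate$dim
    else if (!all(dim == candidate$dim))
      stop("dl_distance: reference and candidate frame sizes differ")
    candidate <- candidate$pixels
  }
  if (is.null(dim)) stop("dl_distance: frame size 'dim' required")
  reference <- as.matrix(reference); candidate <- as.matrix(candidate)
  if (!nrow(reference)) stop("dl_distance: empty reference DL")
  if (!nrow(candidate))
    stop("dl_distance: empty candidate (no boundary at this k)")
  d2map <- edt_squared(pixels_to_mask(candidate, dim))
  d <- sqrt(d2map[reference + 1L])
  switch(summary, mean = mean(d), median = stats::median(d), max = max(d))
}

#' Aggregate per-image distances into per-case and per-k summaries
#'
#' @param results A data frame with columns `case`, `image`, `k`,
#'   `distance` (one row per image and cluster count; `NA` distance marks
#'   "no boundary at this k" and is dropped from summaries).
#' @return A list of class `"evaluation_result"`:
#'   \describe{
#'     \item{per_image}{the input table, cleaned;}
#'     \item{case_by_k}{mean distance across a case's images at each k;}
#'     \item{per_case}{min / average / max over all (image, k) cells of the
#'       case;}
#'     \item{by_k}{the cross-case average at each k (the per-k mean
#'       curve).}
#'   }
#' @export
aggregate_case <- function(results) {
  stopifnot(all(c("case", "image", "k", "distance") %in% names(results)))
  res <- results[!is.na(results$distance), , drop = FALSE]
  if (!nrow(res)) stop("aggregate_case: no finite distances")
  case_by_k <- aggregate(distance ~ case + k, res, mean)
  case_by_k <- case_by_k[order(case_by_k$case, case_by_k$k), ]
  per_case <- do.call(rbind, lapply(split(res, res$case), function(d)
    data.frame(case = d$case[1], min = min(d$distance),
               avg = mean(d$distance), max = max(d$distance))))
  rownames(per_case) <- NULL
  by_k <- aggregate(distance ~ k, res, mean)
  names(by_k)[2] <- "mean_distance"
  structure(list(per_image = res, case_by_k = case_by_k,
                 per_case = per_case, by_k = by_k),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("evaluation_result over", nrow(x$per_case), "case(s)\n")
  cat("per-k mean distance (pixels):\n")
  print(x$by_k, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation result as CSV and JSON
#'
#' @param result An `evaluation_result`.
#' @param dir Output directory (created if needed); writes
#'   `distances.csv`, `aggregate.json`.
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$per_image, file.path(dir, "distances.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(case_by_k = result$case_by_k,
                            per_case = result$per_case,
                            by_k = result$by_k),
                       file.path(dir, "aggregate.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
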