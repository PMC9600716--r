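#' Quantization scheme for entropy computation
#'
#' Each plane is quantized into `n_levels` equal-width bins over its fixed
#' canonical range (L* `[0,100]`, a*/b* `[-128,127]`, H `[0,360)`, S/V
#' `[0,100]`), so entropies are comparable across superpixels and images.
#' Values are clamped to the range before binning.
#'
#' @param n_levels Number of intensity levels L (default 256, the 8-bit
#'   scale).
#' @return A list of class `"quantization_scheme"`.
#' @export
quantization_scheme <- function(n_levels = 256L) {
  stopifnot(n_levels >= 2)
  structure(list(n_levels = as.integer(n_levels), ranges = plane_ranges),
            class = "quantization_scheme")
}

quantize_values <- function(x, range, n_levels) {
  lev <- floor((x - range[1]) / (range[2] - range[1]) * n_levels)
  pmin.int(pmax.int(lev, 0L), n_levels - 1L)
}

#' Local Shannon entropy of a value multiset
#'
#' Quantizes the values to `n_levels` intensity levels and returns the
#' Shannon entropy of the resulting histogram in bits:
#' `H = -sum_l (n_l / T) log2(n_l / T)`, with `0 log2 0 := 0`. Within this
#' pipeline the multiset is one superpixel's pixels in one color plane, and
#' the entropy serves as the texture-irregularity descriptor.
#'
#' @param values Numeric vector (at least one value).
#' @param range Canonical `c(lo, hi)` range used for equal-width binning.
#' @param scheme A [quantization_scheme()].
#' @return Entropy in bits, in `[0, log2(n_levels)]`.
#' @export
local_entropy <- function(values, range = c(0, 100),
                          scheme = quantization_scheme()) {
  if (!length(values)) stop("local_entropy: empty input")
  lev <- quantize_values(values, range, scheme$n_levels)
  p <- tabulate(lev + 1L, nbins = scheme$n_levels) / length(values)
  p <- p[p > 0]
  -sum(p * log2(p))
}

feature_colnames <- c(paste0("mean_", plane_names),
                      paste0("entropy_", plane_names))

#' Compute the 12-dimensional feature matrix of a segmentation
#'
#' Row `i` (for superpixel label `i - 1`) holds the arithmetic mean of each
#' of the six color planes over that superpixel's pixels, followed by the
#' local entropy of each plane over the same pixels. The hue mean is the
#' plain arithmetic mean of degree values (no circular statistics).
#'
#' @param stack A `channel_stack` from [rgb_to_planes()] (unsmoothed; the
#'   entropy descriptor needs the original texture).
#' @param sp A `superpixel_map` from [slic_segment()].
#' @param scheme A [quantization_scheme()].
#' @param zscore If `TRUE`, z-score each column (constant columns are left
#'   at zero). Off by default: features go to the clusterer unscaled.
#' @return A numeric `n_superpixels x 12` matrix with columns
#'   `mean_L ... mean_V, entropy_L ... entropy_V`.
#' @export
compute_features <- function(stack, sp, scheme = quantization_scheme(),
                             zscore = FALSE) {
  if (!all(stack$dim == sp$dim))
    stop("compute_features: stack and superpixel map dimensions differ")
  lab <- as.vector(sp$labels)
  n <- sp$n_superpixels
  cnt <- tabulate(lab + 1L, nbins = n)
  lab_f <- factor(lab, levels = 0:(n - 1L))
  feats <- matrix(NA_real_, n, 12L, dimnames = list(NULL, feature_colnames))
  for (j in seq_along(plane_names)) {
    pn <- plane_names[j]
    v <- as.vector(stack[[pn]])
    # group-wise mean() (long-double two-pass accumulation): identical
    # pixel values yield bit-identical means whatever the superpixel size
    feats[, j] <- vapply(split(v, lab_f), mean, numeric(1), USE.NAMES = FALSE)
    lev <- quantize_values(v, plane_ranges[[pn]], scheme$n_levels)
    hist2 <- tabulate(lab * scheme$n_levels + lev + 1L,
                      nbins = n * scheme$n_levels)
    pm <- matrix(hist2, nrow = scheme$n_levels) / rep(cnt, each = scheme$n_levels)
    plogp <- ifelse(pm > 0, pm * log2(pm), 0)
    feats[, 6L + j] <- -colSums(plogp)
  }
  if (zscore) {
    sds <- apply(feats, 2, stats::sd)
    feats <- scale(feats, center = TRUE,
                   scale = ifelse(sds > 0, sds, 1))
    attr(feats, "scaled:center") <- NULL
    attr(feats, "scaled:scale") <- NULL
  }
  feats
}

#' Write a feature matrix as CSV with the fixed 12-column header
#'
#' @param features Matrix from [compute_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}
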