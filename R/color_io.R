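#' Construct and validate an 8-bit RGB image
#'
#' The raw input type of the pipeline: a `height x width x 3` integer array
#' with values in `[0, 255]`, row 0 at the top. All pixel coordinates in this
#' package are 0-based `(row, col)`.
#'
#' @param x A numeric array. A `h x w` matrix is replicated to 3 channels; a
#'   `h x w x 1` array likewise; a `h x w x 4` array has its alpha channel
#'   dropped with a warning.
#' @return An integer array of dimension `h x w x 3`, class `"rgb_image"`.
#' @export
rgb_image <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("rgb_image: expected a h x w x channels array")
  d <- dim(x)
  if (d[1] < 2L || d[2] < 2L)
    stop("rgb_image: image must be at least 2 x 2 pixels")
  if (d[3] == 1L) {
    x <- array(rep(x, 3L), c(d[1], d[2], 3L))
  } else if (d[3] == 4L) {
    warning("rgb_image: alpha channel dropped")
    x <- x[, , 1:3, drop = FALSE]
  } else if (d[3] != 3L) {
    stop("rgb_image: expected 1, 3 or 4 channels, got ", d[3])
  }
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    stop("rgb_image: channel values must be in [0, 255]")
  x <- array(as.integer(round(x)), dim(x))
  class(x) <- c("rgb_image", class(x))
  x
}

#' Read an image file as an 8-bit RGB image
#'
#' Decodes PNG, TIFF or JPEG. Grayscale images are replicated to three
#' channels; an alpha channel is dropped with a warning.
#'
#' @param path Path to the image file.
#' @return An [rgb_image()] array (`h x w x 3`, integer, 0--255).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("read_image: file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("read_image: cannot decode '",
                                           path, "': ", conditionMessage(e)))
  a <- EBImage::imageData(img)      # EBImage stores (x, y[, ch]) in [0, 1]
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  a <- aperm(a, c(2L, 1L, 3L))      # to (row, col, ch)
  rgb_image(round(a * 255))
}

#' Write an 8-bit RGB image to disk
#'
#' Format is chosen from the file extension (png, tif/tiff, jpg/jpeg).
#'
#' @param img An [rgb_image()] array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- rgb_image(unclass(img))
  a <- aperm(img, c(2L, 1L, 3L)) / 255
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

plane_names <- c("L", "a", "b", "H", "S", "V")

# canonical per-plane value ranges; H's upper end 360 is exclusive
plane_ranges <- list(
  L = c(0, 100), a = c(-128, 127), b = c(-128, 127),
  H = c(0, 360), S = c(0, 100),    V = c(0, 100)
)

#' Convert an RGB image to the six color planes used by the pipeline
#'
#' Computes CIE L*a*b* (sRGB primaries, D65 illuminant) and HSV planes.
#' Canonical ranges: L* in `[0, 100]`, a*/b* in `[-128, 127]`, H in
#' `[0, 360)` degrees, S and V in `[0, 100]` percent.
#'
#' @param img An [rgb_image()] array.
#' @return A `channel_stack`: a list with matrices `L`, `a`, `b`, `H`, `S`,
#'   `V` (each `h x w`) and a `dim` element `c(h, w)`.
#' @export
rgb_to_planes <- function(img) {
  img <- rgb_image(unclass(img))
  h <- dim(img)[1]; w <- dim(img)[2]
  rgb <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
               as.vector(img[, , 3]))
  lab <- grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab")
  hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 255)
  H <- hsv[1, ] * 360; H[H >= 360] <- 0
  planes <- list(
    L = matrix(lab[, 1], h, w), a = matrix(lab[, 2], h, w),
    b = matrix(lab[, 3], h, w), H = matrix(H, h, w),
    S = matrix(hsv[2, ] * 100, h, w), V = matrix(hsv[3, ] * 100, h, w)
  )
  structure(c(planes, list(dim = c(h, w))), class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat("channel_stack:", x$dim[1], "x", x$dim[2],
      "pixels; planes L*, a*, b*, H, S, V\n")
  invisible(x)
}

# fold an out-of-range index back into [1, n] by symmetric (half-sample)
# reflection; valid for any offset, period 2n
fold_reflect <- function(idx, n) {
  m <- (idx - 1L) %% (2L * n)
  ifelse(m < n, m + 1L, 2L * n - m)
}

smooth_matrix <- function(m, sigma) {
  if (sigma == 0) return(m)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  w <- exp(-(-r:r)^2 / (2 * sigma^2)); w <- w / sum(w)
  conv1 <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    acc <- m * w[r + 1L]
    for (k in seq_len(r)) {
      im <- fold_reflect(seq_len(n) - k, n)
      ip <- fold_reflect(seq_len(n) + k, n)
      acc <- acc + if (along_rows) w[r + 1L - k] * (m[im, , drop = FALSE] +
                                                    m[ip, , drop = FALSE])
             else w[r + 1L - k] * (m[, im, drop = FALSE] +
                                   m[, ip, drop = FALSE])
    }
    acc
  }
  conv1(conv1(m, TRUE), FALSE)
}

#' Gaussian smoothing of channel planes
#'
#' Convolves each plane with an isotropic Gaussian of the given sigma
#' (pixels), with symmetric reflective boundary handling, which preserves
#' the plane mean. `sigma = 0` leaves a plane unchanged.
#'
#' @param stack A `channel_stack` from [rgb_to_planes()], or any named list
#'   of equal-sized matrices.
#' @param sigmas Non-negative kernel widths, one per plane (recycled if
#'   length 1). For a full six-plane stack the order is L*, a*, b*, H, S, V.
#' @return The smoothed stack, same structure as the input.
#' @export
gaussian_smooth <- function(stack, sigmas) {
  nm <- intersect(plane_names, names(stack))
  sigmas <- rep_len(sigmas, length(nm))
  if (any(!is.finite(sigmas)) || any(sigmas < 0))
    stop("gaussian_smooth: sigmas must be finite and >= 0")
  for (i in seq_along(nm)) stack[[nm[i]]] <- smooth_matrix(stack[[nm[i]]],
                                                           sigmas[i])
  stack
}

#' Read an expert demarcation-line annotation
#'
#' Two dialects: `"mask"` -- an image whose nonzero pixels mark the DL;
#' `"coords"` -- a CSV with header `row,col` of 0-based pixel coordinates,
#' whose frame size must be supplied via `height`/`width`.
#'
#' @param path Path to the annotation file.
#' @param dialect `"mask"` or `"coords"`.
#' @param height,width Frame size in pixels, required for the coordinate
#'   dialect.
#' @return A logical `h x w` matrix (class `"annotation_mask"`) with at
#'   least one `TRUE` pixel.
#' @export
read_annotation <- function(path, dialect = c("mask", "coords"),
                            height = NULL, width = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "mask") {
    img <- read_image(path)
    mask <- img[, , 1] > 0 | img[, , 2] > 0 | img[, , 3] > 0
  } else {
    if (is.null(height) || is.null(width))
      stop("read_annotation: coordinate dialect needs height and width")
    co <- utils::read.csv(path)
    if (!all(c("row", "col") %in% names(co)))
      stop("read_annotation: coordinate CSV must have columns row,col")
    mask <- pixels_to_mask(cbind(row = co$row, col = co$col),
                           c(height, width))
  }
  if (!any(mask)) stop("read_annotation: annotation contains no DL pixels")
  structure(mask, class = c("annotation_mask", class(mask)))
}

#' Convert a binary mask to a 0-based pixel coordinate set
#'
#' @param mask A logical matrix.
#' @return An integer matrix with columns `row`, `col` (0-based), ordered
#'   row-major (top-to-bottom, then left-to-right).
#' @export
mask_to_pixels <- function(mask) {
  idx <- which(unclass(mask), arr.ind = TRUE)
  px <- cbind(row = idx[, 1] - 1L, col = idx[, 2] - 1L)
  px[order(px[, 1], px[, 2]), , drop = FALSE]
}

#' Convert a 0-based pixel coordinate set to a binary mask
#'
#' @param pixels An integer matrix with columns `row`, `col` (0-based).
#' @param dim Frame size `c(height, width)`.
#' @return A logical `h x w` matrix.
#' @export
pixels_to_mask <- function(pixels, dim) {
  pixels <- as.matrix(pixels)
  bad <- pixels[, 1] < 0 | pixels[, 1] >= dim[1] |
         pixels[, 2] < 0 | pixels[, 2] >= dim[2]
  if (any(bad))
    stop("pixels_to_mask: out-of-range coordinates at rows ",
         paste(utils::head(which(bad), 10), collapse = ", "))
  mask <- matrix(FALSE, dim[1], dim[2])
  mask[cbind(pixels[, 1] + 1L, pixels[, 2] + 1L)] <- TRUE
  mask
}
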