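#' Full pipeline configuration
#'
#' Bundles every tunable of the four pipeline stages. The defaults are the
#' study conditions: 100 superpixels, compactness 5, sigma 5 per L*a*b*
#' plane, 300 k-means iterations, k-means++ seeding, 10 trials per k,
#' sweep k = 2..6, canonical evaluation frame 564 x 515.
#'
#' @param slic A [slic_params()].
#' @param scheme A [quantization_scheme()].
#' @param kmeans A [kmeans_params()].
#' @param ks Cluster-count sweep (strictly increasing).
#' @param canonical A [canonical_size()].
#' @param overlay_color RGB 0--255 used to draw candidates.
#' @param zscore Z-score features before clustering (off by default; the
#'   12 features go to k-means unscaled).
#' @param seed Base seed; overrides `kmeans$seed`.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(slic = slic_params(),
                            scheme = quantization_scheme(),
                            kmeans = kmeans_params(),
                            ks = 2:6,
                            canonical = canonical_size(),
                            overlay_color = c(0L, 255L, 0L),
                            zscore = FALSE,
                            seed = 1L) {
  ks <- as.integer(ks)
  stopifnot(length(ks) >= 1, all(diff(ks) > 0), all(ks >= 2))
  kmeans$seed <- as.integer(seed)
  structure(list(slic = slic, scheme = scheme, kmeans = kmeans, ks = ks,
                 canonical = canonical,
                 overlay_color = as.integer(overlay_color),
                 zscore = isTRUE(zscore), seed = as.integer(seed)),
            class = "pipeline_config")
}

# recursively drop S3 classes so configs serialize as plain lists
strip_s3 <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_s3)
    attributes(x) <- list(names = names(x))
    x
  } else unclass(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' Serialization round-trips losslessly through [pipeline_config()].
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return For `write_config`, `path` invisibly; for `read_config`, the
#'   configuration.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(strip_s3(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    slic = do.call(slic_params, y$slic[c("n_segments", "compactness",
                                         "sigmas", "max_iters",
                                         "enforce_connectivity")]),
    scheme = quantization_scheme(y$scheme$n_levels),
    kmeans = do.call(kmeans_params, y$kmeans[c("k", "max_iters", "n_trials",
                                               "seed", "tol")]),
    ks = y$ks,
    canonical = canonical_size(width = y$canonical$width,
                               height = y$canonical$height),
    overlay_color = y$overlay_color, zscore = y$zscore, seed = y$seed)
}

#' Run the DL-candidate pipeline on one image
#'
#' Executes the four stages -- superpixel segmentation, feature extraction,
#' k-means sweep, boundary extraction -- and (optionally) writes per-k
#' overlay PNGs, boundary CSVs, cluster label maps, cluster-model JSONs and
#' a run manifest that makes the run bit-reproducible. A k whose clustering
#' is constant is recorded as "no boundary at this k" and does not stop the
#' run.
#'
#' @param image An [rgb_image()] array, a `synthetic_sample`, or a path to
#'   a PNG/TIFF/JPEG file.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; `NULL` skips all disk artifacts.
#' @return The `candidate_sweep`, invisibly, with the `superpixel_map` in
#'   attribute `superpixels`.
#' @export
run_pipeline <- function(image, config = pipeline_config(), out_dir = NULL) {
  t0 <- Sys.time()
  if (is.character(image)) image <- read_image(image)
  if (inherits(image, "synthetic_sample")) image <- image$image
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) unlink(out_dir, recursive = TRUE)
      stop("run_pipeline [", name, "]: ", conditionMessage(e), call. = FALSE)
    })
  }
  stack <- stage("color conversion", rgb_to_planes(image))
  sp <- stage("superpixel segmentation", slic_segment(stack, config$slic))
  feats <- stage("feature extraction",
                 compute_features(stack, sp, config$scheme,
                                  zscore = config$zscore))
  sweep <- stage("clustering sweep",
                 run_sweep(feats, sp, ks = config$ks, params = config$kmeans))
  attr(sweep, "superpixels") <- sp

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_label_map(sp, file.path(out_dir, "superpixels.csv"))
    write_features(feats, file.path(out_dir, "features.csv"))
    models <- attr(sweep, "models")
    limgs <- attr(sweep, "label_images")
    for (nm in names(sweep)) {
      write_boundary_csv(sweep[[nm]],
                         file.path(out_dir, paste0("boundary_", nm, ".csv")))
      write_label_map(limgs[[nm]],
                      file.path(out_dir, paste0("clusters_", nm, ".csv")))
      write_cluster_model(models[[nm]],
                          file.path(out_dir, paste0("model_", nm, ".json")))
      write_image(overlay_boundary(image, sweep[[nm]], config$overlay_color),
                  file.path(out_dir, paste0("overlay_", nm, ".png")))
    }
    empty_ks <- attr(sweep, "ks")[vapply(sweep, function(b)
      nrow(b$pixels) == 0L, logical(1))]
    manifest <- list(
      package_version = as.character(utils::packageVersion("demarcate")),
      config = strip_s3(config),
      image_dim = dim(image)[1:2],
      n_superpixels = sp$n_superpixels,
      inertia = lapply(models, `[[`, "inertia"),
      no_boundary_at = as.list(empty_ks),
      elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(sweep)
}

#' Score DL candidates against a reference annotation
#'
#' Resamples the reference mask and each k's cluster label image to the
#' canonical frame, re-extracts boundaries there, and computes the
#' nearest-pixel distance from the reference DL to each candidate.
#'
#' @param reference An annotation mask (logical matrix or
#'   [read_annotation()] result) or a path to a mask image.
#' @param candidates A `candidate_sweep` from [run_pipeline()], or the
#'   pipeline output directory containing `clusters_k*.csv`.
#' @param config A [pipeline_config()] (for the canonical frame).
#' @param case,image Identifiers recorded in the result table.
#' @return A data frame with columns `case`, `image`, `k`, `distance`
#'   (pixels at canonical scale; `NA` where a k had no boundary).
#' @export
run_eval <- function(reference, candidates, config = pipeline_config(),
                     case = "case", image = "image") {
  if (is.character(reference)) reference <- read_annotation(reference)
  if (!any(reference)) stop("run_eval: empty reference DL")
  ref_canon <- resize_to_canonical(unclass(reference), config$canonical)
  ref_px <- mask_to_pixels(ref_canon)

  if (is.character(candidates)) {
    files <- sort(list.files(candidates, pattern = "^clusters_k[0-9]+\\.csv$",
                             full.names = TRUE))
    if (!length(files)) stop("run_eval: no cluster label maps in ", candidates)
    ks <- as.integer(sub(".*clusters_k([0-9]+)\\.csv$", "\\1", files))
    limgs <- lapply(files, read_label_map)
    ord <- order(ks); ks <- ks[ord]; limgs <- limgs[ord]
  } else {
    ks <- attr(candidates, "ks")
    limgs <- attr(candidates, "label_images")
  }
  dists <- vapply(limgs, function(li) {
    li_canon <- resize_to_canonical(li, config$canonical)
    bs <- extract_boundaries(li_canon)
    if (!nrow(bs$pixels)) return(NA_real_)
    dl_distance(ref_px, bs$pixels, dim = c(nrow(li_canon), ncol(li_canon)))
  }, numeric(1))
  data.frame(case = case, image = image, k = ks, distance = unname(dists))
}
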