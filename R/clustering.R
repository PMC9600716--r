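#' k-means parameter set
#'
#' Defaults follow the study conditions: at most 300 Lloyd iterations per
#' run, 10 independent k-means++-seeded trials per k, keeping the
#' minimum-inertia solution.
#'
#' @param k Number of clusters (>= 2).
#' @param max_iters Iteration cap for a single run.
#' @param n_trials Independent restarts; the best (minimum-inertia) model
#'   is returned.
#' @param seed Base random seed; trial `t` is seeded deterministically from
#'   `(seed, t)` so the whole pipeline is reproducible.
#' @param tol Relative center-shift convergence tolerance.
#' @return A list of class `"kmeans_params"`.
#' @export
kmeans_params <- function(k = 2L, max_iters = 300L, n_trials = 10L,
                          seed = 1L, tol = 1e-4) {
  stopifnot(k >= 2, max_iters >= 1, n_trials >= 1, tol >= 0)
  structure(list(k = as.integer(k), max_iters = as.integer(max_iters),
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 tol = tol),
            class = "kmeans_params")
}

# run expr with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-trial seed below 2^31
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483647)
}

# squared Euclidean distances between rows of X (n x d) and C (k x d)
sqdist_to_centers <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), `+`) - 2 * X %*% t(C)
  pmax(d2, 0)
}

# k-means++ seeding: first center uniform, then each next center drawn with
# probability proportional to squared distance to the nearest chosen center
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L)) {
    if (sum(d2) <= 0) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[j + 1L, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j + 1L, ])^2))
  }
  centers
}

lloyd_run <- function(X, centers, max_iters, tol) {
  k <- nrow(centers)
  for (iter in seq_len(max_iters)) {
    d2 <- sqdist_to_centers(X, centers)
    assign <- max.col(-d2, ties.method = "first")
    new_centers <- centers
    cnt <- tabulate(assign, nbins = k)
    present <- cnt > 0
    sums <- rowsum(X, assign, reorder = TRUE)
    new_centers[sort(unique(assign)), ] <- sums / cnt[present]
    # empty-cluster repair: relocate to the point farthest from its center
    # (skipped when all points coincide with their centers -- a relocation
    # could not lower the already-zero inertia)
    for (j in which(!present)) {
      own <- d2[cbind(seq_len(nrow(X)), assign)]
      far <- which.max(own)
      if (own[far] <= 0) next
      new_centers[j, ] <- X[far, ]
      assign[far] <- j
      d2[far, ] <- Inf          # don't reuse the same point
    }
    shift <- sqrt(sum((new_centers - centers)^2))
    centers <- new_centers
    if (shift <= tol * sqrt(sum(centers^2) + 1e-12)) break
  }
  d2 <- sqdist_to_centers(X, centers)
  assign <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(nrow(X)), assign)])
  list(centers = centers, assignment = assign - 1L, inertia = inertia)
}

#' Cluster superpixel features by multi-trial k-means
#'
#' Runs `n_trials` independent k-means fits (k-means++ seeding, Lloyd
#' iterations until the relative center shift drops below `tol` or
#' `max_iters` is reached) and returns the model with the minimum inertia,
#' the sum of squared distances of rows to their assigned centers. Each
#' trial's RNG stream derives deterministically from `(seed, trial)`, so
#' results are reproducible; each superpixel is one unweighted sample.
#'
#' @param features Numeric matrix, one row per superpixel (e.g. from
#'   [compute_features()]).
#' @param params A [kmeans_params()] object.
#' @return A `cluster_model`: list with `centers` (`k x d`), `assignment`
#'   (0-based cluster index per row), `inertia`, `k`, `seed`.
#' @export
kmeans_fit <- function(features, params = kmeans_params()) {
  X <- as.matrix(features)
  if (params$k > nrow(X))
    stop("kmeans_fit: k exceeds the number of superpixels")
  if (any(!is.finite(X)))
    stop("kmeans_fit: features contain non-finite values")
  best <- NULL
  for (t in seq_len(params$n_trials)) {
    fit <- with_private_seed(derive_seed(params$seed, t), {
      init <- kmeanspp_init(X, params$k)
      lloyd_run(X, init, params$max_iters, params$tol)
    })
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  structure(list(centers = best$centers, assignment = best$assignment,
                 inertia = best$inertia, k = params$k, seed = params$seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster_model: k =", x$k, " inertia =", format(x$inertia),
      " (seed", x$seed, ")\n")
  invisible(x)
}

#' Project superpixel cluster assignments back to pixels
#'
#' @param sp A `superpixel_map`.
#' @param model A `cluster_model` whose assignment has one entry per
#'   superpixel.
#' @return An integer `h x w` matrix of 0-based cluster indices (a cluster
#'   label image).
#' @export
project_to_pixels <- function(sp, model) {
  if (length(model$assignment) != sp$n_superpixels)
    stop("project_to_pixels: assignment length (", length(model$assignment),
         ") != n_superpixels (", sp$n_superpixels, ")")
  matrix(model$assignment[sp$labels + 1L], sp$dim[1], sp$dim[2])
}

#' Export a cluster model as JSON
#'
#' @param model A `cluster_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_model <- function(model, path) {
  jsonlite::write_json(list(k = model$k, seed = model$seed,
                            inertia = model$inertia,
                            centers = model$centers,
                            assignment = model$assignment),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
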