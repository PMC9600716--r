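# In-code fixtures (no binary files): hand-built channel stacks and
# superpixel maps so features/clustering can be tested without running the
# earlier stages.

make_stack <- function(L, a = NULL, b = NULL, H = NULL, S = NULL, V = NULL) {
  z <- matrix(0, nrow(L), ncol(L))
  structure(list(L = L, a = if (is.null(a)) z else a,
                 b = if (is.null(b)) z else b,
                 H = if (is.null(H)) z else H,
                 S = if (is.null(S)) z else S,
                 V = if (is.null(V)) z else V,
                 dim = dim(L)),
            class = "channel_stack")
}

make_sp <- function(labels) {
  structure(list(labels = labels, n_superpixels = max(labels) + 1L,
                 dim = dim(labels)),
            class = "superpixel_map")
}

# two flat gray levels split at a column (0-based edge between col
# `split - 1` and `split`), as a channel stack
two_tone_stack <- function(h = 100, w = 100, split = 50, lo = 25, hi = 75) {
  L <- matrix(lo, h, w)
  L[, (split + 1):w] <- hi
  make_stack(L)
}

flat_rgb <- function(h, w, rgb = c(0L, 0L, 0L)) {
  rgb_image(array(rep(rgb, each = h * w), c(h, w, 3)))
}

# small random feature matrix with the bimodal group structure superpixel
# features of a two-region image exhibit: two Gaussian groups (each with at
# least two members, as real regions own many superpixels) separated along
# a random direction, padded to the 12 pipeline dimensions
random_cluster_fixture <- function(n = NULL) {
  if (is.null(n)) n <- sample(4:12, 1)
  d <- sample(2:4, 1)
  n1 <- sample(2:(n - 2L), 1)
  mu <- rnorm(d); mu <- 8 * mu / sqrt(sum(mu^2))
  X <- rbind(matrix(rnorm(n1 * d, 0, 1.5), n1, d),
             sweep(matrix(rnorm((n - n1) * d, 0, 1.5), n - n1, d), 2, mu, `+`))
  cbind(X, matrix(0, n, 12 - d))
}
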