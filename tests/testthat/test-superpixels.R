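# reusable segmentation of a flat 100x100 image into 4 target superpixels
flat_stack_100 <- make_stack(matrix(50, 100, 100))

test_that("flat image: one segment covers everything, four form quadrants", {
  sp1 <- slic_segment(flat_stack_100, slic_params(n_segments = 1, sigmas = 0))
  expect_equal(sp1$n_superpixels, 1L)
  expect_true(all(sp1$labels == 0L))

  # with 4 segments the partition approximates the grid quadrants: each
  # quadrant's majority label is unique (structure confirmed against a
  # reference SLIC implementation on the same input)
  sp4 <- slic_segment(flat_stack_100, slic_params(n_segments = 4, sigmas = 0))
  expect_equal(sp4$n_superpixels, 4L)
  quad_major <- sapply(list(1:50, 51:100), function(r)
    sapply(list(1:50, 51:100), function(c) {
      t <- table(sp4$labels[r, c]); as.integer(names(t)[which.max(t)])
    }))
  expect_equal(sort(as.vector(quad_major)), 0:3)

  expect_error(slic_segment(flat_stack_100, slic_params(n_segments = 1e6)),
               "area")
})

test_that("label maps are contiguous partitions of 4-connected regions", {
  set.seed(21)
  L <- matrix(runif(64 * 64, 20, 80), 64, 64)
  st <- make_stack(L)
  sp <- slic_segment(st, slic_params(n_segments = 16, sigmas = 1))
  # partition: every pixel exactly one label, labels contiguous from 0
  expect_equal(sort(unique(as.vector(sp$labels))),
               0:(sp$n_superpixels - 1L))
  expect_true(all(tabulate(sp$labels + 1L) >= 1L))
  # each label's pixel set is 4-connected
  comp <- demarcate:::connected_components(sp$labels)
  for (lb in unique(as.vector(sp$labels)))
    expect_equal(length(unique(comp[sp$labels == lb])), 1L)
  # determinism: bit-identical repeat
  expect_identical(slic_segment(st, slic_params(n_segments = 16, sigmas = 1)),
                   sp)
})

# majority-side disagreement on the two-tone fixture: pixels whose
# superpixel's majority lies on the other side of the color edge
edge_leak <- function(sp, split = 50) {
  side <- col(sp$labels) > split
  leak <- 0L
  for (lb in 0:(sp$n_superpixels - 1L)) {
    px_side <- side[sp$labels == lb]
    maj <- mean(px_side) >= 0.5
    leak <- leak + sum(px_side != maj)
  }
  leak
}

test_that("superpixels adhere to a strong color edge", {
  st <- two_tone_stack()   # Delta L* = 50 at column 50
  sp <- slic_segment(st, slic_params(n_segments = 4, compactness = 5,
                                     sigmas = 0))
  # no superpixel spans the edge by more than 2 pixels
  for (lb in 0:(sp$n_superpixels - 1L)) {
    cols <- col(sp$labels)[sp$labels == lb] - 1L   # 0-based
    expect_true(max(cols) <= 51 || min(cols) >= 48,
                label = sprintf("superpixel %d spans cols %d..%d",
                                lb, min(cols), max(cols)))
  }
})

test_that("lower compactness never worsens edge adherence", {
  st <- two_tone_stack()
  leaks <- sapply(c(1, 5, 20), function(m)
    edge_leak(slic_segment(st, slic_params(n_segments = 4, compactness = m,
                                           sigmas = 0))))
  expect_true(all(diff(leaks) >= 0))
})

test_that("label maps survive CSV, PNG and 16-bit TIFF export", {
  tmp <- withr::local_tempdir()
  sp <- slic_segment(flat_stack_100, slic_params(n_segments = 4, sigmas = 0))
  write_label_map(sp, file.path(tmp, "lab.csv"))
  expect_identical(read_label_map(file.path(tmp, "lab.csv")), sp$labels)
  write_label_map(sp, file.path(tmp, "lab.png"))
  expect_identical(read_label_map(file.path(tmp, "lab.png")), sp$labels)
  big <- matrix(sample(0:999, 600, TRUE), 20, 30)   # needs 16 bits
  write_label_map(big, file.path(tmp, "big.tif"))
  expect_identical(read_label_map(file.path(tmp, "big.tif")), big)
  expect_error(write_label_map(big, file.path(tmp, "big.png")), "256")
})
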