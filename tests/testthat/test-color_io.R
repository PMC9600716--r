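test_that("image files round-trip losslessly and degenerate inputs decode", {
  tmp <- withr::local_tempdir()

  black <- flat_rgb(2, 2, c(0L, 0L, 0L))
  write_image(black, file.path(tmp, "black.png"))
  expect_true(all(read_image(file.path(tmp, "black.png")) == 0L))

  white <- flat_rgb(2, 2, c(255L, 255L, 255L))
  write_image(white, file.path(tmp, "white.png"))
  expect_true(all(read_image(file.path(tmp, "white.png")) == 255L))

  set.seed(11)
  fix <- rgb_image(array(sample(0:255, 100 * 100 * 3, TRUE), c(100, 100, 3)))
  for (ext in c("png", "tif")) {
    p <- file.path(tmp, paste0("fix.", ext))
    write_image(fix, p)
    expect_identical(unclass(read_image(p)), unclass(fix))
  }
  # JPEG decodes to the right shape (lossy, so no pixel identity)
  write_image(fix, file.path(tmp, "fix.jpg"))
  expect_equal(dim(read_image(file.path(tmp, "fix.jpg"))), c(100L, 100L, 3L))

  expect_error(read_image(file.path(tmp, "nope.png")), "nope.png")
})

test_that("grayscale images replicate to 3 channels and alpha is dropped", {
  tmp <- withr::local_tempdir()
  png::writePNG(matrix(seq(0, 1, length.out = 12), 3, 4),
                file.path(tmp, "gray.png"))
  g <- read_image(file.path(tmp, "gray.png"))
  expect_equal(dim(g), c(3L, 4L, 3L))
  expect_identical(g[, , 1], g[, , 2])
  expect_identical(g[, , 1], g[, , 3])

  png::writePNG(array(0.5, c(3, 4, 4)), file.path(tmp, "alpha.png"))
  expect_warning(a <- read_image(file.path(tmp, "alpha.png")), "alpha")
  expect_equal(dim(a), c(3L, 4L, 3L))
})

test_that("rgb_to_planes matches the color-space definitions", {
  st_black <- rgb_to_planes(flat_rgb(2, 2, c(0L, 0L, 0L)))
  expect_equal(st_black$L[1, 1], 0)
  expect_equal(st_black$S[1, 1], 0)
  expect_equal(st_black$V[1, 1], 0)

  st_white <- rgb_to_planes(flat_rgb(2, 2, c(255L, 255L, 255L)))
  expect_equal(st_white$L[1, 1], 100, tolerance = 1e-6)
  expect_lt(abs(st_white$a[1, 1]), 0.5)
  expect_lt(abs(st_white$b[1, 1]), 0.5)
  expect_equal(st_white$S[1, 1], 0)
  expect_equal(st_white$V[1, 1], 100)

  # sRGB red against published D65 reference values (L*a*b* 53.24, 80.09,
  # 67.20), agreement within 0.5 per plane
  st_red <- rgb_to_planes(flat_rgb(2, 2, c(255L, 0L, 0L)))
  expect_equal(st_red$H[1, 1], 0)
  expect_equal(st_red$S[1, 1], 100)
  expect_equal(st_red$V[1, 1], 100)
  expect_lt(abs(st_red$L[1, 1] - 53.24), 0.5)
  expect_lt(abs(st_red$a[1, 1] - 80.09), 0.5)
  expect_lt(abs(st_red$b[1, 1] - 67.20), 0.5)

  # any gray: zero saturation, near-zero a*/b*; conversion is deterministic
  set.seed(3)
  gray_vals <- sample(0:255, 5)
  for (g in gray_vals) {
    st <- rgb_to_planes(flat_rgb(2, 2, c(g, g, g)))
    expect_equal(st$S[1, 1], 0)
    expect_lt(abs(st$a[1, 1]), 0.5)
    expect_lt(abs(st$b[1, 1]), 0.5)
  }
  img <- rgb_image(array(sample(0:255, 48, TRUE), c(4, 4, 3)))
  expect_identical(rgb_to_planes(img), rgb_to_planes(img))
})

test_that("gaussian_smooth: identity, constant, impulse peak, mean", {
  set.seed(7)
  plane <- matrix(runif(400, 0, 100), 20, 20)
  st <- make_stack(plane)

  expect_identical(gaussian_smooth(st, 0)$L, plane)
  const <- make_stack(matrix(42, 15, 15))
  expect_equal(gaussian_smooth(const, 3)$L, matrix(42, 15, 15))

  # unit impulse, sigma 2: center of the smoothed plane equals the 2-D
  # Gaussian peak 1 / (2 pi sigma^2)
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  sm <- gaussian_smooth(make_stack(imp), 2)$L
  expect_equal(sm[11, 11], 1 / (2 * pi * 4), tolerance = 1e-3)

  # reflective boundaries preserve the plane mean
  expect_equal(mean(gaussian_smooth(st, 3)$L), mean(plane),
               tolerance = 1e-6)
  expect_error(gaussian_smooth(st, -1), "sigma")
})

test_that("annotations read in both dialects and round-trip", {
  tmp <- withr::local_tempdir()
  mask <- matrix(FALSE, 5, 6)
  mask[cbind(c(1, 3, 5), c(2, 4, 6))] <- TRUE
  write_image(rgb_image(matrix(255L * mask, 5, 6)),
              file.path(tmp, "mask.png"))
  m <- read_annotation(file.path(tmp, "mask.png"), "mask")
  expect_equal(sum(m), 3)

  write.csv(data.frame(row = c(0L, 1L), col = c(0L, 1L)),
            file.path(tmp, "dl.csv"), row.names = FALSE)
  m2 <- read_annotation(file.path(tmp, "dl.csv"), "coords",
                        height = 2, width = 2)
  expect_identical(unclass(m2), matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))

  # mask -> coordinates -> mask is the identity
  px <- mask_to_pixels(m)
  expect_identical(pixels_to_mask(px, dim(m)), unclass(m))

  write_image(flat_rgb(4, 4, c(0L, 0L, 0L)), file.path(tmp, "empty.png"))
  expect_error(read_annotation(file.path(tmp, "empty.png")), "no DL")
  write.csv(data.frame(row = 9L, col = 0L), file.path(tmp, "oob.csv"),
            row.names = FALSE)
  expect_error(read_annotation(file.path(tmp, "oob.csv"), "coords",
                               height = 2, width = 2), "out-of-range")
})
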