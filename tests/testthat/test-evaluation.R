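test_that("canonical resize is nearest-neighbor and categorical", {
  m <- matrix(sample(0:3, 30, TRUE), 5, 6)
  expect_identical(resize_to_canonical(m, canonical_size(6, 5)), m)

  mask <- matrix(FALSE, 3, 3); mask[2, 2] <- TRUE
  up <- resize_to_canonical(mask, canonical_size(6, 6))
  # 2x upscale: the set pixel becomes exactly its 2x2 block
  expected <- matrix(FALSE, 6, 6); expected[3:4, 3:4] <- TRUE
  expect_identical(up, expected)

  lab <- matrix(sample(0:9, 100, TRUE), 10, 10)
  down <- resize_to_canonical(lab, canonical_size(4, 4))
  expect_true(all(down %in% lab))

  sparse <- matrix(FALSE, 8, 8); sparse[1, 2] <- TRUE
  expect_warning(resize_to_canonical(sparse, canonical_size(2, 2)), "lost")
})

test_that("dl_distance reproduces hand-computed values", {
  px <- cbind(row = c(0L, 3L, 7L), col = c(0L, 4L, 2L))
  expect_equal(dl_distance(px, px, dim = c(10, 10)), 0)
  expect_equal(dl_distance(cbind(0L, 0L), cbind(3L, 4L), dim = c(10, 10)), 5)
  # mean of 0 and 2
  expect_equal(dl_distance(cbind(c(0L, 0L), c(0L, 2L)), cbind(0L, 0L),
                           dim = c(5, 5)), 1)
  expect_error(dl_distance(px[0, ], px, dim = c(10, 10)), "empty reference")
  expect_error(dl_distance(px, px[0, ], dim = c(10, 10)), "no boundary")
})

test_that("the metric is directional and monotone in the candidate set", {
  # asymmetric fixture: a far-away candidate pixel is invisible from the
  # reference side but dominates the transposed call
  ref <- cbind(row = c(0L, 1L), col = c(0L, 0L))
  cand <- cbind(row = c(0L, 1L, 30L), col = c(0L, 0L, 30L))
  expect_equal(dl_distance(ref, cand, dim = c(40, 40)), 0)
  expect_gt(dl_distance(cand, ref, dim = c(40, 40)), 10)

  set.seed(29)
  for (i in 1:5) {
    ref <- random_pixel_set(30, 60, 60)
    cand <- random_pixel_set(20, 60, 60)
    extra <- random_pixel_set(15, 60, 60)
    d_small <- dl_distance(ref, cand, dim = c(60, 60))
    d_big <- dl_distance(ref, unique(rbind(cand, extra)), dim = c(60, 60))
    expect_lte(d_big, d_small + 1e-12)
  }
})

test_that("distance-transform metric equals the brute-force double loop", {
  set.seed(37)
  for (i in 1:20) {
    h <- sample(20:120, 1); w <- sample(20:120, 1)
    ref <- random_pixel_set(sample(10:60, 1), h, w)
    cand <- random_pixel_set(sample(10:60, 1), h, w)
    expect_equal(dl_distance(ref, cand, dim = c(h, w)),
                 brute_force_dl_distance(ref, cand), tolerance = 0)
  }
  # median and directed-Hausdorff summaries agree with direct computation
  ref <- random_pixel_set(25, 50, 50); cand <- random_pixel_set(25, 50, 50)
  dvec <- vapply(seq_len(nrow(ref)), function(i)
    min(sqrt((ref[i, 1] - cand[, 1])^2 + (ref[i, 2] - cand[, 2])^2)),
    numeric(1))
  expect_equal(dl_distance(ref, cand, dim = c(50, 50), summary = "median"),
               median(dvec))
  expect_equal(dl_distance(ref, cand, dim = c(50, 50), summary = "max"),
               max(dvec))
})

test_that("case aggregation reproduces hand and spreadsheet arithmetic", {
  one <- data.frame(case = "A", image = "i1", k = 2, distance = 4.2)
  agg1 <- aggregate_case(one)
  expect_equal(agg1$per_case$min, 4.2)
  expect_equal(agg1$per_case$avg, 4.2)
  expect_equal(agg1$per_case$max, 4.2)

  two <- data.frame(case = "A", image = c("i1", "i2"), k = 2,
                    distance = c(2, 4))
  agg2 <- aggregate_case(two)
  expect_equal(agg2$per_case[, c("min", "avg", "max")],
               data.frame(min = 2, avg = 3, max = 4))

  # 23 images x 5 k values: cross-check every summary independently
  set.seed(43)
  tab <- expand.grid(image = paste0("img", 1:23), k = 2:6)
  tab$case <- rep(paste0("C", rep(1:8, length.out = 23)), 5)
  tab$distance <- round(runif(nrow(tab), 1, 200), 2)
  agg <- aggregate_case(tab)
  by_k_oracle <- tapply(tab$distance, tab$k, mean)
  expect_equal(agg$by_k$mean_distance, unname(as.vector(by_k_oracle)))
  for (cs in unique(tab$case)) {
    sel <- tab$distance[tab$case == cs]
    pc <- agg$per_case[agg$per_case$case == cs, ]
    expect_equal(pc$min, min(sel))
    expect_equal(pc$avg, mean(sel))
    expect_equal(pc$max, max(sel))
  }
  # NA distances ("no boundary at this k") are dropped, not propagated
  tab$distance[1] <- NA
  expect_false(anyNA(aggregate_case(tab)$by_k$mean_distance))
})
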