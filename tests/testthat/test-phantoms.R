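test_that("rasterized disk area matches direct pixel-center enumeration", {
  spec <- phantom_spec(list(shape_disk(0.5, 0.5, 0.25, 1)), 128L)
  img <- rasterize(spec, 128L)
  # independent enumeration of pixel centers inside the disk
  xs <- (seq_len(128) - 0.5) / 128
  inside <- outer(xs, xs, function(y, x) (x - 0.5)^2 + (y - 0.5)^2 <= 0.25^2)
  expect_identical(sum(img > 0), sum(inside))
  expect_equal(sum(img > 0), pi * (0.25 * 128)^2, tolerance = 0.02)
  expect_true(all(img >= 0))
})

test_that("rasterize is deterministic and rejects out-of-FOV shapes", {
  spec <- circles_phantom()
  expect_identical(rasterize(spec, 128L), rasterize(spec, 128L))
  expect_error(phantom_spec(list(shape_disk(0.9, 0.5, 0.2, 1)), 64L),
               "outside")
  expect_identical(rasterize(phantom_spec(list(), 32L), 32L),
                   matrix(0, 32, 32))
})

test_that("downsum sums 2x2 blocks and conserves total activity", {
  expect_equal(downsum(matrix(c(1, 3, 2, 4), 2, 2)),
               matrix(10, 1, 1))
  expect_identical(downsum(matrix(0, 8, 8)), matrix(0, 4, 4))
  set.seed(3)
  x <- matrix(runif(16), 4, 4)
  expect_equal(sum(downsum(x)), sum(x))
  expect_error(downsum(matrix(0, 3, 4)), "even")
})

test_that("LR rasterization equals downsum(HR)/4 away from shape boundaries", {
  spec <- circles_phantom()
  lr <- rasterize(spec, 128L)
  hr <- rasterize(spec, 256L)
  ds <- downsum(hr) / 4
  # mismatches only where the HR 2x2 block is mixed (a shape boundary)
  mixed <- downsum((hr - ds[rep(1:128, each = 2), rep(1:128, each = 2)])^2) > 0
  diff <- abs(ds - lr) > 1e-12
  expect_true(all(!diff | mixed))
  expect_lt(mean(diff), 0.05)  # boundary pixels are a small fraction
})

test_that("circle phantom has a base disk with six contained hot ROIs", {
  spec <- circles_phantom()
  expect_gte(length(spec$shapes), 7L)
  base <- spec$shapes[[1]]
  for (sh in spec$shapes[-1]) {
    d <- sqrt((sh$cx - base$cx)^2 + (sh$cy - base$cy)^2)
    expect_lt(d + sh$r, base$r)       # fully inside the base disk
    expect_gt(sh$intensity, base$intensity)
  }
  rois <- circles_rois(128L)
  expect_named(rois$masks, paste0("R", 1:6))
  img <- rasterize(spec, 128L)
  for (msk in rois$masks) expect_true(all(img[msk] == 4))
  expect_true(all(img[rois$background] == 1))
  expect_gte(sum(rois$background), 16)
})

test_that("brain phantom supplies 10 regional ROIs, a CRC ROI and a background disk", {
  bp <- brain_phantom()
  expect_equal(dim(bp$image), c(128L, 128L))
  expect_true(all(bp$image >= 0))
  masks <- bp$rois$masks
  expect_setequal(names(masks), c(paste0("R", 1:10), "CRC"))
  # regional ROIs pairwise disjoint
  regional <- masks[paste0("R", 1:10)]
  for (i in seq_along(regional)) for (k in seq_len(i - 1))
    expect_false(any(regional[[i]] & regional[[k]]))
  # R1-R8 straddle edges, R9/R10 are monotonic, per design
  edge_counts <- vapply(regional, function(m)
    length(unique(bp$image[m])), integer(1))
  expect_true(all(edge_counts[1:8] >= 2))
  expect_true(all(edge_counts[9:10] == 1))
  # warm background disk is uniform activity and outside the brain
  expect_true(all(bp$image[bp$rois$background] == 1))
  expect_gte(sum(bp$rois$background), 16)
  # CRC ROI sits in gray matter (full contrast against the background disk)
  expect_true(all(bp$image[masks$CRC] == 4))
})

test_that("a user-supplied label image replaces the procedural slice", {
  lab <- matrix(2, 128, 128)
  bp <- brain_phantom(label_image = lab)
  expect_identical(bp$image, lab)
  expect_null(bp$spec)
  expect_error(brain_phantom(label_image = matrix(1, 64, 64)))
})
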