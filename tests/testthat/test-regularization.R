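test_that("psi approximates the absolute value with bounded curvature ratio", {
  eps <- 0.04
  expect_equal(psi(0, eps), sqrt(eps))
  expect_equal(omega(0, eps), 1 / sqrt(eps))
  expect_equal(psi(3, 1e-12), 3, tolerance = 1e-12)
  expect_equal(psi(-3, 1e-12), 3, tolerance = 1e-12)
  # omega decreasing in |xi|, bounded by 1/sqrt(eps), positive
  xi <- seq(-5, 5, by = 0.25)
  om <- omega(xi, eps)
  expect_true(all(om > 0 & om <= 1 / sqrt(eps)))
  expect_gt(omega(1, eps), omega(2, eps))
  # finite-difference check of the derivative
  h <- 1e-6
  fd <- (psi(xi + h, eps) - psi(xi - h, eps)) / (2 * h)
  expect_equal(psi_dot(xi, eps), fd, tolerance = 1e-6)
  # convexity via the midpoint inequality on random pairs
  set.seed(1)
  x1 <- runif(200, -5, 5); x2 <- runif(200, -5, 5)
  expect_true(all(psi((x1 + x2) / 2, eps) <=
                  (psi(x1, eps) + psi(x2, eps)) / 2 + 1e-12))
})

test_that("patch differences match a brute-force double loop", {
  set.seed(2)
  f <- matrix(runif(25), 5, 5)
  brute <- function(j, jp, pr) {
    refl <- function(i) { i <- ifelse(i < 1, 1 - i, i); ifelse(i > 5, 11 - i, i) }
    acc <- 0
    for (dy in -pr:pr) for (dx in -pr:pr)
      acc <- acc + (f[refl(j[1] + dy), refl(j[2] + dx)] -
                    f[refl(jp[1] + dy), refl(jp[2] + dx)])^2
    acc
  }
  for (j in list(c(3, 3), c(1, 1), c(5, 2))) for (jp in list(c(2, 4), c(3, 3))) {
    expect_equal(patch_difference(f, j, jp, 1L), brute(j, jp, 1))
  }
  expect_equal(patch_difference(f, c(2, 2), c(2, 2)), 0)
  expect_equal(patch_difference(matrix(3, 5, 5), c(1, 2), c(4, 4)), 0)
})

test_that("similarity weights are row-stochastic and reduce to uniform when flat", {
  set.seed(4)
  f <- matrix(runif(64), 8, 8)
  w <- sdmr_weights(f, delta = 0.5)
  expect_true(all(w$W >= 0))
  expect_equal(rowSums(w$W), rep(1, 64))
  expect_equal(sdmr_weights(matrix(2, 8, 8))$W, uniform_weights(8)$W)
  expect_equal(sdmr_weights(f, delta = Inf)$W, uniform_weights(8)$W)
  u <- uniform_weights(8)
  expect_equal(rowSums(u$W), rep(1, 64))
  expect_true(all(u$W == 1 / 9))
})

test_that("interior similarity weights agree with the pairwise definition", {
  set.seed(6)
  f <- matrix(runif(100), 10, 10)
  delta <- 0.7
  w <- sdmr_weights(f, delta = delta)
  off <- w$offsets
  for (px in list(c(5, 5), c(4, 7))) {
    d <- vapply(seq_len(off$n), function(o)
      patch_difference(f, px, c(px[1] + off$dy[o], px[2] + off$dx[o]), 1L),
      numeric(1))
    wt <- exp(-d / delta^2)
    j <- (px[2] - 1) * 10 + px[1]
    expect_equal(as.numeric(w$W[j, ]), wt / sum(wt), tolerance = 1e-12)
  }
})

test_that("weights across a step edge favor same-side neighbors", {
  f <- cbind(matrix(0, 8, 4), matrix(5, 8, 4))
  w <- sdmr_weights(f, delta = 1)
  off <- w$offsets
  # pixel (4, 3): its flat-side neighbor has an identical patch, while the
  # neighbor toward the edge has a patch straddling the step
  j <- (3 - 1) * 8 + 4
  same_side <- which(off$dx == -1 & off$dy == 0)
  toward_edge <- which(off$dx == 1 & off$dy == 0)
  expect_gt(w$W[j, same_side], w$W[j, toward_edge])
})

test_that("mirroring the image mirrors the weight field", {
  set.seed(8)
  f <- matrix(runif(81), 9, 9)
  fm <- f[, 9:1]                      # mirror columns
  w <- sdmr_weights(f, delta = 0.4)
  wm <- sdmr_weights(fm, delta = 0.4)
  off <- w$offsets
  for (px in list(c(5, 3), c(2, 8))) {
    j <- (px[2] - 1) * 9 + px[1]
    jm <- (9 - px[2]) * 9 + px[1]     # mirrored pixel
    for (o in seq_len(off$n)) {
      om <- which(off$dy == off$dy[o] & off$dx == -off$dx[o])
      expect_equal(w$W[j, o], wm$W[jm, om], tolerance = 1e-12)
    }
  }
})

test_that("the smoothed weighted median selects (weighted) medians", {
  expect_equal(smoothed_weighted_median(c(1, 2, 9), rep(1 / 3, 3)), 2,
               tolerance = 1e-3)
  expect_equal(smoothed_weighted_median(c(5, 1, 9), c(0.7, 0.15, 0.15)), 5,
               tolerance = 1e-3)
  expect_equal(smoothed_weighted_median(rep(4, 9), rep(1 / 9, 9)), 4)
  v <- c(0, 1, 2, 3, 10)
  m <- smoothed_weighted_median(v, rep(0.2, 5))
  expect_gte(m, min(v)); expect_lte(m, max(v))
})
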