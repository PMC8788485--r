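test_that("degenerate one-pixel, one-bin system gives unit weight", {
  sm <- system_matrix(pet_geometry(1L, 1L, pi, 1L), 1L)
  expect_equal(as.matrix(sm$H), matrix(1), ignore_attr = TRUE)
})

test_that("axis-aligned strips collect exact pixel areas", {
  # at angle 0 each pixel lies fully inside one unit-wide bin strip
  geom <- pet_geometry(4L, 1L, pi, 4L)
  sm <- system_matrix(geom, 4L)
  f <- matrix(0, 4, 4); f[2, 1] <- 1          # pixel in column 1
  g <- forward_project(sm, f)
  expect_equal(g[1], 1)                        # full pixel area in bin 1
  expect_equal(sum(g), 1)
  expect_equal(g[-1], rep(0, 3))
})

test_that("forward projection is linear with the stated totals", {
  fx <- toy_system32()
  expect_equal(forward_project(fx$sm, matrix(0, 32, 32)), rep(0, 32 * 32))
  f <- matrix(0, 32, 32); f[17, 13] <- 2
  j <- (13 - 1) * 32 + 17
  expect_equal(forward_project(fx$sm, f), 2 * as.numeric(fx$sm$H[, j]))
  expect_equal(sum(forward_project(fx$sm, fx$truth, r = 0.5)),
               sum(fx$sm$sens * as.vector(fx$truth)) + 0.5 * nrow(fx$sm$H))
  expect_error(forward_project(fx$sm, -fx$truth), "negative")
})

test_that("adjoint identity holds to near machine precision", {
  fx <- toy_system32()
  set.seed(5)
  for (rep in 1:3) {
    x <- runif(32 * 32)
    y <- runif(nrow(fx$sm$H))
    lhs <- sum(forward_project(fx$sm, x) * y)
    rhs <- sum(x * as.vector(back_project(fx$sm, y)))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("sensitivity is strictly positive over the reconstruction support", {
  fx <- toy_system32()
  expect_true(all(fx$sm$H@x >= 0))
  expect_true(all(fx$sm$sens > 0))
})

test_that("count scaling hits the target exactly and scales linearly", {
  fx <- toy_system32()
  f2 <- scale_to_counts(fx$truth, fx$sm, 5e5)
  expect_equal(sum(forward_project(fx$sm, f2)), 5e5, tolerance = 1e-10)
  cur <- sum(forward_project(fx$sm, fx$truth))
  expect_equal(scale_to_counts(fx$truth, fx$sm, cur), fx$truth)
  expect_equal(sum(forward_project(fx$sm, scale_to_counts(fx$truth, fx$sm, 2 * cur))),
               2 * cur, tolerance = 1e-10)
  expect_error(scale_to_counts(matrix(0, 32, 32), fx$sm, 100), "zero")
})

test_that("Poisson sampling is seeded, mean-faithful and integer", {
  geom <- pet_geometry(100L, 100L, pi, 100L)
  gbar <- rep(50, 100 * 100)
  s1 <- sample_poisson(gbar, geom, seed = 42)
  s2 <- sample_poisson(gbar, geom, seed = 42)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$seed, 42L)
  expect_true(all(s1$counts >= 0), all(s1$counts == round(s1$counts)))
  # CLT bound on the sample mean of 10,000 draws at mean 50
  expect_lt(abs(mean(s1$counts) - 50), 3 * sqrt(50 / 10000))
  expect_identical(sample_poisson(rep(0, 100 * 100), geom, seed = 1)$counts,
                   rep(0L, 100 * 100))
  expect_error(sample_poisson(rep(-1, 100 * 100), geom, seed = 1),
               "negative")
})

test_that("sampling leaves the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(sample_poisson(rep(5, 32 * 32), tiny_geom(32L), seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("angle subsets partition the sinogram into balanced interleaved groups", {
  geom <- tiny_geom(32L)
  subs <- angle_subsets(geom, 4L)
  expect_length(subs, 4L)
  expect_setequal(unlist(subs), seq_len(32 * 32))
  expect_equal(unique(lengths(subs)), 32L * 8L)
  # view t goes to subset (t mod L) + 1
  expect_true(all((subs[[2]] - 1) %/% 32 %% 4 == 1))
  expect_error(angle_subsets(geom, 64L))
})

test_that("grid sizes incompatible with the FOV are rejected", {
  geom <- tiny_geom(32L)
  expect_error(system_matrix(geom, 48L), "multiple")
  expect_s3_class(system_matrix(geom, 64L), "system_matrix")
})

test_that("consistent LR/HR image pairs project to nearly the same sinogram", {
  spec <- circles_phantom()
  geom <- tiny_geom(64L)
  sml <- system_matrix(geom, 64L)
  smh <- system_matrix(geom, 128L)
  gl <- forward_project(sml, rasterize(spec, 64L))
  gh <- forward_project(smh, rasterize(spec, 128L))
  # frozen threshold for this 64-pixel fixture (discretization-limited)
  expect_lt(sqrt(sum((gl - gh)^2) / sum(gl^2)), 0.03)
})
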