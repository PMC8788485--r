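test_that("complete-data accumulators agree with hand computation on a 2x2 system", {
  # two pixels, two bins: H = [[1, 0.5], [0, 0.5]]
  H <- Matrix::Matrix(matrix(c(1, 0, 0.5, 0.5), 2, 2), sparse = TRUE)
  f <- c(2, 4)
  g <- c(5, 3)
  gbar <- as.numeric(H %*% f)                      # (4, 2)
  # per-pixel sums over i of C_ij = g_i H_ij f_j / gbar_i
  expected <- c(5 * 1 * 2 / gbar[1],
                5 * 0.5 * 4 / gbar[1] + 3 * 0.5 * 4 / gbar[2])
  expect_equal(cosem_complete_data(f, H, g), expected)
  # exact data: accumulators redistribute exactly the observed counts
  expect_equal(sum(cosem_complete_data(f, H, gbar)), sum(gbar))
  # no counts, no complete data
  expect_equal(cosem_complete_data(f, H, c(0, 0)), c(0, 0))
  # observed counts on a vanishing mean projection is a model mismatch
  expect_error(cosem_complete_data(c(0, 0), H, g), "mismatch")
})

test_that("per-pixel quadratic update solves its equation and limits", {
  # hand-set coefficients a = 1, b = -3, c = -4 (csum = 4): root 4
  f <- medreg:::solve_pixel_quadratic(1, -3, 4)
  expect_equal(f, 4)
  expect_lt(abs(1 * f^2 + (-3) * f - 4), 1e-10)
  # c = 0 with b >= 0 gives 0
  expect_equal(medreg:::solve_pixel_quadratic(1, 2, 0), 0)
  # a -> 0 falls back to the EM limit csum / b, matching the quadratic root
  expect_equal(medreg:::solve_pixel_quadratic(0, 5, 10), 2)
  expect_equal(medreg:::solve_pixel_quadratic(1e-9, 5, 10),
               medreg:::solve_pixel_quadratic(0, 5, 10), tolerance = 1e-8)
  # vectorized, nonnegative
  set.seed(9)
  a <- runif(50); b <- runif(50, -2, 5); cs <- runif(50)
  out <- medreg:::solve_pixel_quadratic(a, b, cs)
  expect_true(all(out >= 0))
  expect_lt(max(abs(a * out^2 + b * out - cs)), 1e-9)
})

test_that("median-image sweeps stay in the local data range and fix constants", {
  G <- 8L
  f <- matrix(3, G, G)
  w <- uniform_weights(G)
  m0 <- as.vector(matrix(runif(G * G), G, G))
  m1 <- medreg:::m_sweep_cpp(as.vector(f), m0, w$W, w$offsets$dy,
                             w$offsets$dx, G, 1e-8)
  expect_equal(m1, rep(3, G * G))        # constant image: fixed in one sweep
  set.seed(10)
  f2 <- matrix(runif(G * G), G, G)
  m <- as.vector(f2)
  for (q in 1:5)
    m <- medreg:::m_sweep_cpp(as.vector(f2), m, w$W, w$offsets$dy,
                              w$offsets$dx, G, 1e-8)
  expect_true(all(m >= min(f2) - 1e-12 & m <= max(f2) + 1e-12))
})

test_that("without a penalty the optimizer is exactly MLEM (L = 1)", {
  fx <- toy_system32()
  cfg <- recon_config("ml", n_iterations = 8L, n_subsets = 1L)
  rec <- reconstruct(fx$sino, fx$sm, cfg)
  ref <- mlem_reference(fx$sino, fx$sm, 8L)
  expect_equal(as.vector(rec$f), ref, tolerance = 1e-12)
})

test_that("EM mass conservation holds after every full iteration", {
  fx <- toy_system32()
  for (n in c(1L, 3L)) {
    rec <- reconstruct(fx$sino, fx$sm,
                       recon_config("ml", n_iterations = n, n_subsets = 1L))
    expect_equal(sum(fx$sm$sens * as.vector(rec$f)), sum(fx$sino$counts),
                 tolerance = 1e-10)
  }
})

test_that("noiseless data reproduce a uniform disk under plain EM", {
  geom <- tiny_geom(32L)
  sm <- system_matrix(geom, 32L)
  truth <- rasterize(phantom_spec(list(shape_disk(0.5, 0.5, 0.3, 2)), 32L), 32L)
  gbar <- forward_project(sm, truth)
  sino <- structure(list(counts = gbar, geom = geom, r = 0, seed = 0L),
                    class = "sinogram")   # exact means as data
  rec <- reconstruct(sino, sm, recon_config("ml", n_iterations = 300L,
                                            n_subsets = 4L,
                                            objective_every = 0L))
  inner <- rasterize(phantom_spec(list(shape_disk(0.5, 0.5, 0.25, 1)), 32L),
                     32L) > 0
  expect_equal(mean(abs(rec$f[inner] - 2)), 0, tolerance = 0.05)
  expect_true(all(rec$f >= 0))
})

test_that("the penalized objective decreases and reconstruction is deterministic", {
  fx <- toy_system32()
  cfg <- recon_config("sdmr", beta = 0.3, n_iterations = 10L, n_subsets = 2L,
                      objective_every = 1L)
  r1 <- reconstruct(fx$sino, fx$sm, cfg)
  r2 <- reconstruct(fx$sino, fx$sm, cfg)
  expect_identical(r1$f, r2$f)
  expect_identical(r1$m, r2$m)
  expect_true(all(r1$f >= 0) && all(r1$m >= 0))
  obj <- r1$objective$objective
  expect_lt(obj[length(obj)], obj[1])
})

test_that("adaptive weights at infinite bandwidth replicate the uniform median", {
  fx <- toy_system32()
  a <- reconstruct(fx$sino, fx$sm,
                   recon_config("sdmr", beta = 0.4, delta = Inf,
                                n_iterations = 6L, n_subsets = 2L))
  b <- reconstruct(fx$sino, fx$sm,
                   recon_config("nwmr", beta = 0.4,
                                n_iterations = 6L, n_subsets = 2L))
  expect_identical(a$f, b$f)
  expect_identical(a$m, b$m)
})

test_that("single-precision operator path tracks the double-precision result", {
  fx <- toy_system32()
  cfg_d <- recon_config("sdmr", beta = 0.3, n_iterations = 10L,
                        n_subsets = 2L, precision = "double")
  cfg_s <- recon_config("sdmr", beta = 0.3, n_iterations = 10L,
                        n_subsets = 2L, precision = "single")
  rd <- reconstruct(fx$sino, fx$sm, cfg_d)
  rs <- reconstruct(fx$sino, fx$sm, cfg_s)
  expect_equal(rs$f, rd$f, tolerance = 1e-4)
})

test_that("super-resolution reconstruction runs on the finer grid", {
  fx <- toy_system32()
  smh <- system_matrix(fx$geom, 64L)
  rec <- reconstruct(fx$sino, smh,
                     recon_config("sdmr", beta = 0.3, n_iterations = 5L,
                                  n_subsets = 2L, sr_factor = 2L))
  expect_equal(dim(rec$f), c(64L, 64L))
  expect_true(all(is.finite(rec$f)))
})

test_that("geometry mismatches and bad initializations are rejected", {
  fx <- toy_system32()
  other <- system_matrix(tiny_geom(16L), 16L)
  expect_error(reconstruct(fx$sino, other, recon_config("ml")), "geometr")
  expect_error(reconstruct(fx$sino, fx$sm,
                           recon_config("ml", n_iterations = 1L,
                                        f0 = matrix(-1, 32, 32))),
               "negative")
})
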