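test_that("mean percentage error follows its definition", {
  truth <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(mpe(truth, truth), 0)
  expect_equal(mpe(2 * truth, truth), 100)
  # two hand-built trials
  f1 <- truth + matrix(c(1, 0, 0, 0), 2, 2)
  f2 <- truth - matrix(c(0, 0, 0, 2), 2, 2)
  hand <- mean(c(sqrt(1 / 30), sqrt(4 / 30))) * 100
  expect_equal(mpe(list(f1, f2), truth), hand)
  # scale covariance
  expect_equal(mpe(list(3 * f1, 3 * f2), 3 * truth), hand)
  expect_error(mpe(truth, matrix(0, 2, 2)), "zero")
})

test_that("contrast recovery is 1 on truth, 0 without contrast, linear between", {
  truth <- matrix(1, 8, 8); roi <- matrix(FALSE, 8, 8); bg <- matrix(FALSE, 8, 8)
  roi[3:4, 3:4] <- TRUE; bg[6:8, 6:8] <- TRUE
  truth[roi] <- 4
  expect_equal(crc(truth, roi, bg, truth), 1)
  expect_equal(crc(matrix(1, 8, 8), roi, bg, truth), 0)
  half <- truth; half[roi] <- 2.5        # halfway between bg 1 and truth 4
  expect_equal(crc(half, roi, bg, truth), 0.5)
  expect_equal(mcrc(list(truth, half), roi, bg, truth), 0.75)
  bad <- truth; bad[bg] <- 0
  expect_error(crc(bad, roi, bg, truth), "background")
})

test_that("image quality metrics hit their closed-form anchors", {
  set.seed(12)
  truth <- matrix(runif(64 * 64, 0.5, 2), 64, 64)
  same <- image_quality(truth, truth)
  expect_equal(same$MSSIM, 1)
  expect_equal(same$MAE, 0)
  expect_equal(same$RMSE, 0)
  expect_equal(same$PSNR, 99)
  expect_equal(same$VIF, 1, tolerance = 1e-6)
  # normalized RMSE of 0.1 gives 20 dB by construction
  truth2 <- matrix(1, 32, 32)
  rec2 <- truth2 + 0.1
  iq <- image_quality(rec2, truth2)
  expect_equal(iq$RMSE, 0.1)
  expect_equal(iq$PSNR, 20)
  expect_equal(iq$PSNR, 20 * log10(1 / iq$RMSE))
  # MAE is the plain mean absolute difference on the activity scale
  a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8) + 0.5
  expect_equal(image_quality(b, a)$MAE, mean(abs(b - a)))
  expect_error(image_quality(matrix(0, 4, 4), matrix(1, 5, 5)))
})

test_that("degrading an image lowers MSSIM and VIF", {
  truth <- rasterize(circles_phantom(), 128L)
  set.seed(13)
  noisy <- pmax(truth + matrix(rnorm(128^2, 0, 0.4), 128, 128), 0)
  iq <- image_quality(noisy, truth)
  expect_lt(iq$MSSIM, 0.9)
  expect_lt(iq$VIF, 0.9)
  expect_gt(iq$MSSIM, 0)
  expect_gt(iq$VIF, 0)
})

test_that("background noise is the masked standard deviation with a size guard", {
  img <- matrix(1, 10, 10)
  mask <- matrix(TRUE, 10, 10)
  expect_equal(background_noise(img, mask), 0)
  set.seed(14)
  img2 <- matrix(rnorm(100, 5, 0.3), 10, 10)
  expect_equal(background_noise(img2, mask), sd(img2))
  small <- matrix(FALSE, 10, 10); small[1:3, 1] <- TRUE
  expect_error(background_noise(img, small), "16")
})

test_that("background noise decreases with beta and matching finds the target", {
  fx <- toy_system64()
  rois <- circles_rois(64L)
  cfg <- recon_config("nwmr", n_iterations = 40L, n_subsets = 4L)
  noise <- vapply(c(0.02, 0.2, 2), function(b) {
    cfg$beta <- b
    background_noise(reconstruct(fx$sino, fx$sm, cfg)$f, rois$background)
  }, numeric(1))
  expect_true(all(diff(noise) < 0))
  target <- mean(noise[1:2])
  mb <- match_beta(fx$sino, fx$sm, cfg, rois$background, target,
                   log10_range = c(-2, 1), n_evals = 5L)
  expect_lt(abs(mb$achieved_noise - target) / target, 0.5)
  expect_true(mb$beta >= 0.01 && mb$beta <= 10)
  # an essentially noise-free target cannot be reached below the grid floor:
  # the largest smoothing wins; a huge target returns the smallest beta
  mb2 <- match_beta(fx$sino, fx$sm, cfg, rois$background, 10,
                    log10_range = c(-2, 1), n_evals = 3L)
  expect_equal(mb2$beta, 0.01)
})

test_that("line profiles slice rows and columns with resolution-scaled length", {
  img <- matrix(seq_len(36), 6, 6)
  expect_equal(line_profile(img, 2, "row")$value, img[2, ])
  expect_equal(line_profile(img, 5, "col")$value, img[, 5])
  expect_equal(line_profile(matrix(7, 4, 4), 1, "row")$value, rep(7, 4))
  expect_error(line_profile(img, 9, "row"), "outside")
  lr <- line_profile(matrix(0, 64, 64), 32, "row")
  hr <- line_profile(matrix(0, 128, 128), 64, "row")
  expect_equal(nrow(hr), 2 * nrow(lr))
})
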