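as_ensemble <- function(x) {
  if (is.matrix(x)) list(x)
  else if (is.list(x)) lapply(x, function(e) if (inherits(e, "pet_recon")) e$f else e)
  else stop("ensemble must be a matrix or a list of matrices/pet_recon")
}

#' Mean percentage error over noise trials
#'
#' For each trial `k`, the normalized L2 error
#' `sqrt(sum((fhat_k - f)^2) / sum(f^2))` as a percentage, averaged over
#' the `K` trials. Scale-covariant: scaling reconstructions and truth
#' together leaves it unchanged. Reconstructions are compared against the
#' truth on their own grid (HR reconstructions against the HR phantom).
#'
#' @param ensemble a matrix, a list of image matrices, or a list of
#'   `pet_recon` objects (all on the truth's grid).
#' @param truth ground-truth activity image.
#' @return MPE in percent.
#' @export
mpe <- function(ensemble, truth) {
  ens <- as_ensemble(ensemble)
  denom <- sum(truth^2)
  if (denom <= 0) stop("zero truth image")
  pe <- vapply(ens, function(fh) {
    stopifnot(all(dim(fh) == dim(truth)))
    sqrt(sum((fh - truth)^2) / denom) * 100
  }, numeric(1))
  mean(pe)
}

#' Contrast recovery coefficient
#'
#' `CR = |mean(recon[roi]) - mean(recon[bg])| / mean(recon[bg])`,
#' normalized by the same contrast computed on the truth, so the truth
#' itself scores exactly 1 and a contrast-free reconstruction scores 0.
#' `mcrc()` averages the CRC over an ensemble of noise trials.
#'
#' @param recon reconstructed activity image.
#' @param roi,bg logical masks on the same grid (nonempty; background
#'   mean must be positive).
#' @param truth ground-truth image on the same grid.
#' @return scalar CRC (or mean CRC).
#' @export
crc <- function(recon, roi, bg, truth) {
  stopifnot(any(roi), any(bg), all(dim(recon) == dim(truth)))
  contrast <- function(img) {
    mb <- mean(img[bg])
    if (mb <= 0) stop("nonpositive background mean")
    abs(mean(img[roi]) - mb) / mb
  }
  cr0 <- contrast(truth)
  if (cr0 <= 0) stop("truth has no ROI/background contrast")
  contrast(recon) / cr0
}

#' @rdname crc
#' @param ensemble as in [mpe()].
#' @export
mcrc <- function(ensemble, roi, bg, truth) {
  mean(vapply(as_ensemble(ensemble), crc, numeric(1),
              roi = roi, bg = bg, truth = truth))
}

gauss_kernel <- function(n, sigma) {
  x <- seq(-(n - 1) / 2, (n - 1) / 2)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# mean SSIM, 11x11 Gaussian window sd 1.5, standard constants, dynamic
# range 1 (inputs already normalized), valid-region convolution
mssim_index <- function(x, y, n = 11L, sigma = 1.5) {
  n <- min(n, nrow(x), ncol(x))     # shrink the window for tiny images
  if (n %% 2L == 0L) n <- n - 1L
  k <- gauss_kernel(n, sigma)
  C1 <- 0.01^2; C2 <- 0.03^2
  mu1 <- sepconv_valid_cpp(x, k); mu2 <- sepconv_valid_cpp(y, k)
  s11 <- sepconv_valid_cpp(x * x, k) - mu1^2
  s22 <- sepconv_valid_cpp(y * y, k) - mu2^2
  s12 <- sepconv_valid_cpp(x * y, k) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

# pixel-domain visual information fidelity (VIFP), 4 scales, variance
# floor 1e-10, noise variance 2 on a 0-255 intensity scale
vifp_index <- function(ref, dist, sigma_nsq = 2) {
  num <- 0; den <- 0
  for (scale in 1:4) {
    N <- 2^(4 - scale + 1) + 1
    k <- gauss_kernel(N, N / 5)
    if (scale > 1) {
      if (min(dim(ref)) < 2 * N) break   # image exhausted at this scale
      ref <- sepconv_valid_cpp(ref, k)
      dist <- sepconv_valid_cpp(dist, k)
      ref <- ref[seq(1, nrow(ref), 2), seq(1, ncol(ref), 2), drop = FALSE]
      dist <- dist[seq(1, nrow(dist), 2), seq(1, ncol(dist), 2), drop = FALSE]
    }
    if (min(dim(ref)) <= N) break
    mu1 <- sepconv_valid_cpp(ref, k); mu2 <- sepconv_valid_cpp(dist, k)
    s1 <- pmax(sepconv_valid_cpp(ref * ref, k) - mu1^2, 0)
    s2 <- pmax(sepconv_valid_cpp(dist * dist, k) - mu2^2, 0)
    s12 <- sepconv_valid_cpp(ref * dist, k) - mu1 * mu2
    g <- s12 / (s1 + 1e-10)
    sv <- s2 - g * s12
    g[s1 < 1e-10] <- 0; sv[s1 < 1e-10] <- s2[s1 < 1e-10]
    s1[s1 < 1e-10] <- 0
    g[s2 < 1e-10] <- 0; sv[s2 < 1e-10] <- 0
    sv[g < 0] <- s2[g < 0]; g[g < 0] <- 0
    sv[sv <= 1e-10] <- 1e-10
    num <- num + sum(log10(1 + g^2 * s1 / (sv + sigma_nsq)))
    den <- den + sum(log10(1 + s1 / sigma_nsq))
  }
  num / den
}

#' Image quality metrics against a reference
#'
#' MSSIM, PSNR, RMSE and VIF are computed after normalizing both images
#' by the truth's maximum (so RMSE is on a [0, 1] scale and
#' `PSNR = 20 log10(1 / RMSE)`, capped at 99 dB); MAE is on the raw
#' activity scale. VIF is the pixel-domain multi-scale formulation on a
#' 0-255 intensity range.
#'
#' @param recon reconstructed activity image.
#' @param truth reference image of the same size.
#' @return named list: `MSSIM`, `MAE`, `PSNR`, `RMSE`, `VIF`.
#' @export
image_quality <- function(recon, truth) {
  stopifnot(all(dim(recon) == dim(truth)))
  mx <- max(truth)
  if (mx <= 0) stop("zero truth image")
  rn <- recon / mx; tn <- truth / mx
  rmse <- sqrt(mean((rn - tn)^2))
  psnr <- if (rmse == 0) 99 else min(99, 20 * log10(1 / rmse))
  list(MSSIM = mssim_index(rn, tn),
       MAE = mean(abs(recon - truth)),
       PSNR = psnr,
       RMSE = rmse,
       VIF = vifp_index(tn * 255, rn * 255))
}

#' Background noise level
#'
#' Sample standard deviation of the reconstruction over a mask that is
#' flat in the truth; the study protocol matches smoothing parameters so
#' different methods reach the same background noise.
#'
#' @param recon activity image.
#' @param bg_mask logical mask with at least 16 pixels.
#' @return standard deviation (activity units).
#' @export
background_noise <- function(recon, bg_mask) {
  stopifnot(is.matrix(recon), is.logical(bg_mask),
            all(dim(recon) == dim(bg_mask)))
  if (sum(bg_mask) < 16) stop("background mask too small (< 16 pixels)")
  sd(recon[bg_mask])
}

#' Choose the smoothing parameter by background-noise matching
#'
#' Scans a log-spaced `beta` grid, reconstructing at each value and
#' measuring the background standard deviation. Background noise
#' decreases with `beta` until over-smoothing bias takes over (for the
#' diffusive quadratic penalty the curve can turn back up), so the scan
#' looks for the first downward crossing of `target_noise` and refines
#' the bracketing pair by repeated log-log interpolation (three further
#' reconstructions). Evaluations after the first
#' warm-start from the previous reconstruction with half the iterations
#' (the optimizer is convergent, so continuation from a neighboring
#' solution is close to a cold run). If the whole grid sits below
#' (above) the target, the smallest (closest) `beta` is returned.
#'
#' @param sino,sm data and system matrix as in [reconstruct()].
#' @param config a [recon_config()]; its `beta` is overridden.
#' @param bg_mask background mask on the reconstruction grid.
#' @param target_noise desired background standard deviation.
#' @param log10_range search interval for `log10(beta)`.
#' @param n_evals grid points scanned (>= 3; refinement adds up to three
#'   more reconstructions when a crossing is found).
#' @return list: `beta`, `achieved_noise`, `trace` (data frame of the
#'   evaluations).
#' @export
match_beta <- function(sino, sm, config, bg_mask, target_noise,
                       log10_range = c(-2, 3), n_evals = 7L) {
  stopifnot(n_evals >= 3L, target_noise >= 0)
  trace <- NULL
  flast <- NULL
  eval_noise <- function(lb, f0 = flast) {
    cfg <- config
    cfg$beta <- 10^lb
    if (!is.null(f0)) {
      # continuation from a smoother neighboring solution: relaxing
      # toward a weaker prior is well-behaved, unlike the reverse
      cfg$f0 <- f0
      cfg$n_iterations <- max(10L, config$n_iterations %/% 2L)
    }
    rec <- reconstruct(sino, sm, cfg)
    nz <- background_noise(rec$f, bg_mask)
    trace <<- rbind(trace, data.frame(log10_beta = lb, noise = nz))
    flast <<- rec$f
    nz
  }
  # scan from the smoothest end down: the cold start at the largest beta
  # is well-posed (the median prior holds the uniform initializer flat),
  # and every warm start is smoother than its successor's solution
  grid <- seq(log10_range[2], log10_range[1], length.out = n_evals)
  scan_imgs <- vector("list", n_evals)
  noise <- numeric(n_evals)
  for (i in seq_len(n_evals)) {
    noise[i] <- eval_noise(grid[i])
    scan_imgs[[i]] <- flast
  }
  if (all(noise <= target_noise)) {
    n <- length(grid)   # even the weakest smoothing is below target
    return(list(beta = 10^grid[n], achieved_noise = noise[n], trace = trace))
  }
  cross <- which(noise[-length(noise)] <= target_noise &
                 noise[-1] > target_noise)
  if (length(cross) == 0) {
    k <- which.min(abs(log(pmax(noise, 1e-12) / target_noise)))
    return(list(beta = 10^grid[k], achieved_noise = noise[k], trace = trace))
  }
  # take the noise-dominated crossing (smallest beta side) and refine it
  # by repeated log-log interpolation on the bracket
  k <- max(cross)
  smooth <- c(grid[k], max(noise[k], 1e-12))     # noise <= target
  rough <- c(grid[k + 1], noise[k + 1])          # noise > target
  fsmooth <- scan_imgs[[k]]
  pick <- smooth
  for (it in 1:3) {
    t <- (log(rough[2]) - log(target_noise)) /
         (log(rough[2]) - log(smooth[2]))
    lb <- rough[1] + max(0.05, min(0.95, t)) * (smooth[1] - rough[1])
    nz <- eval_noise(lb, f0 = fsmooth)
    if (abs(log(max(nz, 1e-12) / target_noise)) <
        abs(log(max(pick[2], 1e-12) / target_noise)))
      pick <- c(lb, nz)
    if (nz > target_noise) {
      rough <- c(lb, nz)
    } else {
      smooth <- c(lb, max(nz, 1e-12))
      fsmooth <- flast
    }
  }
  list(beta = 10^pick[1], achieved_noise = pick[2], trace = trace)
}

#' Extract a line profile
#'
#' Pixel values along one row or column, for profile plots through the
#' reconstruction. On a twice-finer grid the same relative position has
#' twice the samples.
#'
#' @param image activity image.
#' @param index 1-based row or column index.
#' @param orientation `"row"` traces along a row (varying column),
#'   `"col"` along a column.
#' @return data frame with `position` and `value`.
#' @export
line_profile <- function(image, index, orientation = c("row", "col")) {
  orientation <- match.arg(orientation)
  n <- if (orientation == "row") nrow(image) else ncol(image)
  if (index < 1 || index > n) stop("profile line outside the image")
  v <- if (orientation == "row") image[index, ] else image[, index]
  data.frame(position = seq_along(v), value = as.numeric(v))
}
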