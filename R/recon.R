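method_traits <- function(method) {
  switch(method,
    sdmr = list(weights = "sdmr", prior = "median", quad = FALSE),
    nwmr = list(weights = "uniform", prior = "median", quad = FALSE),
    lqr  = list(weights = "uniform", prior = "local", quad = TRUE),
    lnqr = list(weights = "uniform", prior = "local", quad = FALSE),
    nlr  = list(weights = "sdmr", prior = "local", quad = TRUE),
    ml   = list(weights = "none", prior = "none", quad = FALSE),
    stop("unknown method: ", method)
  )
}

#' Reconstruction run configuration
#'
#' Bundles the optimizer settings for [reconstruct()].
#'
#' `method` selects the regularizer: `"sdmr"` (similarity-driven median),
#' `"nwmr"` (non-weighted median), `"lqr"` (local quadratic), `"lnqr"`
#' (local non-quadratic, smoothed absolute), `"nlr"` (patch-weighted
#' quadratic), or `"ml"` (no penalty; plain COSEM, `beta` ignored).
#'
#' @param method regularizer name (see Details).
#' @param beta smoothing parameter (>= 0), in sensitivity-normalized
#'   units: the penalty enters the objective multiplied by
#'   `beta * mean(sensitivity)`, so the useful range of `beta` does not
#'   depend on the count level, the grid resolution or the projector
#'   normalization.
#' @param n_iterations number of full iterations `N`.
#' @param n_subsets number of ordered subsets `L`.
#' @param n_sub_iterations median-image fixed-point sweeps `Q` per
#'   iteration.
#' @param epsilon,delta,patch_radius,neighborhood_radius penalty
#'   parameters, see [penalty_params()]; `neighborhood_radius` defaults
#'   to 1 (a 3x3 window) except for `"nlr"`, whose search window defaults
#'   to 5x5 — a 3x3 window would leave the non-local comparator with no
#'   non-local reach.
#' @param sr_factor 1 reconstructs on the native LR grid, 2 on the twice
#'   finer super-resolution grid (used by the experiment drivers to select
#'   the system matrix).
#' @param weight_refresh when adaptive weights are refreshed:
#'   `"per_subset"` (before every subset's image update, the literal
#'   schedule), `"per_iteration"` (once per iteration, cheaper and nearly
#'   identical in practice) or `"fixed"` (frozen at the weights computed
#'   from `weights_image`).
#' @param weights_image image on which `"fixed"` weights are computed
#'   (default: the initializer).
#' @param f0 optional initial image; default is a uniform image matched to
#'   the observed counts.
#' @param objective_every record the penalized-likelihood objective every
#'   this many iterations (0 = never; tracking costs one extra forward
#'   projection per record).
#' @param precision arithmetic of the stored system-matrix copy used in
#'   the likelihood passes: `"double"` (reference) or `"single"` (half
#'   the memory traffic; system matrices are conventionally stored in
#'   single precision, and all accumulation stays in double).
#' @return object of class `recon_config`.
#' @export
recon_config <- function(method = "sdmr", beta = 0.2, n_iterations = 200L,
                         n_subsets = 4L, n_sub_iterations = 2L,
                         epsilon = NULL, delta = NULL, patch_radius = 1L,
                         neighborhood_radius = NULL, sr_factor = 1L,
                         weight_refresh = c("per_subset", "per_iteration",
                                            "fixed"),
                         weights_image = NULL, f0 = NULL,
                         objective_every = 0L,
                         precision = c("double", "single")) {
  method <- match.arg(method, c("sdmr", "nwmr", "lqr", "lnqr", "nlr", "ml"))
  weight_refresh <- match.arg(weight_refresh)
  precision <- match.arg(precision)
  if (is.null(neighborhood_radius))  # nlr needs genuinely non-local reach
    neighborhood_radius <- if (method == "nlr") 2L else 1L
  stopifnot(beta >= 0, n_iterations >= 1, n_subsets >= 1,
            n_sub_iterations >= 1, sr_factor %in% c(1L, 2L))
  structure(list(method = method, beta = beta,
                 n_iterations = as.integer(n_iterations),
                 n_subsets = as.integer(n_subsets),
                 n_sub_iterations = as.integer(n_sub_iterations),
                 epsilon = epsilon, delta = delta,
                 patch_radius = as.integer(patch_radius),
                 neighborhood_radius = as.integer(neighborhood_radius),
                 sr_factor = as.integer(sr_factor),
                 weight_refresh = weight_refresh,
                 weights_image = weights_image, f0 = f0,
                 objective_every = as.integer(objective_every),
                 precision = precision),
            class = "recon_config")
}

# weights for the configured method on the given image
make_weights <- function(fmat, config) {
  tr <- method_traits(config$method)
  if (tr$weights == "sdmr")
    sdmr_weights(fmat, delta = config$delta,
                 patch_radius = config$patch_radius,
                 neighborhood_radius = config$neighborhood_radius,
                 bandwidth = if (config$method == "nlr") "noise"
                             else "structure")
  else
    uniform_weights(nrow(fmat), config$neighborhood_radius)
}

#' Complete-data accumulator for one subset
#'
#' COSEM keeps, per subset `S_l`, the per-pixel sums of the complete data
#' `C_ij = g_i H_ij f_j / gbar_i` over `i` in `S_l`. This computes that
#' sum as a single back-projection of `g/gbar` over the subset rows, times
#' `f`. With exact data (`g = gbar`, `r = 0`) the accumulators sum back to
#' the subset counts.
#'
#' @param f current image vector (column-major).
#' @param H_l subset rows of the system matrix (`dgCMatrix`).
#' @param g_l,r_l subset counts and background means.
#' @return per-pixel accumulator vector `sum_{i in S_l} C_ij`.
#' @export
cosem_complete_data <- function(f, H_l, g_l, r_l = 0) {
  gbar <- as.numeric(H_l %*% f) + r_l
  bad <- g_l > 0 & gbar <= 1e-12 * max(gbar, 1)
  if (any(bad))
    stop("model mismatch: zero mean projection where counts were observed")
  y <- ifelse(g_l > 0, g_l / pmax(gbar, 1e-15), 0)
  f * as.numeric(Matrix::crossprod(H_l, y))
}

# stable nonnegative root of a f^2 + b f - csum = 0 (a >= 0, csum >= 0);
# a below threshold falls back to the EM limit csum / b
solve_pixel_quadratic <- function(a, b, csum, active = rep(TRUE, length(a))) {
  out <- quad_root_cpp(as.numeric(a), as.numeric(b), as.numeric(csum), active)
  if (out$status != 0)
    stop("degenerate update: vanishing curvature with negative slope")
  out$f
}

#' Penalized-likelihood objective
#'
#' `sum_i (gbar_i - g_i log gbar_i) + beta * R`, the Poisson negative
#' log-likelihood (constant `log g_i!` terms omitted) plus the penalty:
#' for the median methods `R = sum_j sum_{j' in N_j} w_jj' psi(f_j -
#' m_j')`, for the local methods the pairwise analogue on `f` itself.
#'
#' @param f image (matrix or vector) on the grid of `sm`.
#' @param m median image (ignored for non-median methods; may be `NULL`).
#' @param sino a `sinogram`.
#' @param sm the [system_matrix()] used for reconstruction.
#' @param weights a `weight_field` ([sdmr_weights()], [uniform_weights()]).
#' @param beta smoothing parameter.
#' @param epsilon smoothing constant of `psi`.
#' @param method regularizer name as in [recon_config()].
#' @return scalar objective value.
#' @export
pl_objective <- function(f, m, sino, sm, weights, beta, epsilon,
                         method = "sdmr") {
  tr <- method_traits(method)
  fv <- as_image_vector(f, sm$grid_size)
  g <- sino$counts
  gbar <- as.numeric(sm$H %*% fv) + sino$r
  if (any(g > 0 & gbar <= 0))
    stop("log of zero mean projection with positive counts")
  loglik_part <- sum(gbar) - sum(g[g > 0] * log(gbar[g > 0]))
  if (tr$prior == "none" || beta == 0) return(loglik_part)
  mv <- if (tr$prior == "median")
    as_image_vector(m, sm$grid_size) else fv
  R <- penalty_value_cpp(fv, mv, weights$W, weights$offsets$dy,
                         weights$offsets$dx, sm$grid_size, epsilon,
                         tr$quad, tr$prior == "local")
  # same sensitivity-normalized beta units as reconstruct()
  loglik_part + beta * mean(sm$sens[sm$sens > 0]) * R
}

#' Penalized-likelihood reconstruction with median regularization
#'
#' Runs the COSEM-based alternating optimizer: per iteration, each ordered
#' subset refreshes its complete-data accumulators and performs the
#' closed-form per-pixel quadratic image update (surrogate of the
#' penalized likelihood); for the median methods the auxiliary median
#' image is then refreshed by `Q` iteratively reweighted sweeps with
#' transposed weights, computed on the current image. Deterministic given
#' its inputs; every step preserves nonnegativity.
#'
#' Super-resolution reconstruction is simply this routine with a system
#' matrix on a finer grid than the detector sampling (same sinogram).
#'
#' @param sino a `sinogram` (see [sample_poisson()]).
#' @param sm a [system_matrix()] whose geometry matches the sinogram.
#' @param config a [recon_config()].
#' @return object of class `pet_recon`: `f` and `m` (matrices), the
#'   config, epsilon/delta actually used, and an `objective` data frame
#'   when tracking was enabled.
#' @export
reconstruct <- function(sino, sm, config = recon_config()) {
  stopifnot(inherits(sino, "sinogram"), inherits(sm, "system_matrix"),
            inherits(config, "recon_config"))
  if (!identical(unclass(sino$geom), unclass(sm$geom)))
    stop("sinogram and system matrix geometries differ")
  tr <- method_traits(config$method)
  G <- sm$grid_size
  J <- G * G
  g <- as.numeric(sino$counts)
  L <- config$n_subsets
  rows <- angle_subsets(sm$geom, L)
  single <- identical(config$precision, "single")
  csr <- csr_form(sm, if (single) "single" else "double")
  g_l <- lapply(rows, function(ix) g[ix])
  r_l <- lapply(rows, function(ix)
    if (length(sino$r) == 1L) rep(sino$r, length(ix)) else sino$r[ix])
  subset_pass <- function(fv, l) {
    out <- if (single)
      cosem_subset_pass_f2_cpp(csr, rows[[l]] - 1L, g_l[[l]], r_l[[l]], fv, J)
    else
      cosem_subset_pass_cpp(csr$rp, csr$cj, csr$vx, rows[[l]] - 1L,
                            g_l[[l]], r_l[[l]], fv, J)
    if (out$mismatch)
      stop("model mismatch: zero mean projection where counts were observed")
    fv * out$B
  }
  sens <- sm$sens
  active <- sens > 0

  if (is.null(config$f0)) {
    f <- numeric(J)
    f[active] <- sum(g) / sum(sens)
  } else {
    f <- as_image_vector(config$f0, G)
    if (any(f < 0)) stop("negative initial image")
    f[!active] <- 0
  }
  m <- f
  epsilon <- config$epsilon
  if (is.null(epsilon)) {
    # sqrt(epsilon) ~ 1% of the dynamic range (proxied by 4x the mean of
    # the count-matched uniform start): close enough to |.| to act as a
    # median penalty, large enough that the surrogate curvature
    # 1/sqrt(epsilon) does not stall the updates
    scale <- mean(f[active])
    epsilon <- max(1e-4 * (4 * scale)^2, 1e-300)
  }
  cfg <- config
  cfg$epsilon <- epsilon
  if (is.null(cfg$delta) && config$method != "nlr")
    # median-weight bandwidth: fixed per run, on the data activity scale
    # (nlr re-estimates its noise-scale bandwidth at each refresh)
    cfg$delta <- default_delta(4 * mean(f[active]), cfg$patch_radius)

  uses_adaptive <- tr$weights == "sdmr"
  # nlr: the noise-scale bandwidth must reflect the data noise, not the
  # state of the (possibly smoothed, possibly warm-started) iterate, so
  # it is estimated once from a short unregularized burn-in that always
  # starts from the count-matched uniform image, and frozen for the run
  if (config$method == "nlr" && is.null(cfg$delta)) {
    fb <- numeric(J)
    fb[active] <- sum(g) / sum(sens)
    Cb <- matrix(0, J, L)
    for (l in seq_len(L)) Cb[, l] <- subset_pass(fb, l)
    csb <- rowSums(Cb)
    for (n in 1:10) for (l in seq_len(L)) {
      Cn <- subset_pass(fb, l)
      csb <- csb - Cb[, l] + Cn
      Cb[, l] <- Cn
      fb <- ifelse(active, csb / pmax(sens, 1e-300), 0)
    }
    cfg$delta <- sdmr_weights(matrix(fb, G, G),
                              patch_radius = cfg$patch_radius,
                              neighborhood_radius = cfg$neighborhood_radius,
                              bandwidth = "noise")$delta
  }
  refresh_weights <- function(img) make_weights(img, cfg)
  W <- if (tr$prior == "none") NULL else {
    base_img <- if (config$weight_refresh == "fixed") {
      if (is.null(config$weights_image)) matrix(f, G, G)
      else config$weights_image
    } else matrix(f, G, G)
    refresh_weights(base_img)
  }

  # beta is specified in sensitivity-normalized units: the multiplier on
  # the penalty is beta * mean per-pixel sensitivity, which makes the
  # useful beta range independent of count level, grid resolution and
  # projector normalization
  beta_cfg <- if (tr$prior == "none") 0 else config$beta
  beta <- beta_cfg * mean(sens[active])
  # complete-data accumulators, initialized from the starting image
  C <- matrix(0, J, L)
  for (l in seq_len(L)) C[, l] <- subset_pass(f, l)
  csum <- rowSums(C)

  obj <- NULL
  track <- config$objective_every > 0L
  record <- function(iter, phase, Wcur) {
    val <- pl_objective(f, m, sino, sm, Wcur, beta_cfg, epsilon,
                        config$method)
    rbind(obj, data.frame(iteration = iter, phase = phase, objective = val))
  }
  if (track && !is.null(W)) obj <- record(0L, "init", W)

  for (n in seq_len(config$n_iterations)) {
    for (l in seq_len(L)) {
      if (!is.null(W) && uses_adaptive &&
          config$weight_refresh == "per_subset")
        W <- refresh_weights(matrix(f, G, G))
      C_new <- subset_pass(f, l)
      csum <- csum - C[, l] + C_new
      C[, l] <- C_new
      if (beta > 0) {
        pc <- if (W$kind == "uniform")
          prior_coeffs_u_cpp(f, m, 1 / W$offsets$n, W$offsets$dy,
                             W$offsets$dx, G, epsilon, tr$quad,
                             tr$prior == "local")
        else
          prior_coeffs_cpp(f, m, W$W, W$offsets$dy, W$offsets$dx, G,
                           epsilon, tr$quad, tr$prior == "local")
        a <- beta * pc$a
        b <- sens - beta * pc$s
      } else {
        a <- numeric(J)
        b <- sens
      }
      f <- solve_pixel_quadratic(a, b, csum, active)
      if (any(!is.finite(f)))
        stop("divergence: non-finite pixel at iteration ", n, ", subset ", l)
    }
    if (!is.null(W) && uses_adaptive &&
        config$weight_refresh != "fixed")
      W <- refresh_weights(matrix(f, G, G))
    if (track && n %% config$objective_every == 0L && !is.null(W))
      obj <- record(n, "f", W)
    if (tr$prior == "median") {
      for (q in seq_len(config$n_sub_iterations))
        m <- if (W$kind == "uniform")
          m_sweep_u_cpp(f, m, 1 / W$offsets$n, W$offsets$dy, W$offsets$dx,
                        G, epsilon)
        else
          m_sweep_cpp(f, m, W$W, W$offsets$dy, W$offsets$dx, G, epsilon)
      if (track && n %% config$objective_every == 0L)
        obj <- record(n, "m", W)
    }
  }

  structure(list(f = matrix(f, G, G),
                 m = if (tr$prior == "median") matrix(m, G, G) else NULL,
                 config = cfg, epsilon = epsilon,
                 delta = if (!is.null(W)) W$delta else NA_real_,
                 objective = obj, grid_size = G, seed = sino$seed),
            class = "pet_recon")
}

#' @export
print.pet_recon <- function(x, ...) {
  cat(sprintf(
    "pet_recon: %s, beta %.4g, %d iterations x %d subsets, grid %dx%d\n",
    x$config$method, x$config$beta, x$config$n_iterations,
    x$config$n_subsets, x$grid_size, x$grid_size))
  if (!is.null(x$objective))
    cat(sprintf("  final objective: %.6g\n",
                x$objective$objective[nrow(x$objective)]))
  invisible(x)
}

#' Display a reconstruction (or any activity image)
#'
#' @param x a `pet_recon` object.
#' @param which `"f"` for the image, `"m"` for the median image.
#' @param ... passed to [graphics::image()].
#' @export
plot.pet_recon <- function(x, which = c("f", "m"), ...) {
  which <- match.arg(which)
  img <- if (which == "m") x$m else x$f
  if (is.null(img)) stop("no median image for this method")
  plot_activity(img, main = paste(x$config$method, which), ...)
}

#' @rdname plot.pet_recon
#' @param img activity image matrix (rows = image rows, origin top-left).
#' @param main plot title.
#' @export
plot_activity <- function(img, main = "", ...) {
  graphics::image(t(img)[, nrow(img):1], asp = 1, axes = FALSE,
                  col = grDevices::gray.colors(256, 0, 1), main = main, ...)
}
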