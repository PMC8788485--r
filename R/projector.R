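#' Parallel-beam acquisition geometry
#'
#' Detector bins are contiguous intervals on an axis through the center of
#' the field of view; views are evenly spaced on `[0, angular_span)`. All
#' lengths are in units of one reference (LR) pixel, so the same geometry
#' serves the native grid and finer super-resolution grids.
#'
#' @param n_bins detector bins per view.
#' @param n_angles number of views.
#' @param angular_span angular coverage in radians (default `pi`).
#' @param fov_size side length of the reference LR grid, in LR pixels.
#' @param bin_width detector bin width in LR pixel units
#'   (default `fov_size / n_bins`).
#' @return object of class `pet_geometry`.
#' @export
pet_geometry <- function(n_bins = 128L, n_angles = 128L, angular_span = pi,
                         fov_size = 128L, bin_width = fov_size / n_bins) {
  stopifnot(n_bins >= 1, n_angles >= 1, angular_span > 0,
            fov_size >= 1, bin_width > 0)
  structure(list(n_bins = as.integer(n_bins), n_angles = as.integer(n_angles),
                 angular_span = angular_span, fov_size = as.integer(fov_size),
                 bin_width = bin_width),
            class = "pet_geometry")
}

#' @export
print.pet_geometry <- function(x, ...) {
  cat(sprintf(
    "pet_geometry: %d bins x %d angles over %.1f deg, FOV %d LR px, bin width %.3f\n",
    x$n_bins, x$n_angles, x$angular_span * 180 / pi, x$fov_size, x$bin_width))
  invisible(x)
}

#' Strip-integral system matrix
#'
#' Builds the sparse parallel-beam operator `H` mapping a `grid_size` x
#' `grid_size` activity image (column-major vector) to expected projection
#' counts, one row per (bin, angle) pair. Weights are area-weighted strip
#' integrals: `H[i, j]` is the area of pixel `j` inside the strip of
#' detector bin `i`, in LR-pixel^2 units, computed in closed form from the
#' trapezoidal projection profile of a square pixel. Area weighting gives
#' full pixel coverage on grids finer than the detector sampling, which the
#' super-resolution mode requires.
#'
#' Images are intensity-valued (activity per LR-pixel^2), so a consistent
#' LR/HR image pair projects to nearly the same sinogram.
#'
#' @param geom a [pet_geometry()].
#' @param grid_size reconstruction grid side; must equal `fov_size` or an
#'   integer multiple of it (same physical FOV, finer pixels).
#' @return object of class `system_matrix`: list with `H`
#'   (`Matrix::dgCMatrix`), `geom`, `grid_size`, `px` (pixel size in LR
#'   units) and `sens` (per-pixel column sums).
#' @export
system_matrix <- function(geom, grid_size = geom$fov_size) {
  stopifnot(inherits(geom, "pet_geometry"))
  grid_size <- as.integer(grid_size)
  if (grid_size %% geom$fov_size != 0L)
    stop("grid_size must be the FOV size or an integer multiple of it")
  px <- geom$fov_size / grid_size
  tri <- build_strip_matrix_cpp(geom$n_bins, geom$n_angles, geom$angular_span,
                                geom$bin_width, grid_size, px)
  H <- Matrix::sparseMatrix(i = tri$i + 1L, j = tri$j + 1L, x = tri$x,
                            dims = c(geom$n_bins * geom$n_angles,
                                     grid_size * grid_size))
  structure(list(H = H, geom = geom, grid_size = grid_size, px = px,
                 sens = Matrix::colSums(H), cache = new.env(parent = emptyenv())),
            class = "system_matrix")
}

# row-major (CSR) copies of H used by the fused reconstruction kernel;
# built on first use and cached (the cache environment is shared by
# reference across copies of the system_matrix object). The single
# precision copy lives in C++ memory behind an external pointer and is
# rebuilt if the pointer did not survive (e.g. serialization).
csr_form <- function(sm, precision = "double") {
  if (precision == "single") {
    if (is.null(sm$cache$csrf) || !xptr_valid_cpp(sm$cache$csrf))
      sm$cache$csrf <- build_csrf_cpp(sm$H@p, sm$H@i, sm$H@x,
                                      nrow(sm$H), ncol(sm$H))
    sm$cache$csrf
  } else {
    if (is.null(sm$cache$csr))
      sm$cache$csr <- csc_to_csr_cpp(sm$H@p, sm$H@i, sm$H@x,
                                     nrow(sm$H), ncol(sm$H))
    sm$cache$csr
  }
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf(
    "system_matrix: %d x %d, grid %dx%d (px %.2f LR), %.2fM nonzeros\n",
    nrow(x$H), ncol(x$H), x$grid_size, x$grid_size, x$px,
    length(x$H@x) / 1e6))
  invisible(x)
}

as_image_vector <- function(f, grid_size) {
  if (is.matrix(f)) {
    stopifnot(all(dim(f) == c(grid_size, grid_size)))
    as.vector(f)
  } else {
    stopifnot(length(f) == grid_size^2)
    as.numeric(f)
  }
}

#' Forward and back projection
#'
#' `forward_project()` returns the mean sinogram `gbar = H f + r`;
#' `back_project()` applies the adjoint `t(H) y`.
#'
#' @param sm a [system_matrix()].
#' @param f nonnegative activity image (matrix or column-major vector).
#' @param r mean background events per bin (scalar or per-bin vector).
#' @param y sinogram-length vector.
#' @return `forward_project`: numeric vector of length
#'   `n_bins * n_angles`; `back_project`: image matrix.
#' @export
forward_project <- function(sm, f, r = 0) {
  stopifnot(inherits(sm, "system_matrix"))
  fv <- as_image_vector(f, sm$grid_size)
  if (any(fv < 0)) stop("negative pixel values in forward projection")
  as.numeric(sm$H %*% fv) + r
}

#' @rdname forward_project
#' @export
back_project <- function(sm, y) {
  stopifnot(inherits(sm, "system_matrix"), length(y) == nrow(sm$H))
  matrix(as.numeric(Matrix::crossprod(sm$H, y)), sm$grid_size, sm$grid_size)
}

#' Scale a phantom to a target number of expected counts
#'
#' Returns `c * f` with `c` chosen so the total mean sinogram equals
#' `target_counts` exactly (background excluded from the scaling).
#'
#' @inheritParams forward_project
#' @param target_counts desired total of `sum(H f)`.
#' @return rescaled image of the same shape as `f`.
#' @export
scale_to_counts <- function(f, sm, target_counts) {
  stopifnot(target_counts > 0)
  tot <- sum(forward_project(sm, f, r = 0))
  if (tot <= 0) stop("phantom projects to zero counts; cannot scale")
  f * (target_counts / tot)
}

#' Sample a Poisson sinogram
#'
#' Independent Poisson draws per (bin, angle) pair from the mean sinogram,
#' deterministic given `seed` (the caller's RNG state is left untouched and
#' the seed is recorded in the output).
#'
#' @param gbar nonnegative mean sinogram (vector).
#' @param geom the [pet_geometry()] the sinogram belongs to.
#' @param seed integer seed.
#' @param r mean background recorded with the data (scalar or vector).
#' @return object of class `sinogram`: list with integer `counts`, `geom`,
#'   `r` and `seed`.
#' @export
sample_poisson <- function(gbar, geom, seed, r = 0) {
  stopifnot(inherits(geom, "pet_geometry"),
            length(gbar) == geom$n_bins * geom$n_angles)
  if (any(gbar < 0)) stop("negative sinogram means")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  counts <- rpois(length(gbar), gbar)
  structure(list(counts = counts, geom = geom, r = r,
                 seed = as.integer(seed)),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("sinogram: %d bins x %d angles, %d total counts, seed %d\n",
              x$geom$n_bins, x$geom$n_angles, sum(x$counts), x$seed))
  invisible(x)
}

#' Interleaved angle subsets
#'
#' Partitions the projection rows into `L` balanced subsets by assigning
#' view `t` (0-based) to subset `t mod L + 1`, the standard interleaving
#' used by ordered-subsets algorithms.
#'
#' @param geom a [pet_geometry()].
#' @param L number of subsets; must not exceed `n_angles`.
#' @return list of `L` integer vectors of row indices.
#' @export
angle_subsets <- function(geom, L) {
  stopifnot(inherits(geom, "pet_geometry"), L >= 1, L <= geom$n_angles)
  lapply(seq_len(L), function(l) {
    ang <- seq(l - 1L, geom$n_angles - 1L, by = L)
    as.integer(outer(seq_len(geom$n_bins), ang * geom$n_bins, `+`))
  })
}

#' Simulate a noisy sinogram from a phantom
#'
#' Convenience wrapper: scales the phantom to `target_counts`, forward
#' projects, and draws Poisson counts. Returns the scaled truth alongside
#' the data so evaluation uses the same activity scale.
#'
#' @param truth activity image on the grid of `sm`.
#' @param sm a [system_matrix()].
#' @param target_counts expected total projection counts.
#' @param seed integer seed for the Poisson draw.
#' @param r mean background per bin.
#' @return list with `sino` ([sample_poisson()] result), `truth` (scaled
#'   image) and `gbar` (mean sinogram).
#' @export
simulate_sinogram <- function(truth, sm, target_counts = 5e5, seed = 1L,
                              r = 0) {
  truth <- scale_to_counts(truth, sm, target_counts)
  gbar <- forward_project(sm, truth, r = r)
  list(sino = sample_poisson(gbar, sm$geom, seed = seed, r = r),
       truth = truth, gbar = gbar)
}
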