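#' Read and write activity images as float TIFF
#'
#' Pixel data are stored as 32-bit float TIFF on a [0, 1] scale (the TIFF
#' writer's domain); the activity scale (the image maximum) is kept in a
#' small JSON sidecar `<path>.json` and restored on read. Requires the
#' `tiff` package.
#'
#' @param img activity image matrix.
#' @param path file path.
#' @return `read_image_tiff` returns a numeric matrix.
#' @export
write_image_tiff <- function(img, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF output")
  scale <- max(img, 1e-300)
  tiff::writeTIFF(img / scale, path, bits.per.sample = 32L, reduce = TRUE)
  jsonlite::write_json(list(activity_scale = scale), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF input")
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    img <- img * jsonlite::read_json(sidecar)$activity_scale
  img
}

#' Save and load sinograms as flat binary plus JSON header
#'
#' Counts are written as little-endian 32-bit integers (bin fastest,
#' angle slowest) next to a `.json` sidecar holding the geometry, the
#' background term and the RNG seed.
#'
#' @param sino a `sinogram`.
#' @param path base path; `<path>.bin` and `<path>.json` are written.
#' @return `read_sinogram` returns a `sinogram`.
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.integer(sino$counts), con, size = 4L, endian = "little")
  hdr <- list(n_bins = sino$geom$n_bins, n_angles = sino$geom$n_angles,
              angular_span = sino$geom$angular_span,
              fov_size = sino$geom$fov_size, bin_width = sino$geom$bin_width,
              r = sino$r, seed = sino$seed, dtype = "int32le",
              order = "bin_fastest")
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geom <- pet_geometry(hdr$n_bins, hdr$n_angles, hdr$angular_span,
                       hdr$fov_size, hdr$bin_width)
  n <- geom$n_bins * geom$n_angles
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  counts <- readBin(con, "integer", n = n, size = 4L, endian = "little")
  structure(list(counts = counts, geom = geom, r = hdr$r,
                 seed = as.integer(hdr$seed)),
            class = "sinogram")
}

#' Save and load phantom specifications as JSON
#'
#' @param spec a [phantom_spec()].
#' @param path JSON file path.
#' @return `read_phantom_spec` returns a `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  shapes <- lapply(x$shapes, function(sh) lapply(sh, function(v)
    if (is.character(v)) v else as.numeric(v)))
  phantom_spec(shapes, grid_size = as.integer(x$grid_size), name = x$name)
}
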