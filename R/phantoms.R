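#' Shape primitives for parametric phantoms
#'
#' Shapes live in the unit square: `cx`, `cy` (and radii / semi-axes) are
#' fractions of the field of view; `cx` runs along image columns, `cy` along
#' rows (origin top-left). Intensities are arbitrary activity units.
#' Later shapes overwrite earlier ones when rasterized.
#'
#' @param cx,cy center, unit-square coordinates.
#' @param r disk radius (fraction of FOV).
#' @param a,b ellipse semi-axes along x (columns) and y (rows).
#' @param x0,x1,y0,y1 rectangle bounds.
#' @param intensity nonnegative activity value painted by the shape.
#' @return a shape list understood by [rasterize()].
#' @export
shape_disk <- function(cx, cy, r, intensity) {
  stopifnot(r > 0, intensity >= 0)
  list(type = "disk", cx = cx, cy = cy, r = r, intensity = intensity)
}

#' @rdname shape_disk
#' @export
shape_ellipse <- function(cx, cy, a, b, intensity) {
  stopifnot(a > 0, b > 0, intensity >= 0)
  list(type = "ellipse", cx = cx, cy = cy, a = a, b = b, intensity = intensity)
}

#' @rdname shape_disk
#' @export
shape_rect <- function(x0, x1, y0, y1, intensity) {
  stopifnot(x0 < x1, y0 < y1, intensity >= 0)
  list(type = "rect", x0 = x0, x1 = x1, y0 = y0, y1 = y1, intensity = intensity)
}

shape_extent <- function(sh) {
  switch(sh$type,
    disk = c(sh$cx - sh$r, sh$cx + sh$r, sh$cy - sh$r, sh$cy + sh$r),
    ellipse = c(sh$cx - sh$a, sh$cx + sh$a, sh$cy - sh$b, sh$cy + sh$b),
    rect = c(sh$x0, sh$x1, sh$y0, sh$y1),
    stop("unknown shape type: ", sh$type)
  )
}

#' Parametric phantom specification
#'
#' A `phantom_spec` is an ordered list of shapes on the unit square plus a
#' nominal grid size; it rasterizes to a piecewise-constant activity image.
#' Every shape must lie fully inside the unit square.
#'
#' @param shapes list of shapes from [shape_disk()], [shape_ellipse()],
#'   [shape_rect()].
#' @param grid_size nominal pixels per side (rasterization may use another).
#' @param name identifier carried through outputs.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shapes, grid_size = 128L, name = "phantom") {
  stopifnot(is.list(shapes), grid_size >= 1)
  for (sh in shapes) {
    ext <- shape_extent(sh)
    if (ext[1] < 0 || ext[2] > 1 || ext[3] < 0 || ext[4] > 1)
      stop("shape extends outside the unit-square field of view")
    if (sh$intensity < 0) stop("shape intensity must be nonnegative")
  }
  structure(list(shapes = shapes, grid_size = as.integer(grid_size),
                 name = name),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec '%s': %d shapes, nominal grid %dx%d\n",
              x$name, length(x$shapes), x$grid_size, x$grid_size))
  invisible(x)
}

shape_mask <- function(sh, grid_size) {
  G <- grid_size
  xs <- (seq_len(G) - 0.5) / G
  cx <- matrix(xs, G, G, byrow = TRUE)  # column coordinate
  cy <- matrix(xs, G, G)                # row coordinate
  switch(sh$type,
    disk = (cx - sh$cx)^2 + (cy - sh$cy)^2 <= sh$r^2,
    ellipse = ((cx - sh$cx) / sh$a)^2 + ((cy - sh$cy) / sh$b)^2 <= 1,
    rect = cx >= sh$x0 & cx <= sh$x1 & cy >= sh$y0 & cy <= sh$y1
  )
}

#' Rasterize a phantom specification
#'
#' Pixel-center test, no anti-aliasing: a pixel takes the intensity of the
#' topmost (last-listed) shape whose region contains its center, else 0.
#' This keeps the image exactly piecewise constant, so ROI means and the
#' LR/HR downsum relation are exact away from shape boundaries.
#'
#' @param spec a [phantom_spec()].
#' @param grid_size pixels per side; defaults to the spec's nominal size.
#' @return `grid_size` x `grid_size` numeric matrix (rows = image rows).
#' @export
rasterize <- function(spec, grid_size = spec$grid_size) {
  stopifnot(inherits(spec, "phantom_spec"), grid_size >= 1)
  img <- matrix(0, grid_size, grid_size)
  for (sh in spec$shapes) img[shape_mask(sh, grid_size)] <- sh$intensity
  img
}

#' Sum 2x2 pixel blocks of a high-resolution image
#'
#' Each low-resolution pixel is the sum of its four high-resolution
#' children, so total activity is conserved exactly. With intensity-valued
#' images (activity per unit area times pixel area at the native grid),
#' `downsum(hr) / 4` is the LR intensity image away from shape boundaries.
#'
#' @param hr numeric matrix with even side lengths.
#' @return matrix of half the size in each dimension.
#' @export
downsum <- function(hr) {
  stopifnot(is.matrix(hr))
  if (nrow(hr) %% 2L != 0L || ncol(hr) %% 2L != 0L)
    stop("downsum needs even side lengths")
  nr <- nrow(hr) %/% 2L
  nc <- ncol(hr) %/% 2L
  hr[seq(1, 2 * nr, 2), seq(1, 2 * nc, 2), drop = FALSE] +
    hr[seq(2, 2 * nr, 2), seq(1, 2 * nc, 2), drop = FALSE] +
    hr[seq(1, 2 * nr, 2), seq(2, 2 * nc, 2), drop = FALSE] +
    hr[seq(2, 2 * nr, 2), seq(2, 2 * nc, 2), drop = FALSE]
}

# Frozen geometry of the circle phantom: base disk intensity 1 carrying six
# hot disks at 4:1 contrast with radii from 4 to 14 LR pixels. The layout is
# versioned package data in code form; all regional numbers downstream are
# regression-tested against it.
circles_layout <- function() {
  ang <- c(90, 150, 210, 270, 330, 30) * pi / 180
  rad_px <- c(8, 6, 4, 9, 11, 14)       # R1..R6, LR pixels at 128
  dist <- 0.26
  list(base = shape_disk(0.5, 0.5, 0.45, 1),
       hot = lapply(seq_along(rad_px), function(k) {
         shape_disk(0.5 + dist * cos(ang[k]), 0.5 + dist * sin(ang[k]),
                    rad_px[k] / 128, 4)
       }))
}

#' Circle phantom with graded hot disks
#'
#' A large base disk of low activity containing six smaller high-activity
#' disks (4:1 contrast) with radii spanning 4-14 LR pixels, used for the
#' method-comparison studies. Deterministic, frozen geometry.
#'
#' @return a [phantom_spec()] with 7 shapes (base + R1..R6 hot disks).
#' @seealso [circles_rois()] for the matching ROI masks.
#' @export
circles_phantom <- function() {
  lay <- circles_layout()
  phantom_spec(c(list(lay$base), lay$hot), grid_size = 128L, name = "circles")
}

#' ROI masks for the circle phantom
#'
#' Masks `R1`..`R6` cover the six hot disks; the background mask is the
#' flat area of the base disk (eroded, and clear of every hot disk), used
#' both as the contrast-recovery background and for background-noise
#' measurement.
#'
#' @param grid_size mask resolution (128 for LR, 256 for HR).
#' @return list with `masks` (named list of logical matrices),
#'   `background` (logical matrix) and `grid_size`.
#' @export
circles_rois <- function(grid_size = 128L) {
  lay <- circles_layout()
  masks <- lapply(lay$hot, shape_mask, grid_size = grid_size)
  names(masks) <- paste0("R", seq_along(masks))
  bg <- shape_mask(shape_disk(0.5, 0.5, 0.40, 1), grid_size)
  for (sh in lay$hot) {
    guard <- shape_disk(sh$cx, sh$cy, sh$r + 0.04, 1)
    bg <- bg & !shape_mask(guard, grid_size)
  }
  list(masks = masks, background = bg, grid_size = as.integer(grid_size))
}

brain_layout <- function() {
  list(
    shapes = list(
      shape_ellipse(0.50, 0.50, 0.330, 0.400, 4),   # cortical gray rim
      shape_ellipse(0.50, 0.50, 0.285, 0.355, 1),   # white matter interior
      shape_rect(0.48, 0.52, 0.16, 0.44, 4),        # fissure, anterior
      shape_rect(0.48, 0.52, 0.56, 0.86, 4),        # fissure, posterior
      shape_ellipse(0.38, 0.32, 0.050, 0.100, 4),   # gray folds
      shape_ellipse(0.62, 0.32, 0.050, 0.100, 4),
      shape_ellipse(0.36, 0.62, 0.055, 0.090, 4),
      shape_ellipse(0.64, 0.62, 0.055, 0.090, 4),
      shape_ellipse(0.45, 0.48, 0.030, 0.070, 0.2), # ventricles
      shape_ellipse(0.55, 0.48, 0.030, 0.070, 0.2),
      shape_disk(0.46, 0.60, 0.030, 4),             # deep gray nuclei
      shape_disk(0.54, 0.60, 0.030, 4),
      shape_disk(0.115, 0.115, 0.085, 1)            # warm noise disk, outside brain
    ),
    # boxes (x0,x1,y0,y1): R1-R8 straddle gray/white or rim edges,
    # R9 (white matter) and R10 (noise disk) are monotonic
    roi_boxes = list(
      R1 = c(0.14, 0.22, 0.46, 0.54),
      R2 = c(0.78, 0.86, 0.46, 0.54),
      R3 = c(0.46, 0.54, 0.07, 0.15),
      R4 = c(0.46, 0.54, 0.85, 0.93),
      R5 = c(0.44, 0.56, 0.20, 0.28),
      R6 = c(0.33, 0.43, 0.26, 0.34),
      R7 = c(0.40, 0.50, 0.44, 0.54),
      R8 = c(0.57, 0.71, 0.56, 0.68),
      R9 = c(0.64, 0.70, 0.44, 0.50),
      R10 = c(0.08, 0.15, 0.08, 0.15)
    ),
    crc_box = c(0.605, 0.635, 0.29, 0.35),          # inside right-top fold (gray)
    noise_disk = shape_disk(0.115, 0.115, 0.070, 1) # eroded, for noise/CRC bg
  )
}

#' Procedural brain-slice phantom with ROI masks
#'
#' A 128 x 128 piecewise-constant brain-like slice (gray/white contrast 4:1,
#' ventricles, fissure, folds) in the style of the Hoffman phantom, plus a
#' warm disk outside the brain used to measure background noise and as the
#' contrast-recovery background. This is a synthetic procedural stand-in,
#' not the measured Hoffman slice; any user-supplied 128 x 128 label image
#' can be passed instead via `label_image`.
#'
#' The ROI set holds 10 regional masks (`R1`-`R8` contain sharp edges,
#' `R9` and `R10` are monotonic), one `CRC` mask inside a gray fold, and a
#' background mask inside the warm disk.
#'
#' @param grid_size image side length (default 128).
#' @param label_image optional activity image to use instead of the
#'   procedural slice (must be `grid_size` x `grid_size`); ROI masks still
#'   come from the procedural layout.
#' @return list with `image`, `spec` (NULL when `label_image` given) and
#'   `rois` (list: `masks` R1..R10 + `CRC`, `background`, `grid_size`).
#' @export
brain_phantom <- function(grid_size = 128L, label_image = NULL) {
  lay <- brain_layout()
  spec <- phantom_spec(lay$shapes, grid_size = grid_size, name = "brain")
  if (is.null(label_image)) {
    img <- rasterize(spec, grid_size)
  } else {
    stopifnot(is.matrix(label_image),
              all(dim(label_image) == c(grid_size, grid_size)),
              all(label_image >= 0))
    img <- label_image
    spec <- NULL
  }
  masks <- lapply(lay$roi_boxes, function(b)
    shape_mask(shape_rect(b[1], b[2], b[3], b[4], 1), grid_size))
  masks$CRC <- shape_mask(shape_rect(lay$crc_box[1], lay$crc_box[2],
                                     lay$crc_box[3], lay$crc_box[4], 1),
                          grid_size)
  bg <- shape_mask(lay$noise_disk, grid_size)
  list(image = img, spec = spec,
       rois = list(masks = masks, background = bg,
                   grid_size = as.integer(grid_size)))
}
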