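#' Create a section image
#'
#' A registered 2D grayscale section: a numeric matrix of intensities in
#' `[0, 2^bit_depth - 1]`, with the physical pixel size and the serial
#' position of the section attached as attributes.
#'
#' @param pixels numeric matrix (rows = dorso-ventral axis, columns =
#'   rostro-caudal axis for sagittal sections).
#' @param pixel_size physical size of one pixel in micrometres.
#' @param bit_depth 8 or 16.
#' @param section_index integer serial index of the section.
#' @param medio_lateral_pos medio-lateral position of the section in
#'   micrometres (sagittal series are ordered lateral to medial).
#' @return a `section_image` object.
#' @export
section_image <- function(pixels, pixel_size, bit_depth = 16L,
                          section_index = 1L, medio_lateral_pos = NA_real_) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!bit_depth %in% c(8L, 16L)) {
    stop("bit_depth must be 8 or 16")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("pixel_size must be a positive scalar (micrometres per pixel)")
  }
  maxval <- 2^bit_depth - 1
  if (min(pixels) < 0 || max(pixels) > maxval) {
    stop("pixel intensities outside [0, ", maxval, "]")
  }
  structure(pixels,
            pixel_size = pixel_size,
            bit_depth = as.integer(bit_depth),
            section_index = as.integer(section_index),
            medio_lateral_pos = as.numeric(medio_lateral_pos),
            class = c("section_image", "matrix", "array"))
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image> %d x %d px, %d-bit, %.3g um/px, section %d\n",
              nrow(x), ncol(x), attr(x, "bit_depth"), attr(x, "pixel_size"),
              attr(x, "section_index")))
  invisible(x)
}

#' Create an atlas plate
#'
#' The colour-coded atlas segmentation plate paired with a section image:
#' an H x W x 3 integer array of RGB values in 0..255.  Black (0,0,0) is
#' the background outside all regions.
#'
#' @param rgb integer array of dimension `c(H, W, 3)`, values in 0..255.
#' @return an `atlas_plate` object.
#' @export
atlas_plate <- function(rgb) {
  stopifnot(is.array(rgb), length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  if (min(rgb) < 0 || max(rgb) > 255) stop("RGB values must be in 0..255")
  storage.mode(rgb) <- "integer"
  structure(rgb, class = c("atlas_plate", "array"))
}

#' Create a colour-to-region lookup table
#'
#' @param region_id character or integer region identifiers (unique).
#' @param name human-readable region names.
#' @param r,g,b integer colour components in 0..255; each colour must be
#'   unique.
#' @return a `region_map` data frame with columns
#'   `region_id, name, r, g, b`.
#' @export
region_map <- function(region_id, name = as.character(region_id), r, g, b) {
  df <- data.frame(region_id = as.character(region_id),
                   name = as.character(name),
                   r = as.integer(r), g = as.integer(g), b = as.integer(b),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$region_id)) stop("region_ids must be unique")
  key <- df$r * 65536L + df$g * 256L + df$b
  if (anyDuplicated(key)) stop("region colours must be unique")
  if (any(key == 0L)) stop("black (0,0,0) is reserved for background")
  if (any(df$r < 0 | df$r > 255 | df$g < 0 | df$g > 255 |
          df$b < 0 | df$b > 255)) {
    stop("colour components must be in 0..255")
  }
  class(df) <- c("region_map", "data.frame")
  df
}

#' Create a voxelized region volume
#'
#' A binary voxel mask over a regular grid in atlas micrometre
#' coordinates, used as the spatial support of a brain region (e.g. the
#' pontine nuclei) for point-cloud analyses.
#'
#' @param mask 3D logical array (x, y, z order).
#' @param voxel_size edge length of a voxel in micrometres.
#' @param origin numeric length-3: the atlas coordinate of the corner of
#'   voxel `[1,1,1]`, in micrometres.
#' @return a `region_volume` object.
#' @export
region_volume <- function(mask, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("region volume mask is empty")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  structure(list(mask = mask, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "region_volume")
}

#' @export
print.region_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<region_volume> %d x %d x %d voxels @ %.3g um, %d in mask\n",
              d[1], d[2], d[3], x$voxel_size, sum(x$mask)))
  invisible(x)
}

#' Test whether points fall inside a region volume
#'
#' @param volume a [region_volume()].
#' @param xyz numeric matrix with columns x, y, z (micrometres).
#' @return logical vector, one entry per row of `xyz`.
#' @export
in_volume <- function(volume, xyz) {
  stopifnot(inherits(volume, "region_volume"))
  xyz <- as.matrix(xyz)
  d <- dim(volume$mask)
  idx <- sweep(xyz, 2, volume$origin)
  idx <- floor(idx / volume$voxel_size) + 1
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
        idx[, 2] >= 1 & idx[, 2] <= d[2] &
        idx[, 3] >= 1 & idx[, 3] <= d[3]
  res <- logical(nrow(xyz))
  if (any(ok)) {
    res[ok] <- volume$mask[cbind(idx[ok, 1], idx[ok, 2], idx[ok, 3])]
  }
  res
}

#' Create a 3D point cloud
#'
#' Labelled points in atlas micrometre coordinates.  Axis convention
#' (documented to prevent silent flips): x increases rostral to caudal,
#' y dorsal to ventral, z left to right.
#'
#' @param x,y,z numeric coordinates in micrometres.
#' @param density_class ordinal labelling-density class (1 = low); the
#'   semi-quantitative recording scheme plants more points where the
#'   observed signal is denser.
#' @param group group label (e.g. "control", "mutant").
#' @param source_section serial index of the section each point was
#'   recorded from.
#' @return a `point_cloud3d` data frame with columns
#'   `x_um, y_um, z_um, density_class, group, source_section`.
#' @export
point_cloud3d <- function(x, y, z, density_class = 1L, group = "control",
                          source_section = NA_integer_) {
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z))) {
    stop("point coordinates must be finite")
  }
  if (any(density_class < 1)) stop("density_class must be >= 1")
  df <- data.frame(x_um = as.numeric(x), y_um = as.numeric(y),
                   z_um = as.numeric(z),
                   density_class = as.integer(density_class),
                   group = as.character(group),
                   source_section = as.integer(source_section),
                   stringsAsFactors = FALSE)
  class(df) <- c("point_cloud3d", "data.frame")
  df
}

# internal: coerce a data.frame-like object to the point_cloud3d contract
as_point_cloud3d <- function(df) {
  need <- c("x_um", "y_um", "z_um")
  if (!all(need %in% names(df))) {
    stop("point cloud needs columns x_um, y_um, z_um")
  }
  if (is.null(df$density_class)) df$density_class <- 1L
  if (is.null(df$group)) df$group <- "control"
  if (is.null(df$source_section)) df$source_section <- NA_integer_
  class(df) <- unique(c("point_cloud3d", class(df)))
  df
}

#' Specify a digital slab slice through a point cloud
#'
#' @param axis `"sagittal"` (normal = z, left-right), `"frontal"`
#'   (normal = x, rostro-caudal) or `"horizontal"` (normal = y,
#'   dorso-ventral).
#' @param centre position of the slab centre along the axis normal, in
#'   micrometres.
#' @param thickness slab thickness in micrometres (default 100, the
#'   conventional thickness of a digital slice).
#' @return a `slab_spec` object.
#' @export
slab_spec <- function(axis = c("sagittal", "frontal", "horizontal"),
                      centre, thickness = 100) {
  axis <- match.arg(axis)
  if (thickness <= 0) stop("slab thickness must be positive")
  structure(list(axis = axis, centre = as.numeric(centre),
                 thickness = as.numeric(thickness)),
            class = "slab_spec")
}
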