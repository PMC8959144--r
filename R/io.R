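#' Read and write section images as TIFF
#'
#' Sections are stored as grayscale TIFF; intensities are scaled to the
#' file's `[0, 1]` convention on write and back to `0 .. 2^bit_depth - 1`
#' on read.
#'
#' @param img a [section_image()].
#' @param path file path.
#' @name section_io
#' @export
write_section_tiff <- function(img, path) {
  bd <- attr(img, "bit_depth")
  maxval <- 2^bd - 1
  tiff::writeTIFF(unclass(img) / maxval, path, bits.per.sample = bd)
  invisible(path)
}

#' @rdname section_io
#' @param pixel_size,bit_depth,section_index,medio_lateral_pos metadata
#'   to attach on read (TIFF carries no atlas metadata).
#' @export
read_section_tiff <- function(path, pixel_size, bit_depth = 16L,
                              section_index = 1L,
                              medio_lateral_pos = NA_real_) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  section_image(round(m * (2^bit_depth - 1)), pixel_size, bit_depth,
                section_index, medio_lateral_pos)
}

#' Read and write atlas plates as RGB PNG
#'
#' @param plate an [atlas_plate()].
#' @param path file path.
#' @name plate_io
#' @export
write_plate_png <- function(plate, path) {
  png::writePNG(unclass(plate) / 255, path)
  invisible(path)
}

#' @rdname plate_io
#' @export
read_plate_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) stop("atlas plates must be RGB")
  atlas_plate(round(a[, , 1:3] * 255))
}

#' Read and write the colour-to-region lookup table as CSV
#'
#' Columns: `region_id, name, r, g, b`.
#'
#' @param map a [region_map()].
#' @param path file path.
#' @name region_map_io
#' @export
write_region_map_csv <- function(map, path) {
  write.csv(as.data.frame(map)[, c("region_id", "name", "r", "g", "b")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname region_map_io
#' @export
read_region_map_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  region_map(df$region_id, df$name, df$r, df$g, df$b)
}

#' Read and write point clouds as JSON records
#'
#' One record per point with fields
#' `x_um, y_um, z_um, density_class, group, source_section`; axis
#' convention: x rostral to caudal, y dorsal to ventral, z left to
#' right.
#'
#' @param cloud a [point_cloud3d()].
#' @param path file path.
#' @name cloud_io
#' @export
write_cloud_json <- function(cloud, path) {
  jsonlite::write_json(as.data.frame(cloud), path, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname cloud_io
#' @export
read_cloud_json <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_point_cloud3d(df)
}
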