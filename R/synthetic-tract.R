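#' Specify a synthetic fibre-tract image
#'
#' Describes a binary sagittal image of a descending fibre tract as a set
#' of fascicles, each a band of signal rows that may vary along the
#' medio-lateral/rostro-caudal (column) axis.  The dorso-ventral axis is
#' the row axis.  Ground-truth widths are computed analytically from the
#' row intervals.
#'
#' @param image_shape integer length-2, rows x columns.
#' @param fascicles list of fascicles; each is a list with elements `top`
#'   and `bottom`, either scalars or integer vectors of length
#'   `ncol` giving the first and last signal row per column (inclusive).
#'   Use `NA` in a column to leave the fascicle absent there.  Fascicle
#'   intervals must be pairwise disjoint in every column.
#' @param measurement_columns named integer vector of labelled column
#'   positions (e.g. `c(rostral = 40, caudal = 120, c250 = 220,
#'   c500 = 320)`); all must lie inside the image.
#' @param pixel_size micrometres per pixel.
#' @param section_index serial index of the section.
#' @param medio_lateral_pos medio-lateral position in micrometres.
#' @return a `tract_spec` object.
#' @seealso [make_tract_image()]
#' @export
tract_spec <- function(image_shape, fascicles, measurement_columns,
                       pixel_size = 2.5, section_index = 1L,
                       medio_lateral_pos = NA_real_) {
  shape <- as.integer(image_shape)
  w <- shape[2]
  fasc <- lapply(fascicles, function(f) {
    top <- rep_len(as.numeric(f$top), w)
    bottom <- rep_len(as.numeric(f$bottom), w)
    bad <- !is.na(top) & !is.na(bottom) &
      (top < 1 | bottom > shape[1] | top > bottom)
    if (any(bad)) stop("fascicle interval outside image or inverted")
    list(top = top, bottom = bottom)
  })
  # disjointness per column
  for (x in seq_len(w)) {
    iv <- do.call(rbind, lapply(fasc, function(f) c(f$top[x], f$bottom[x])))
    iv <- iv[!is.na(iv[, 1]), , drop = FALSE]
    if (nrow(iv) > 1) {
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
        stop("overlapping fascicle intervals at column ", x)
      }
    }
  }
  if (is.null(names(measurement_columns)) ||
      any(!nzchar(names(measurement_columns)))) {
    stop("measurement_columns must be named")
  }
  if (any(measurement_columns < 1 | measurement_columns > w)) {
    stop("measurement columns must lie inside the image")
  }
  structure(list(image_shape = shape, fascicles = fasc,
                 measurement_columns = measurement_columns,
                 pixel_size = pixel_size,
                 section_index = as.integer(section_index),
                 medio_lateral_pos = as.numeric(medio_lateral_pos)),
            class = "tract_spec")
}

#' Generate a binary tract image with analytic ground-truth widths
#'
#' Rasterizes the fascicle bands of a [tract_spec()] and computes, per
#' column, the ground-truth total envelope width (first to last signal
#' row), fibre width (number of signal rows) and gap width, in pixels
#' and micrometres.
#'
#' @param spec a [tract_spec()].
#' @return a list with
#'   * `image`: binary (0/1) [section_image()];
#'   * `ground_truth`: data frame `(column, total_px, fibre_px, gap_px,
#'     total_um, fibre_um, gap_um)`, one row per image column;
#'   * `measurement_truth`: the same restricted to the labelled
#'     measurement columns, with a `label` column.
#' @export
make_tract_image <- function(spec) {
  stopifnot(inherits(spec, "tract_spec"))
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  img <- matrix(0, h, w)
  for (f in spec$fascicles) {
    for (x in seq_len(w)) {
      if (!is.na(f$top[x])) img[f$top[x]:f$bottom[x], x] <- 1
    }
  }
  gt <- data.frame(column = seq_len(w), total_px = 0, fibre_px = 0)
  for (x in seq_len(w)) {
    tops <- vapply(spec$fascicles, function(f) f$top[x], numeric(1))
    bots <- vapply(spec$fascicles, function(f) f$bottom[x], numeric(1))
    keep <- !is.na(tops)
    if (any(keep)) {
      gt$total_px[x] <- max(bots[keep]) - min(tops[keep]) + 1
      gt$fibre_px[x] <- sum(bots[keep] - tops[keep] + 1)
    }
  }
  gt$gap_px <- gt$total_px - gt$fibre_px
  gt$total_um <- gt$total_px * spec$pixel_size
  gt$fibre_um <- gt$fibre_px * spec$pixel_size
  gt$gap_um <- gt$gap_px * spec$pixel_size

  mt <- gt[match(spec$measurement_columns, gt$column), ]
  mt <- cbind(label = names(spec$measurement_columns), mt)
  rownames(mt) <- NULL

  list(image = section_image(img, spec$pixel_size, 8L,
                             section_index = spec$section_index,
                             medio_lateral_pos = spec$medio_lateral_pos),
       ground_truth = gt,
       measurement_truth = mt)
}
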