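#' Dorso-ventral tract widths at one image column
#'
#' Measures, in a binary sagittal image, the total dorso-ventral width of
#' the fibre bundle at column `x` (first to last signal row, inclusive),
#' the fibre width (number of signal rows) and the gap width between
#' fascicles (total minus fibre).  Widths are integer pixel counts
#' converted to micrometres.
#'
#' @param img binary image (matrix or [section_image()]; non-zero =
#'   signal).
#' @param x column index (1-based); optionally a `median_halfwidth` of
#'   `k` takes the per-quantity median over columns `x - k .. x + k` for
#'   robustness to single-column noise.
#' @param pixel_size micrometres per pixel; defaults to the image's
#'   `pixel_size` attribute.
#' @param median_halfwidth integer `k >= 0` (default 0: single column).
#' @return named numeric vector `c(total, fibre, gap)` in micrometres;
#'   an empty column yields `c(0, 0, 0)`.
#' @export
width_at_column <- function(img, x, pixel_size = attr(img, "pixel_size"),
                            median_halfwidth = 0L) {
  if (is.null(pixel_size)) stop("pixel_size missing")
  if (length(x) != 1L || x < 1 || x > ncol(img)) {
    stop("column x outside the image")
  }
  cols <- max(1L, x - median_halfwidth):min(ncol(img), x + median_halfwidth)
  one <- function(xc) {
    rows <- which(unclass(img)[, xc] > 0)
    if (length(rows) == 0) return(c(total = 0, fibre = 0, gap = 0))
    total <- max(rows) - min(rows) + 1
    fibre <- length(rows)
    c(total = total, fibre = fibre, gap = total - fibre)
  }
  px <- vapply(cols, one, numeric(3))
  apply(px, 1, stats::median) * pixel_size
}

#' Width profile of a medio-lateral section series
#'
#' Measures tract widths at labelled column positions on each section of
#' a lateral-to-medial series, producing one profile entry per section
#' per label.  Missing labels are recorded as `NA` entries (flagged, not
#' fatal), and entries are ordered lateral to medial by
#' `medio_lateral_pos`.
#'
#' @param images list of binary [section_image()]s; each must carry
#'   `section_index` and `medio_lateral_pos` attributes.
#' @param columns data frame `(section_index, label, column)` naming the
#'   measurement column for each label on each section; labels absent
#'   for a section yield `NA` widths.
#' @param median_halfwidth passed to [width_at_column()].
#' @return a `width_profile` data frame `(section_index,
#'   medio_lateral_pos, label, total_width, fibre_width, gap_width)`
#'   in micrometres.
#' @export
profile_series <- function(images, columns, median_halfwidth = 0L) {
  stopifnot(length(images) >= 1, is.data.frame(columns),
            all(c("section_index", "label", "column") %in% names(columns)))
  labels <- unique(columns$label)
  rows <- list()
  for (img in images) {
    si <- attr(img, "section_index")
    ml <- attr(img, "medio_lateral_pos")
    for (lb in labels) {
      sel <- columns$section_index == si & columns$label == lb
      if (any(sel)) {
        w <- width_at_column(img, columns$column[which(sel)[1]],
                             median_halfwidth = median_halfwidth)
      } else {
        w <- c(total = NA_real_, fibre = NA_real_, gap = NA_real_)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(section_index = si, medio_lateral_pos = ml, label = lb,
                   total_width = w[["total"]], fibre_width = w[["fibre"]],
                   gap_width = w[["gap"]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$label, out$medio_lateral_pos), ]
  rownames(out) <- NULL
  class(out) <- c("width_profile", "data.frame")
  out
}

#' Area under a width profile
#'
#' Trapezoidal integral of the total width over the medio-lateral extent
#' of the series, summarizing how much fibre crosses the measured level
#' (the area under the lateral-to-medial width curve).  Entries with
#' missing widths are skipped with a warning.
#'
#' @param profile a `width_profile` from [profile_series()].
#' @param label which measurement label to integrate.
#' @param value `"total_width"` (default) or `"fibre_width"`.
#' @return area in square micrometres.
#' @export
area_under_profile <- function(profile, label, value = "total_width") {
  sel <- profile[profile$label == label, ]
  miss <- is.na(sel[[value]]) | is.na(sel$medio_lateral_pos)
  if (any(miss)) {
    warning(sum(miss), " entries with missing values skipped")
    sel <- sel[!miss, ]
  }
  if (nrow(sel) < 2) {
    stop("need at least 2 valid profile entries to integrate")
  }
  sel <- sel[order(sel$medio_lateral_pos), ]
  x <- sel$medio_lateral_pos
  y <- sel[[value]]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Fasciculation index
#'
#' Ratio of fibre width to total envelope width of the tract.  A fully
#' fasciculated bundle with no gaps between fascicles scores 1; spread,
#' defasciculated bundles score lower.  The reciprocal convention
#' (total/fibre) is available via `orientation`.
#'
#' @param total_width,fibre_width widths in consistent units (vectors
#'   allowed).
#' @param orientation `"fibre_over_total"` (default; lower = more
#'   defasciculated) or `"total_over_fibre"`.
#' @return the index; `NA` where `total_width` is 0 (undefined).
#' @export
fasciculation_index <- function(total_width, fibre_width,
                                orientation = c("fibre_over_total",
                                                "total_over_fibre")) {
  orientation <- match.arg(orientation)
  if (any(fibre_width > total_width, na.rm = TRUE)) {
    stop("fibre_width cannot exceed total_width")
  }
  idx <- ifelse(total_width > 0, fibre_width / total_width, NA_real_)
  if (orientation == "total_over_fibre") idx <- 1 / idx
  idx
}

#' Fasciculation measurements at caudal offsets
#'
#' Convenience wrapper: measures total and fibre widths at the columns
#' corresponding to the given caudal offsets from a reference column
#' (e.g. the caudal edge of the pontine nuclei) and returns the
#' fasciculation index at each.  Offsets are converted to columns with
#' round-half-away-from-zero.
#'
#' @param img binary [section_image()].
#' @param reference_column column of the reference landmark.
#' @param offsets_um caudal offsets in micrometres (default
#'   `c(250, 500)`).
#' @param pixel_size micrometres per pixel; defaults to the image
#'   attribute.
#' @param ... passed to [width_at_column()].
#' @return data frame `(offset_um, column, total_width, fibre_width,
#'   gap_width, fasciculation_index)`.
#' @export
fasciculation_at_offsets <- function(img, reference_column,
                                     offsets_um = c(250, 500),
                                     pixel_size = attr(img, "pixel_size"),
                                     ...) {
  if (is.null(pixel_size)) stop("pixel_size missing")
  # round half away from zero, not banker's rounding
  half_away <- function(v) sign(v) * floor(abs(v) + 0.5)
  cols <- reference_column + half_away(offsets_um / pixel_size)
  out <- lapply(seq_along(offsets_um), function(i) {
    w <- width_at_column(img, cols[i], pixel_size = pixel_size, ...)
    data.frame(offset_um = offsets_um[i], column = cols[i],
               total_width = w[["total"]], fibre_width = w[["fibre"]],
               gap_width = w[["gap"]],
               fasciculation_index = fasciculation_index(w[["total"]],
                                                         w[["fibre"]]))
  })
  do.call(rbind, out)
}
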