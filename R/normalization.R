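#' Intensity histogram of an image
#'
#' @param img a [section_image()] or numeric matrix of integer-valued
#'   intensities.
#' @param bit_depth 8 or 16; defaults to the image's attribute.
#' @return integer vector of counts over intensity levels
#'   `0 .. 2^bit_depth - 1`.
#' @export
intensity_histogram <- function(img, bit_depth = attr(img, "bit_depth")) {
  if (is.null(bit_depth)) bit_depth <- 16L
  nlev <- 2^bit_depth
  tabulate(as.integer(round(unclass(img))) + 1L, nbins = nlev)
}

#' Build a histogram-matching lookup table
#'
#' Classical discrete CDF matching: each source level `s` maps to the
#' lowest reference level whose cumulative mass reaches the source
#' cumulative mass at `s`.  The lookup is monotone non-decreasing, so
#' intensity ordering within an image is preserved (ties may merge).
#' Matching every animal's images against one representative reference
#' case equalizes brightness and contrast across a dataset.
#'
#' @param source_hist,reference_hist histograms over the same bit range
#'   (see [intensity_histogram()]); the reference must be non-empty.
#' @return a `histogram_map`: integer lookup vector of length
#'   `2^bit_depth` (index = source level + 1).
#' @export
build_histogram_map <- function(source_hist, reference_hist) {
  if (length(source_hist) != length(reference_hist)) {
    stop("histograms must cover the same bit range")
  }
  if (sum(source_hist) == 0 || sum(reference_hist) == 0) {
    stop("empty histogram")
  }
  cdf_s <- cumsum(source_hist) / sum(source_hist)
  cdf_r <- cumsum(reference_hist) / sum(reference_hist)
  # for each source level, lowest reference level with cdf_r >= cdf_s
  idx <- findInterval(cdf_s, cdf_r, left.open = TRUE) + 1L
  idx <- pmin(idx, length(cdf_r))
  lut <- as.integer(idx - 1L)
  structure(lut, bit_depth = as.integer(round(log2(length(lut)))),
            class = "histogram_map")
}

#' Apply a histogram-matching lookup to an image
#'
#' @param img a [section_image()] or integer-valued matrix whose bit
#'   depth matches the map.
#' @param map a `histogram_map` from [build_histogram_map()].
#' @return the remapped image (same class and attributes).  Applying the
#'   same reference map twice is idempotent.
#' @export
apply_histogram_map <- function(img, map) {
  stopifnot(inherits(map, "histogram_map"))
  bit_depth <- attr(img, "bit_depth")
  if (is.null(bit_depth)) bit_depth <- as.integer(round(log2(length(map))))
  if (2^bit_depth != length(map)) {
    stop("image bit depth does not match the histogram map")
  }
  vals <- as.integer(round(unclass(img)))
  out <- matrix(as.numeric(unclass(map)[vals + 1L]), nrow(img), ncol(img))
  attributes(out) <- attributes(img)
  out
}

#' Match an image's histogram to a reference image
#'
#' Convenience wrapper: builds the CDF-matching lookup from the two
#' image histograms and applies it.
#'
#' @param img image to normalize.
#' @param reference representative reference image (same bit depth).
#' @return the normalized image.
#' @export
match_histogram <- function(img, reference) {
  bd_i <- attr(img, "bit_depth")
  bd_r <- attr(reference, "bit_depth")
  if (!is.null(bd_i) && !is.null(bd_r) && bd_i != bd_r) {
    stop("image and reference bit depths differ")
  }
  bd <- if (!is.null(bd_i)) bd_i else if (!is.null(bd_r)) bd_r else 16L
  map <- build_histogram_map(intensity_histogram(img, bd),
                             intensity_histogram(reference, bd))
  apply_histogram_map(img, map)
}
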