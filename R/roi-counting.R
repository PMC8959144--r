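#' Extract region-of-interest masks from a colour-coded atlas plate
#'
#' Delineates one binary mask per region from the composite RGB
#' segmentation plate, matching colours exactly against the lookup
#' table.  Black pixels (0,0,0) are background.  Colours present in the
#' plate but absent from the table are collected into an `unassigned`
#' mask and reported via attributes rather than treated as an error.
#'
#' @param plate an [atlas_plate()].
#' @param map a [region_map()].
#' @return named list of logical matrices, one per `region_id`, with
#'   attributes `unassigned` (logical matrix of unmapped non-background
#'   pixels) and `n_unassigned` (pixel count).  The masks are pairwise
#'   disjoint and, together with background and unassigned pixels, cover
#'   the plate.
#' @export
extract_rois <- function(plate, map) {
  stopifnot(inherits(plate, "atlas_plate"), is.data.frame(map))
  key <- plate[, , 1] * 65536L + plate[, , 2] * 256L + plate[, , 3]
  map_key <- map$r * 65536L + map$g * 256L + map$b
  rois <- lapply(map_key, function(k) key == k)
  names(rois) <- map$region_id
  unassigned <- key != 0L & !(key %in% map_key)
  attr(rois, "unassigned") <- unassigned
  attr(rois, "n_unassigned") <- sum(unassigned)
  rois
}

#' Subtract background with a grayscale white top-hat
#'
#' Corrects a raw fluorescence image by subtracting its morphological
#' background: the image minus its grayscale opening with a disk
#' structuring element.  Flat regions map to (approximately) zero while
#' objects smaller than the disk - the labelled somata - are preserved.
#' This is the standard morphological equivalent of rolling-ball
#' background subtraction.
#'
#' @param img a [section_image()] or numeric matrix.
#' @param radius_px disk radius in pixels (default 15); must be at least
#'   1 and smaller than the image.
#' @return background-corrected image of the same class; intensities are
#'   non-negative.
#' @export
subtract_background <- function(img, radius_px = 15L) {
  if (radius_px < 1) stop("radius_px must be >= 1")
  if (2 * radius_px + 1 > min(dim(img))) {
    stop("structuring element larger than the image")
  }
  bit_depth <- attr(img, "bit_depth")
  maxval <- if (is.null(bit_depth)) max(1, max(img)) else 2^bit_depth - 1
  kern <- EBImage::makeBrush(2 * radius_px + 1, shape = "disc")
  scaled <- unclass(img) / maxval  # EBImage grayscale morphology needs [0,1]
  th <- EBImage::whiteTopHat(scaled, kern) * maxval
  th <- pmax(th, 0)
  attributes(th) <- attributes(img)
  th
}

#' Otsu threshold of a section image
#'
#' @param img a [section_image()] or numeric matrix.
#' @return scalar threshold on the image's intensity scale.
#' @export
otsu_threshold <- function(img) {
  bit_depth <- attr(img, "bit_depth")
  if (is.null(bit_depth)) bit_depth <- 16L
  maxval <- 2^bit_depth - 1
  EBImage::otsu(EBImage::Image(unclass(img) / maxval),
                range = c(0, 1), levels = maxval + 1) * maxval
}

#' Detect labelled objects in a background-corrected image
#'
#' Binarizes the image at the given intensity threshold and extracts the
#' 8-connected components of the foreground, the standard
#' particle-analysis convention.  Each component is described by its
#' centroid, area, boundary-following perimeter (axis steps count 1,
#' diagonal steps `sqrt(2)`), circularity `4 * pi * area / perimeter^2`
#' (clamped to at most 1, since rasterization can push the raw value
#' above 1), and mean intensity.
#'
#' @param img a [section_image()] or numeric matrix (background
#'   corrected).
#' @param threshold scalar intensity; pixels strictly above it are
#'   foreground.  Use `"otsu"` for an automatic global threshold.
#' @param min_area discard components smaller than this many pixels
#'   (default 1: keep everything); a small minimum size rejects
#'   single-pixel noise specks, which are otherwise near-circular.
#' @return data frame of class `detected_objects` with columns
#'   `label, centroid_row, centroid_col, area, perimeter, circularity,
#'   mean_intensity`, empty when nothing is above threshold.
#' @export
detect_objects <- function(img, threshold = "otsu", min_area = 1L) {
  if (identical(threshold, "otsu")) threshold <- otsu_threshold(img)
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  mask <- unclass(img) > threshold
  lab <- .label_components8(mask)
  nlab <- max(lab)
  if (nlab == 0L) {
    out <- data.frame(label = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area = numeric(0),
                      perimeter = numeric(0), circularity = numeric(0),
                      mean_intensity = numeric(0))
  } else {
    st <- .component_stats(lab, matrix(as.numeric(img), nrow(img)), nlab)
    per <- .trace_perimeters(lab, nlab)
    circ <- pmin(4 * pi * st$area / per^2, 1)
    out <- data.frame(label = seq_len(nlab),
                      centroid_row = st$centroid_row,
                      centroid_col = st$centroid_col,
                      area = st$area, perimeter = per, circularity = circ,
                      mean_intensity = st$mean_intensity)
    if (min_area > 1L) out <- out[out$area >= min_area, , drop = FALSE]
  }
  attr(out, "labels") <- lab
  attr(out, "threshold") <- threshold
  class(out) <- c("detected_objects", "data.frame")
  out
}

#' Keep objects within a circularity range
#'
#' Only elements whose shape is close enough to a circle are counted as
#' labelled somata; elongated profiles (fibre fragments, edge artefacts)
#' are rejected.  Default range 0.5-1.
#'
#' @param objs a `detected_objects` data frame.
#' @param lo,hi inclusive circularity bounds, `0 <= lo <= hi <= 1`.
#' @return the filtered data frame.
#' @export
filter_by_circularity <- function(objs, lo = 0.5, hi = 1.0) {
  if (!(lo >= 0 && lo <= hi && hi <= 1)) {
    stop("need 0 <= lo <= hi <= 1")
  }
  keep <- objs$circularity >= lo & objs$circularity <= hi
  out <- objs[keep, , drop = FALSE]
  attr(out, "labels") <- attr(objs, "labels")
  attr(out, "threshold") <- attr(objs, "threshold")
  class(out) <- class(objs)
  out
}

#' Count objects per atlas region
#'
#' Assigns each detected object to the region whose mask contains its
#' centroid pixel; objects landing on background or unmapped colours are
#' counted in an `"unassigned"` bucket.  The bucket totals always sum to
#' the number of objects passed in.
#'
#' @param objs a `detected_objects` data frame (after circularity
#'   filtering).
#' @param rois ROI mask list from [extract_rois()]; masks must have the
#'   same shape as the image the objects were detected in.
#' @param section_index serial index recorded in the output rows.
#' @return data frame `(section_index, region_id, raw_count)` with one
#'   row per region plus the `"unassigned"` bucket.
#' @export
count_per_region <- function(objs, rois, section_index = 1L) {
  lab <- attr(objs, "labels")
  if (!is.null(lab) && length(rois) > 0 &&
      !identical(dim(lab), dim(rois[[1]]))) {
    stop("image and atlas plate shapes differ")
  }
  counts <- setNames(integer(length(rois)), names(rois))
  unassigned <- 0L
  if (nrow(objs) > 0) {
    pr <- round(objs$centroid_row)
    pc <- round(objs$centroid_col)
    for (k in seq_len(nrow(objs))) {
      hit <- NA_character_
      for (rid in names(rois)) {
        if (rois[[rid]][pr[k], pc[k]]) { hit <- rid; break }
      }
      if (is.na(hit)) unassigned <- unassigned + 1L
      else counts[hit] <- counts[hit] + 1L
    }
  }
  data.frame(section_index = as.integer(section_index),
             region_id = c(names(rois), "unassigned"),
             raw_count = c(as.integer(counts), unassigned),
             stringsAsFactors = FALSE)
}

#' Count labelled somata per region on one section
#'
#' Runs the full counting pipeline on one section: top-hat background
#' subtraction, global thresholding, 8-connected component detection,
#' circularity gating (default 0.5-1) and centroid-based assignment to
#' the colour-coded atlas regions.
#'
#' @param img raw [section_image()].
#' @param plate matching [atlas_plate()].
#' @param map [region_map()].
#' @param threshold scalar intensity or `"otsu"` (applied after
#'   background subtraction).
#' @param circ length-2 circularity range.
#' @param background_radius top-hat disk radius in pixels.
#' @param min_area passed to [detect_objects()].
#' @return data frame `(section_index, region_id, raw_count)`.
#' @export
count_section <- function(img, plate, map, threshold = "otsu",
                          circ = c(0.5, 1.0), background_radius = 15L,
                          min_area = 1L) {
  if (!identical(dim(unclass(img)), dim(plate)[1:2])) {
    stop("image and atlas plate shapes differ")
  }
  rois <- extract_rois(plate, map)
  corrected <- subtract_background(img, background_radius)
  objs <- detect_objects(corrected, threshold, min_area = min_area)
  objs <- filter_by_circularity(objs, circ[1], circ[2])
  count_per_region(objs, rois, attr(img, "section_index"))
}

#' Normalize per-region counts
#'
#' Two normalizations of a raw count table:
#'
#' * `"per_section"`: for each animal and region, the summed raw count
#'   divided by the number of sections analysed for that animal, so that
#'   animals contributing different numbers of sections are comparable.
#' * `"MS_percentage"`: for each animal, counts in the motor (`m_region`)
#'   and somatosensory (`s_region`) areas expressed as percentages of
#'   their sum, so `%M + %S = 100` exactly.
#'
#' @param table data frame with columns `animal_id, genotype,
#'   section_index, region_id, raw_count`.
#' @param mode `"per_section"` or `"MS_percentage"`.
#' @param m_region,s_region region ids of the motor and somatosensory
#'   areas (used by `"MS_percentage"`).
#' @return for `"per_section"`: data frame `(animal_id, genotype,
#'   region_id, total_count, n_sections, per_section)`; for
#'   `"MS_percentage"`: data frame `(animal_id, genotype, region_id,
#'   count, pct)` with two rows per animal.
#' @export
normalize_counts <- function(table, mode = c("per_section", "MS_percentage"),
                             m_region = "M", s_region = "S") {
  mode <- match.arg(mode)
  need <- c("animal_id", "genotype", "section_index", "region_id",
            "raw_count")
  if (!all(need %in% names(table))) {
    stop("count table needs columns ", paste(need, collapse = ", "))
  }
  if (mode == "per_section") {
    nsec <- aggregate(section_index ~ animal_id, table,
                      function(s) length(unique(s)))
    names(nsec)[2] <- "n_sections"
    tot <- aggregate(raw_count ~ animal_id + genotype + region_id, table, sum)
    names(tot)[4] <- "total_count"
    out <- merge(tot, nsec, by = "animal_id")
    out$per_section <- out$total_count / out$n_sections
    out <- out[order(out$animal_id, out$region_id), ]
    rownames(out) <- NULL
    return(out)
  }
  # MS_percentage
  sub <- table[table$region_id %in% c(m_region, s_region), ]
  tot <- aggregate(raw_count ~ animal_id + genotype + region_id, sub, sum)
  out <- do.call(rbind, lapply(split(tot, tot$animal_id), function(d) {
    m <- sum(d$raw_count[d$region_id == m_region])
    s <- sum(d$raw_count[d$region_id == s_region])
    if (m + s == 0) {
      stop("animal ", d$animal_id[1],
           ": zero total count in M and S regions; cannot form percentages")
    }
    data.frame(animal_id = d$animal_id[1], genotype = d$genotype[1],
               region_id = c(m_region, s_region),
               count = c(m, s),
               pct = 100 * c(m, s) / (m + s),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
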