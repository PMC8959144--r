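#' Specify a synthetic serial-section set
#'
#' Describes a set of sagittal cortical sections with cells planted at
#' known positions inside colour-coded atlas regions.  Each planted cell
#' is an isotropic Gaussian blob truncated at its nominal radius (3
#' standard deviations), which yields near-unity circularity after
#' thresholding.  Planted centres are separated by at least
#' `2 * blob_radius_px + 1` pixels so that detected components map
#' one-to-one onto planted cells, making the planted counts an exact
#' oracle for the counting pipeline.
#'
#' @param regions a [region_map()] augmented with a `mask` list-column
#'   (one logical matrix per region, all of dimension `image_shape`), or
#'   the result of [cortical_section_spec()]'s default strip layout.
#' @param planted_counts named integer vector: cells to plant per region
#'   per section; names must match `regions$region_id`.
#' @param image_shape integer length-2, rows x columns.
#' @param pixel_size micrometres per pixel.
#' @param n_sections number of serial sections.
#' @param section_spacing micrometres between consecutive sections.
#' @param blob_radius_px truncation radius of a planted cell, in pixels.
#' @param blob_peak peak intensity of a planted cell above background.
#' @param background_level constant background intensity.
#' @param background_gradient background slope along columns
#'   (intensity per pixel), emulating uneven illumination.
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (clipped to the bit range).
#' @param bit_depth 8 or 16.
#' @param seed integer seed; generation is deterministic given the spec
#'   and seed.
#' @return a `section_spec` object.
#' @seealso [make_section_set()]
#' @export
section_spec <- function(regions, planted_counts, image_shape,
                         pixel_size = 5, n_sections = 1L,
                         section_spacing = 100, blob_radius_px = 4L,
                         blob_peak = 30000, background_level = 2000,
                         background_gradient = 0, noise_sd = 0,
                         bit_depth = 16L, seed = 1L) {
  stopifnot(is.data.frame(regions), !is.null(regions$mask))
  if (is.null(names(planted_counts)) ||
      !all(names(planted_counts) %in% regions$region_id)) {
    stop("planted_counts must be named by region_id")
  }
  if (any(planted_counts < 0)) stop("planted counts must be >= 0")
  if (noise_sd > 0 && blob_peak <= 3 * noise_sd) {
    warning("blob_peak <= 3 * noise_sd: planted cells may be undetectable")
  }
  shape <- as.integer(image_shape)
  for (m in regions$mask) {
    if (!identical(dim(m), shape)) stop("region masks must match image_shape")
  }
  structure(list(regions = regions,
                 planted_counts = planted_counts,
                 image_shape = shape, pixel_size = pixel_size,
                 n_sections = as.integer(n_sections),
                 section_spacing = section_spacing,
                 blob_radius_px = as.integer(blob_radius_px),
                 blob_peak = blob_peak,
                 background_level = background_level,
                 background_gradient = background_gradient,
                 noise_sd = noise_sd, bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "section_spec")
}

#' Default seven-area sagittal section layout
#'
#' Builds a [section_spec()] whose atlas plate consists of seven vertical
#' strips spanning the image, emulating the rostro-caudal sequence of
#' cortical areas seen on a lateral sagittal section: prefrontal (PFC),
#' motor (M), somatosensory (S), auditory (A), visual (V), retrosplenial
#' (RSC) and gustatory (GC) cortex.  The default planted counts follow a
#' control-like gradient with motor/somatosensory dominance; pass a
#' flat vector to emulate a gradient-flattened mutant.
#'
#' @param planted_counts named integer vector over the seven areas;
#'   defaults to a graded control-like profile.
#' @param image_shape rows x columns; columns are split into 7 strips.
#' @param ... further arguments passed to [section_spec()].
#' @return a `section_spec`.
#' @export
cortical_section_spec <- function(planted_counts = c(PFC = 12, M = 40,
                                                     S = 28, A = 18, V = 14,
                                                     RSC = 8, GC = 10),
                                  image_shape = c(600L, 1400L), ...) {
  ids <- c("PFC", "M", "S", "A", "V", "RSC", "GC")
  cols <- rbind(c(230, 60, 60), c(60, 130, 230), c(60, 200, 120),
                c(230, 180, 40), c(170, 80, 220), c(240, 120, 180),
                c(90, 210, 230))
  rmap <- region_map(ids, ids, cols[, 1], cols[, 2], cols[, 3])
  h <- image_shape[1]; w <- image_shape[2]
  edges <- round(seq(0, w, length.out = 8))
  rmap$mask <- lapply(seq_len(7), function(i) {
    m <- matrix(FALSE, h, w)
    m[, (edges[i] + 1):edges[i + 1]] <- TRUE
    m
  })
  section_spec(regions = rmap, planted_counts = planted_counts,
               image_shape = image_shape, ...)
}

# internal: dart-throwing placement of blob centres with a global
# minimum separation; errors out if the region cannot hold the count.
place_centres <- function(masks, counts, radius, shape, max_attempts = 400L) {
  min_sep2 <- (2 * radius + 1)^2
  all_r <- numeric(0); all_c <- numeric(0); all_region <- character(0)
  for (rid in names(counts)) {
    n <- counts[[rid]]
    if (n == 0) next
    m <- masks[[rid]]
    cand <- which(m, arr.ind = TRUE)
    # keep blobs fully inside the image
    cand <- cand[cand[, 1] > radius & cand[, 1] <= shape[1] - radius &
                 cand[, 2] > radius & cand[, 2] <= shape[2] - radius, ,
                 drop = FALSE]
    if (nrow(cand) == 0) {
      stop("region ", rid, " too small for blob radius ", radius)
    }
    placed <- 0L
    attempts <- 0L
    while (placed < n) {
      if (attempts >= max_attempts * n) {
        stop("could not place ", n, " non-overlapping cells in region ", rid,
             " (blob radius ", radius, " px); reduce counts or radius")
      }
      attempts <- attempts + 1L
      i <- cand[sample.int(nrow(cand), 1L), ]
      if (length(all_r)) {
        d2 <- (all_r - i[1])^2 + (all_c - i[2])^2
        if (min(d2) < min_sep2) next
      }
      all_r <- c(all_r, i[1]); all_c <- c(all_c, i[2])
      all_region <- c(all_region, rid)
      placed <- placed + 1L
    }
  }
  data.frame(row = all_r, col = all_c, region_id = all_region,
             stringsAsFactors = FALSE)
}

# internal: render one truncated-Gaussian blob patch (sigma = radius/3)
blob_patch <- function(radius, peak) {
  d <- (-radius):radius
  g <- outer(d^2, d^2, "+")
  sigma <- radius / 3
  p <- peak * exp(-g / (2 * sigma^2))
  p[g > radius^2] <- 0
  p
}

#' Generate a synthetic serial-section set with planted ground truth
#'
#' Renders the section images, the matching colour-coded atlas plates,
#' the colour lookup table and a ground-truth count table.  Each planted
#' cell is a radially symmetric blob whose centre lies inside its
#' assigned region; the ground truth records the exact number of planted
#' cells per region per section.  Generation is deterministic given the
#' spec (including its seed).
#'
#' @param spec a [section_spec()].
#' @return a list with elements
#'   * `images`: list of [section_image()], one per section;
#'   * `plates`: list of [atlas_plate()] (identical layout per section);
#'   * `region_map`: the colour lookup table;
#'   * `ground_truth`: data frame `(section_index, region_id,
#'     planted_count)`;
#'   * `centres`: data frame of planted centres
#'     `(section_index, row, col, region_id)`.
#' @export
make_section_set <- function(spec) {
  stopifnot(inherits(spec, "section_spec"))
  shape <- spec$image_shape
  masks <- setNames(spec$regions$mask, spec$regions$region_id)
  maxval <- 2^spec$bit_depth - 1
  patch <- blob_patch(spec$blob_radius_px, spec$blob_peak)
  r <- spec$blob_radius_px

  plate_arr <- array(0L, dim = c(shape, 3L))
  for (i in seq_len(nrow(spec$regions))) {
    m <- masks[[i]]
    plate_arr[, , 1][m] <- spec$regions$r[i]
    plate_arr[, , 2][m] <- spec$regions$g[i]
    plate_arr[, , 3][m] <- spec$regions$b[i]
  }
  plate <- atlas_plate(plate_arr)

  base_bg <- spec$background_level +
    spec$background_gradient * matrix(rep(seq_len(shape[2]) - 1, each = shape[1]),
                                      shape[1], shape[2])

  out <- withr::with_seed(spec$seed, {
    images <- vector("list", spec$n_sections)
    centres <- vector("list", spec$n_sections)
    for (s in seq_len(spec$n_sections)) {
      ctr <- place_centres(masks, spec$planted_counts, r, shape)
      img <- base_bg
      for (k in seq_len(nrow(ctr))) {
        rr <- (ctr$row[k] - r):(ctr$row[k] + r)
        cc <- (ctr$col[k] - r):(ctr$col[k] + r)
        img[rr, cc] <- img[rr, cc] + patch
      }
      if (spec$noise_sd > 0) {
        img <- img + rnorm(length(img), 0, spec$noise_sd)
      }
      img <- pmin(pmax(img, 0), maxval)
      ctr$section_index <- rep(s, nrow(ctr))
      images[[s]] <- section_image(img, spec$pixel_size, spec$bit_depth,
                                   section_index = s,
                                   medio_lateral_pos =
                                     (s - 1) * spec$section_spacing)
      centres[[s]] <- ctr
    }
    list(images = images, centres = do.call(rbind, centres))
  })

  gt <- expand.grid(region_id = spec$regions$region_id,
                    section_index = seq_len(spec$n_sections),
                    stringsAsFactors = FALSE)
  gt$planted_count <- as.integer(spec$planted_counts[gt$region_id])
  gt$planted_count[is.na(gt$planted_count)] <- 0L
  gt <- gt[order(gt$section_index, gt$region_id),
           c("section_index", "region_id", "planted_count")]
  rownames(gt) <- NULL

  rmap <- spec$regions
  rmap$mask <- NULL
  class(rmap) <- c("region_map", "data.frame")

  list(images = out$images,
       plates = rep(list(plate), spec$n_sections),
       region_map = rmap,
       ground_truth = gt,
       centres = out$centres)
}
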