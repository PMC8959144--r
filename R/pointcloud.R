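#' Semi-quantitatively record labelling density as points
#'
#' Converts a per-section signal-density map into a set of point
#' coordinates whose local count reflects the observed labelling
#' density: each pixel emits a Poisson number of points with rate
#' `density * points_per_unit`, placed uniformly within the pixel and
#' assigned the section's z-plane.  This emulates annotating axonal
#' labelling in section images as dot maps.
#'
#' @param density_map non-negative numeric matrix (rows = y, dorso-
#'   ventral; columns = x, rostro-caudal) of observed signal density.
#' @param points_per_unit expected points per unit density per pixel.
#' @param pixel_size micrometres per pixel.
#' @param section_index serial index of the section.
#' @param section_spacing micrometres between sections; the section's
#'   z-plane is `section_index * section_spacing`.
#' @param density_breaks increasing cut points mapping density to the
#'   ordinal `density_class` (default: terciles of the positive range,
#'   classes 1..3 for low/medium/high).
#' @param group group label stored with the points.
#' @param seed integer seed; recording is deterministic given the seed.
#' @return a [point_cloud3d()].
#' @export
record_points <- function(density_map, points_per_unit, pixel_size = 5,
                          section_index = 1L, section_spacing = 100,
                          density_breaks = NULL, group = "control",
                          seed = NULL) {
  if (any(density_map < 0)) stop("density map must be non-negative")
  draw <- function() {
    lambda <- density_map * points_per_unit
    n <- rpois(length(lambda), lambda)
    idx <- which(n > 0)
    if (length(idx) == 0) {
      return(point_cloud3d(numeric(0), numeric(0), numeric(0),
                           integer(0), character(0), integer(0)))
    }
    reps <- n[idx]
    rows <- ((idx - 1) %% nrow(density_map)) + 1
    cols <- ((idx - 1) %/% nrow(density_map)) + 1
    rr <- rep(rows, reps)
    cc <- rep(cols, reps)
    m <- length(rr)
    x <- (cc - 1 + runif(m)) * pixel_size
    y <- (rr - 1 + runif(m)) * pixel_size
    z <- rep(section_index * section_spacing, m)
    dmax <- max(density_map)
    breaks <- if (is.null(density_breaks)) {
      c(-Inf, dmax / 3, 2 * dmax / 3, Inf)
    } else {
      c(-Inf, density_breaks, Inf)
    }
    dc <- as.integer(cut(rep(density_map[idx], reps), breaks))
    point_cloud3d(x, y, z, density_class = dc, group = group,
                  source_section = section_index)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Randomly displace z-coordinates within the inter-section gap
#'
#' Points recorded from serial sections share the z-coordinate of their
#' section plane; to allow inspection of the 3D distribution
#' perpendicular to the sectioning angle, each point's z is displaced
#' randomly within the thickness of the gap between sections.  x and y
#' are untouched, the displacement is uniform, and a gap of 0 is the
#' identity.
#'
#' @param cloud a [point_cloud3d()].
#' @param gap inter-section gap in micrometres (`>= 0`).
#' @param seed integer seed; jitter is deterministic given the seed.
#' @param mode `"centred"` (default): displacement uniform on
#'   `(-gap/2, +gap/2)` around the section plane; `"forward"`:
#'   uniform on `[0, gap)` towards the next section.
#' @return the jittered cloud; point count, order, x, y and all labels
#'   are preserved exactly.
#' @export
jitter_z <- function(cloud, gap, seed = NULL,
                     mode = c("centred", "forward")) {
  mode <- match.arg(mode)
  if (gap < 0) stop("gap must be >= 0")
  if (gap == 0) return(cloud)
  n <- nrow(cloud)
  u <- if (is.null(seed)) runif(n) else withr::with_seed(seed, runif(n))
  dz <- if (mode == "centred") (u - 0.5) * gap else u * gap
  cloud$z_um <- cloud$z_um + dz
  cloud
}

#' Cut a digital slab slice through a point cloud
#'
#' Keeps the points whose coordinate along the slab normal falls in
#' `[centre - thickness/2, centre + thickness/2)`.  The half-open
#' interval makes a set of slabs tiling the axis a partition: every
#' point belongs to exactly one slab.
#'
#' @param cloud a [point_cloud3d()].
#' @param slab a [slab_spec()].
#' @return the subset cloud, all per-point attributes preserved.
#' @export
slice_points <- function(cloud, slab) {
  stopifnot(inherits(slab, "slab_spec"))
  coord <- switch(slab$axis,
                  sagittal = cloud$z_um,
                  frontal = cloud$x_um,
                  horizontal = cloud$y_um)
  lo <- slab$centre - slab$thickness / 2
  hi <- slab$centre + slab$thickness / 2
  out <- cloud[coord >= lo & coord < hi, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Centroid shift between two point clouds
#'
#' Component-wise difference of centroids (B minus A) in micrometres,
#' with percentile bootstrap confidence intervals, quantifying e.g. a
#' rostral or medial displacement of one group's projection territory
#' relative to another's.
#'
#' @param cloud_a,cloud_b non-empty [point_cloud3d()]s (A = reference,
#'   B = comparison group).
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return list with `shift` (named `dx, dy, dz`), `ci` (2 x 3 matrix of
#'   lower/upper bounds) and `n` (the two cloud sizes).
#' @export
centroid_shift <- function(cloud_a, cloud_b, n_boot = 1000L, conf = 0.95,
                           seed = NULL) {
  if (nrow(cloud_a) == 0 || nrow(cloud_b) == 0) {
    stop("cannot compute a centroid shift from an empty cloud")
  }
  ma <- as.matrix(cloud_a[, c("x_um", "y_um", "z_um")])
  mb <- as.matrix(cloud_b[, c("x_um", "y_um", "z_um")])
  shift <- colMeans(mb) - colMeans(ma)
  names(shift) <- c("dx", "dy", "dz")
  boot <- function() {
    na <- nrow(ma); nb <- nrow(mb)
    reps <- matrix(NA_real_, n_boot, 3)
    for (i in seq_len(n_boot)) {
      ia <- sample.int(na, na, replace = TRUE)
      ib <- sample.int(nb, nb, replace = TRUE)
      reps[i, ] <- colMeans(mb[ib, , drop = FALSE]) -
        colMeans(ma[ia, , drop = FALSE])
    }
    reps
  }
  reps <- if (is.null(seed)) boot() else withr::with_seed(seed, boot())
  alpha <- (1 - conf) / 2
  ci <- apply(reps, 2, quantile, probs = c(alpha, 1 - alpha))
  colnames(ci) <- c("dx", "dy", "dz")
  list(shift = shift, ci = ci, n = c(a = nrow(ma), b = nrow(mb)))
}

#' Density-overlap score of two point clouds within a region
#'
#' Voxelizes both clouds on a common grid restricted to a region volume,
#' normalizes each voxel histogram to unit mass, and returns the
#' histogram intersection: 1 for identical densities, 0 for
#' disjoint-support densities.  Useful for comparing how much of one
#' group's projection territory is shared by another (e.g. depletion of
#' a central core).
#'
#' @param cloud_a,cloud_b non-empty [point_cloud3d()]s.
#' @param volume a [region_volume()]; points outside its mask are
#'   ignored.
#' @param voxel voxel edge for the comparison grid in micrometres
#'   (default: the volume's own voxel size).
#' @return overlap score in `[0, 1]`.
#' @export
density_overlap <- function(cloud_a, cloud_b, volume, voxel = NULL) {
  stopifnot(inherits(volume, "region_volume"))
  if (nrow(cloud_a) == 0 || nrow(cloud_b) == 0) {
    stop("cannot compare empty clouds")
  }
  if (is.null(voxel)) voxel <- volume$voxel_size
  if (voxel <= 0) stop("voxel must be positive")
  d <- dim(volume$mask)
  extent <- d * volume$voxel_size
  nbin <- ceiling(extent / voxel)
  voxelize <- function(cloud) {
    xyz <- as.matrix(cloud[, c("x_um", "y_um", "z_um")])
    keep <- in_volume(volume, xyz)
    xyz <- xyz[keep, , drop = FALSE]
    if (nrow(xyz) == 0) return(NULL)
    idx <- sweep(xyz, 2, volume$origin)
    idx <- pmin(floor(idx / voxel) + 1, matrix(nbin, nrow(idx), 3,
                                               byrow = TRUE))
    key <- (idx[, 1] - 1) + nbin[1] * ((idx[, 2] - 1) +
                                         nbin[2] * (idx[, 3] - 1))
    tab <- table(key)
    h <- setNames(as.numeric(tab), names(tab))
    h / sum(h)
  }
  ha <- voxelize(cloud_a)
  hb <- voxelize(cloud_b)
  if (is.null(ha) || is.null(hb)) return(0)
  common <- intersect(names(ha), names(hb))
  if (length(common) == 0) return(0)
  sum(pmin(ha[common], hb[common]))
}
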