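#' Ellipsoidal pontine-nuclei-like region volume
#'
#' A convenient voxelized ellipsoid standing in for the pontine nuclei
#' when testing point-cloud analyses.  The ellipsoid is centred at
#' `centre` with the given semi-axes; the voxel grid covers its bounding
#' box.
#'
#' @param semi_axes numeric length-3, semi-axis lengths in micrometres
#'   along x (rostro-caudal), y (dorso-ventral) and z (medio-lateral).
#'   Defaults approximate the extent of the mouse pontine nuclei.
#' @param centre numeric length-3 centre in micrometres.
#' @param voxel_size voxel edge in micrometres.
#' @return a [region_volume()].
#' @export
ellipsoid_volume <- function(semi_axes = c(600, 400, 500),
                             centre = c(0, 0, 0), voxel_size = 25) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0))
  n <- ceiling(2 * semi_axes / voxel_size) + 2
  origin <- centre - n / 2 * voxel_size
  ax <- lapply(1:3, function(i) {
    origin[i] + (seq_len(n[i]) - 0.5) * voxel_size
  })
  dx <- (ax[[1]] - centre[1]) / semi_axes[1]
  dy <- (ax[[2]] - centre[2]) / semi_axes[2]
  dz <- (ax[[3]] - centre[3]) / semi_axes[3]
  mask <- outer(outer(dx^2, dy^2, "+"), dz^2, "+") <= 1
  region_volume(mask, voxel_size, origin)
}

#' Specify synthetic corticopontine point clouds
#'
#' Describes clustered point clouds inside a pontine-nuclei-like volume,
#' with a known translation applied to a second ("mutant") group.  Both
#' groups are drawn from the same Gaussian-mixture generative process;
#' the mutant process is translated by `group_shift`, and points falling
#' outside the volume are rejected and resampled so both groups remain
#' valid point processes on the same support.
#'
#' @param volume a [region_volume()]; cluster centres must lie inside.
#' @param clusters list of clusters, each a list with `centre` (length-3
#'   micrometre vector), `sd` (scalar or length-3 isotropic/axis-wise
#'   standard deviation, or a 3x3 covariance matrix as `cov`),
#'   `n_points` (> 0) and optional `density_class` (default 1).
#' @param group_shift numeric length-3 translation (micrometres) applied
#'   to the shifted group.
#' @param section_spacing micrometres between recorded sections; points
#'   are snapped to section planes along z, emulating recording from
#'   serial 2D sections.
#' @param seed integer seed.
#' @return a `cloud_spec` object.
#' @seealso [make_pointclouds()]
#' @export
cloud_spec <- function(volume, clusters, group_shift = c(0, 0, 0),
                       section_spacing = 100, seed = 1L) {
  stopifnot(inherits(volume, "region_volume"), length(group_shift) == 3)
  for (cl in clusters) {
    if (is.null(cl$centre) || length(cl$centre) != 3) {
      stop("each cluster needs a length-3 centre")
    }
    if (is.null(cl$n_points) || cl$n_points <= 0) {
      stop("each cluster needs n_points > 0")
    }
    if (!in_volume(volume, matrix(cl$centre, 1))) {
      stop("cluster centre outside the region volume")
    }
  }
  structure(list(volume = volume, clusters = clusters,
                 group_shift = as.numeric(group_shift),
                 section_spacing = as.numeric(section_spacing),
                 seed = as.integer(seed)),
            class = "cloud_spec")
}

# internal: sample one cluster by rejection; points are snapped to
# section planes along z before the volume-membership test so that the
# returned (snapped) coordinates always lie inside the volume.
sample_cluster <- function(cl, shift, volume, spacing, max_rounds = 200L) {
  n <- cl$n_points
  if (!is.null(cl$cov)) {
    sigma <- cl$cov
  } else {
    sdv <- rep_len(if (is.null(cl$sd)) 100 else cl$sd, 3)
    sigma <- diag(sdv^2)
  }
  mu <- cl$centre + shift
  pts <- matrix(numeric(0), 0, 3)
  rounds <- 0L
  while (nrow(pts) < n) {
    if (rounds >= max_rounds) {
      stop("cluster sampling failed: almost no probability mass inside the ",
           "volume (is the group shift too large?)")
    }
    rounds <- rounds + 1L
    cand <- MASS::mvrnorm(n, mu = mu, Sigma = sigma)
    if (!is.matrix(cand)) cand <- matrix(cand, 1)
    cand[, 3] <- round(cand[, 3] / spacing) * spacing
    cand <- cand[in_volume(volume, cand), , drop = FALSE]
    pts <- rbind(pts, cand)
  }
  pts[seq_len(n), , drop = FALSE]
}

#' Generate control and shifted point clouds with known ground truth
#'
#' Draws the control cloud from the cluster mixture of a [cloud_spec()]
#' and the shifted ("mutant") cloud from the same process translated by
#' `group_shift`, both restricted to the region volume by rejection
#' sampling.  The z-coordinate of every point is snapped to the nearest
#' section plane (`z = k * section_spacing`), emulating semi-quantitative
#' recording from serial 2D sections; [jitter_z()] undoes this
#' discretization for 3D visualization.
#'
#' @param spec a [cloud_spec()].
#' @return a list with
#'   * `control`, `shifted`: [point_cloud3d()] data frames;
#'   * `ground_truth_shift`: the planted translation (micrometres).
#' @export
make_pointclouds <- function(spec) {
  stopifnot(inherits(spec, "cloud_spec"))
  draw_group <- function(shift, label) {
    parts <- lapply(spec$clusters, function(cl) {
      pts <- sample_cluster(cl, shift, spec$volume, spec$section_spacing)
      dc <- if (is.null(cl$density_class)) 1L else as.integer(cl$density_class)
      data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 density_class = dc)
    })
    df <- do.call(rbind, parts)
    point_cloud3d(df$x, df$y, df$z,
                  density_class = df$density_class, group = label,
                  source_section = as.integer(round(df$z /
                                                      spec$section_spacing)))
  }
  control <- withr::with_seed(spec$seed, draw_group(c(0, 0, 0), "control"))
  shifted <- withr::with_seed(spec$seed,
                              draw_group(spec$group_shift, "shifted"))
  list(control = control, shifted = shifted,
       ground_truth_shift = spec$group_shift)
}
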