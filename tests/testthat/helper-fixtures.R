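# Shared fixtures and independent brute-force oracles.

# two-region vertical-split plate + map, for small ROI tests
tiny_two_region <- function(h = 40, w = 60) {
  rmap <- region_map(c("A", "B"), c("regA", "regB"),
                     r = c(200, 0), g = c(0, 200), b = c(0, 0))
  maskA <- matrix(FALSE, h, w); maskA[, 1:(w / 2)] <- TRUE
  maskB <- matrix(FALSE, h, w); maskB[, (w / 2 + 1):w] <- TRUE
  rmap$mask <- list(maskA, maskB)
  rmap
}

# rasterized disk mask: pixels with (r-cr)^2 + (c-cc)^2 <= radius^2
raster_disk <- function(shape, centre, radius) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (r in seq_len(shape[1])) {
    for (c in seq_len(shape[2])) {
      if ((r - centre[1])^2 + (c - centre[2])^2 <= radius^2) m[r, c] <- TRUE
    }
  }
  m
}

# 1-px-wide line mask of given length, horizontal
raster_line <- function(shape, start, length) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[start[1], start[2]:(start[2] + length - 1)] <- TRUE
  m
}

# brute-force grayscale opening with a disk: erosion (min over the
# translated kernel, ignoring out-of-image offsets) then dilation (max),
# the textbook definition computed by direct double loops
oracle_opening <- function(img, radius) {
  off <- which(outer((-radius):radius, (-radius):radius,
                     function(a, b) a^2 + b^2) <= radius^2, arr.ind = TRUE)
  off <- off - radius - 1  # offsets in -radius..radius
  h <- nrow(img); w <- ncol(img)
  ero <- matrix(Inf, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    rr <- r + off[, 1]; cc <- c + off[, 2]
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    ero[r, c] <- min(img[cbind(rr[ok], cc[ok])])
  }
  dil <- matrix(-Inf, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    rr <- r + off[, 1]; cc <- c + off[, 2]
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    dil[r, c] <- max(ero[cbind(rr[ok], cc[ok])])
  }
  dil
}

# independent boundary-walk perimeter: Moore-neighbour tracing written
# directly in R over a single-object mask (TRUE = object)
oracle_perimeter <- function(mask) {
  if (sum(mask) == 1) return(4)
  nr <- nrow(mask); nc <- ncol(mask)
  inside <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  # first object pixel in column-major order
  idx <- which(mask)
  r0 <- ((idx[1] - 1) %% nr) + 1
  c0 <- ((idx[1] - 1) %/% nr) + 1
  dr <- c(0, -1, -1, -1, 0, 1, 1, 1)
  dc <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  stp <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))
  r <- r0; c <- c0; back <- 1  # came from W
  len <- 0; first <- NULL
  repeat {
    k <- (back %% 8) + 1
    found <- NA
    for (i in 0:7) {
      kk <- ((k - 1 + i) %% 8) + 1
      if (inside(r + dr[kk], c + dc[kk])) { found <- kk; break }
    }
    state <- c(r, c, found)
    if (is.null(first)) first <- state
    else if (all(state == first)) break
    r <- r + dr[found]; c <- c + dc[found]
    len <- len + stp[found]
    back <- ((found - 1 + 4) %% 8) + 1
  }
  len
}

# small pontine-like cloud spec used across point-cloud tests
small_cloud_spec <- function(n = 2000, shift = c(0, 0, 0), seed = 1,
                             spacing = 100) {
  vol <- ellipsoid_volume(semi_axes = c(600, 400, 500), voxel_size = 25)
  cloud_spec(vol,
             clusters = list(
               list(centre = c(-100, 0, 0), sd = 120, n_points = ceiling(n / 2),
                    density_class = 3),
               list(centre = c(150, 50, -50), sd = 100,
                    n_points = floor(n / 2), density_class = 1)),
             group_shift = shift, section_spacing = spacing, seed = seed)
}
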