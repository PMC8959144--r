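make_plate <- function(rmap, shape) {
  arr <- array(0L, dim = c(shape, 3L))
  for (i in seq_len(nrow(rmap))) {
    m <- rmap$mask[[i]]
    arr[, , 1][m] <- rmap$r[i]
    arr[, , 2][m] <- rmap$g[i]
    arr[, , 3][m] <- rmap$b[i]
  }
  atlas_plate(arr)
}

test_that("two-colour plates partition into two exact masks", {
  rmap <- tiny_two_region()
  plate <- make_plate(rmap, c(40L, 60L))
  rois <- extract_rois(plate, rmap)
  expect_named(rois, c("A", "B"))
  expect_equal(sum(rois$A), 40 * 30)
  expect_equal(sum(rois$B), 40 * 30)
  expect_false(any(rois$A & rois$B))
  expect_true(all(rois$A | rois$B))
  expect_equal(attr(rois, "n_unassigned"), 0)
  # per-mask pixel counts equal the generator masks exactly
  expect_equal(rois$A, rmap$mask[[1]])
  expect_equal(rois$B, rmap$mask[[2]])
})

test_that("unmapped plate colours are reported as unassigned, not fatal", {
  rmap <- tiny_two_region()
  plate <- make_plate(rmap, c(40L, 60L))
  p <- unclass(plate)
  p[1:5, 1:5, 1] <- 10L; p[1:5, 1:5, 2] <- 10L; p[1:5, 1:5, 3] <- 10L
  rois <- extract_rois(atlas_plate(p), rmap)
  expect_equal(attr(rois, "n_unassigned"), 25)
  expect_equal(sum(attr(rois, "unassigned")[1:5, 1:5]), 25)
  expect_equal(sum(rois$A), 40 * 30 - 25)
})

test_that("top-hat maps flat fields to zero and preserves blobs", {
  flat <- section_image(matrix(5000, 60, 60), pixel_size = 5)
  out <- subtract_background(flat, 8)
  expect_true(all(abs(unclass(out)) < 1))

  # blob on constant background: peak preserved within 5% and the result
  # matches the brute-force opening oracle
  img <- matrix(2000, 50, 50)
  blob <- raster_disk(c(50, 50), c(25, 25), 4)
  img[blob] <- 20000
  si <- section_image(img, pixel_size = 5)
  out <- subtract_background(si, 12)
  expect_gt(max(unclass(out)), 0.95 * 18000)
  oracle <- img - oracle_opening(img, 12)
  expect_lt(max(abs(unclass(out) - oracle)) / 18000, 0.05)

  # linear ramp + blob: residual background below 10% of blob amplitude
  ramp <- matrix(rep(seq(1000, 4000, length.out = 60), each = 60), 60, 60)
  ramp[raster_disk(c(60, 60), c(30, 30), 4)] <- 25000
  out <- subtract_background(section_image(ramp, pixel_size = 5), 12)
  bg <- unclass(out)[!raster_disk(c(60, 60), c(30, 30), 8)]
  expect_lt(max(bg), 0.10 * 25000)
})

test_that("oversized structuring elements are rejected", {
  expect_error(subtract_background(section_image(matrix(0, 20, 20), 5), 15),
               "larger than the image")
  expect_error(subtract_background(section_image(matrix(0, 20, 20), 5), 0),
               ">= 1")
})

test_that("detection finds exactly the suprathreshold components", {
  zero <- section_image(matrix(0, 30, 30), pixel_size = 5)
  expect_equal(nrow(detect_objects(zero, 100)), 0)

  img <- matrix(0, 40, 80)
  img[raster_disk(c(40, 80), c(15, 20), 5)] <- 10000
  img[raster_disk(c(40, 80), c(25, 60), 5)] <- 10000
  objs <- detect_objects(section_image(img, 5), 5000)
  expect_equal(nrow(objs), 2)
  expect_equal(objs$mean_intensity, c(10000, 10000))
})

test_that("disk area and circularity match the brute-force oracle", {
  img <- matrix(0, 40, 40)
  disk <- raster_disk(c(40, 40), c(20, 20), 6)
  img[disk] <- 10000
  objs <- detect_objects(section_image(img, 5), 5000)
  expect_equal(objs$area, sum(disk)) # brute-force pixel count
  oracle_circ <- min(1, 4 * pi * sum(disk) / oracle_perimeter(disk)^2)
  expect_lt(abs(objs$circularity - oracle_circ), 0.1)
  expect_equal(objs$perimeter, oracle_perimeter(disk))
})

test_that("circularity gate keeps disks and rejects thin lines", {
  expect_equal(nrow(filter_by_circularity(
    detect_objects(section_image(matrix(0, 10, 10), 5), 1))), 0)

  withr::with_seed(42, {
    for (i in 1:25) {
      rad <- sample(4:9, 1)
      sz <- 2 * rad + 9
      img <- matrix(0, sz, sz)
      disk <- raster_disk(c(sz, sz), c(rad + 5, rad + 5), rad)
      img[disk] <- 10000
      objs <- detect_objects(section_image(img, 5), 5000)
      expect_gte(objs$circularity, 0.5)
      expect_equal(nrow(filter_by_circularity(objs)), 1)
    }
    for (i in 1:25) {
      len <- sample(10:30, 1)
      img <- matrix(0, 12, len + 10)
      img[raster_line(c(12, len + 10), c(6, 5), len)] <- 10000
      objs <- detect_objects(section_image(img, 5), 5000)
      expect_lt(objs$circularity, 0.5)
      expect_equal(nrow(filter_by_circularity(objs)), 0)
    }
  })
})

test_that("raising the threshold never increases the object count", {
  sp <- cortical_section_spec(planted_counts = c(M = 15, S = 10, V = 5),
                              image_shape = c(250L, 500L),
                              noise_sd = 1500, seed = 8)
  ss <- make_section_set(sp)
  corrected <- subtract_background(ss$images[[1]])
  counts <- vapply(seq(4000, 28000, by = 2000),
                   function(th) nrow(detect_objects(corrected, th)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("objects are assigned to regions by centroid, with conservation", {
  rmap <- tiny_two_region()
  plate <- make_plate(rmap, c(40L, 60L))
  rois <- extract_rois(plate, rmap)
  img <- matrix(0, 40, 60)
  img[raster_disk(c(40, 60), c(20, 10), 3)] <- 10000  # inside A
  img[raster_disk(c(40, 60), c(20, 45), 3)] <- 10000  # inside B
  objs <- detect_objects(section_image(img, 5), 5000)
  tab <- count_per_region(objs, rois, section_index = 7L)
  expect_equal(tab$raw_count[tab$region_id == "A"], 1)
  expect_equal(tab$raw_count[tab$region_id == "B"], 1)
  expect_equal(sum(tab$raw_count), nrow(objs))
  expect_true(all(tab$section_index == 7L))

  # centroid on an unmapped colour lands in the unassigned bucket
  p2 <- unclass(plate)
  p2[15:25, 5:15, ] <- 33L
  rois2 <- extract_rois(atlas_plate(p2), rmap)
  tab2 <- count_per_region(objs, rois2)
  expect_equal(tab2$raw_count[tab2$region_id == "unassigned"], 1)
  expect_equal(sum(tab2$raw_count), nrow(objs))
})

test_that("the full pipeline recovers planted counts exactly without noise", {
  sp <- cortical_section_spec(planted_counts = c(M = 50, S = 20),
                              image_shape = c(300L, 700L),
                              noise_sd = 0, seed = 21)
  ss <- make_section_set(sp)
  tab <- count_section(ss$images[[1]], ss$plates[[1]], ss$region_map,
                       threshold = 15000)
  expect_equal(tab$raw_count[tab$region_id == "M"], 50)
  expect_equal(tab$raw_count[tab$region_id == "S"], 20)
  expect_equal(tab$raw_count[tab$region_id == "unassigned"], 0)
  expect_equal(sum(tab$raw_count), 70)
})

test_that("count normalizations match their definitions", {
  tab <- data.frame(animal_id = rep(c("a1", "a2"), each = 4),
                    genotype = rep(c("ctrl", "mut"), each = 4),
                    section_index = rep(1:2, 4),
                    region_id = rep(c("M", "S"), 4),
                    raw_count = c(10, 20, 20, 50, 5, 5, 10, 10))
  ms <- normalize_counts(tab, "MS_percentage")
  a1 <- ms[ms$animal_id == "a1", ]
  expect_equal(a1$pct[a1$region_id == "M"], 30)
  expect_equal(a1$pct[a1$region_id == "S"], 70)
  a2 <- ms[ms$animal_id == "a2", ]
  expect_equal(a2$pct, c(50, 50))
  expect_equal(sum(a1$pct), 100)

  tab2 <- data.frame(animal_id = "a1", genotype = "ctrl",
                     section_index = rep(1:8, each = 1),
                     region_id = "M", raw_count = 5)
  ps <- normalize_counts(tab2, "per_section")
  expect_equal(ps$total_count, 40)
  expect_equal(ps$n_sections, 8)
  expect_equal(ps$per_section, 5)

  tab3 <- data.frame(animal_id = "a1", genotype = "ctrl", section_index = 1,
                     region_id = c("M", "S"), raw_count = c(0, 0))
  expect_error(normalize_counts(tab3, "MS_percentage"), "a1")
})
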