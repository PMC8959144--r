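test_that("zero planted counts give blank images and all-zero truth", {
  rmap <- tiny_two_region()
  sp <- section_spec(rmap, c(A = 0, B = 0), image_shape = c(40L, 60L),
                     noise_sd = 0, background_level = 0, seed = 1)
  ss <- make_section_set(sp)
  expect_true(all(unclass(ss$images[[1]]) == 0))
  expect_true(all(ss$ground_truth$planted_count == 0))
  expect_equal(nrow(ss$centres), 0)
})

test_that("section generation is deterministic given the seed", {
  sp <- cortical_section_spec(planted_counts = c(M = 20, S = 10),
                              image_shape = c(200L, 350L),
                              noise_sd = 800, seed = 99)
  a <- make_section_set(sp)
  b <- make_section_set(sp)
  expect_identical(a$images[[1]], b$images[[1]])
  expect_identical(a$centres, b$centres)
})

test_that("planted truth conserves the number of blobs drawn", {
  sp <- cortical_section_spec(planted_counts = c(PFC = 5, M = 20, S = 10,
                                                 A = 3, V = 7, RSC = 2,
                                                 GC = 4),
                              image_shape = c(300L, 700L),
                              n_sections = 3, seed = 5)
  ss <- make_section_set(sp)
  expect_equal(nrow(ss$centres), sum(ss$ground_truth$planted_count))
  # per-section, per-region: centre tally equals the recorded truth
  tab <- table(ss$centres$section_index, ss$centres$region_id)
  for (s in 1:3) {
    for (rid in colnames(tab)) {
      gt <- ss$ground_truth
      expect_equal(unname(tab[as.character(s), rid]),
                   gt$planted_count[gt$section_index == s &
                                      gt$region_id == rid])
    }
  }
  # every centre lies inside its assigned region mask
  masks <- setNames(sp$regions$mask, sp$regions$region_id)
  for (k in seq_len(nrow(ss$centres))) {
    expect_true(masks[[ss$centres$region_id[k]]][ss$centres$row[k],
                                                 ss$centres$col[k]])
  }
})

test_that("overfull regions are rejected with an informative error", {
  rmap <- tiny_two_region(h = 20, w = 30)
  sp <- section_spec(rmap, c(A = 500, B = 0), image_shape = c(20L, 30L),
                     blob_radius_px = 4L, seed = 1)
  expect_error(make_section_set(sp), "non-overlapping")
})

test_that("tract ground truth follows interval arithmetic", {
  # single band rows 10..20: total 11, fibre 11, gap 0
  sp1 <- tract_spec(c(40L, 30L),
                    fascicles = list(list(top = 10, bottom = 20)),
                    measurement_columns = c(rostral = 15), pixel_size = 1)
  gt1 <- make_tract_image(sp1)$ground_truth
  expect_equal(gt1$total_px[15], 11)
  expect_equal(gt1$fibre_px[15], 11)
  expect_equal(gt1$gap_px[15], 0)

  # two bands 10..14 and 18..20: total 11, fibre 8, gap 3
  sp2 <- tract_spec(c(40L, 30L),
                    fascicles = list(list(top = 10, bottom = 14),
                                     list(top = 18, bottom = 20)),
                    measurement_columns = c(caudal = 5), pixel_size = 1)
  out2 <- make_tract_image(sp2)
  expect_equal(out2$ground_truth$total_px[5], 11)
  expect_equal(out2$ground_truth$fibre_px[5], 8)
  expect_equal(out2$ground_truth$gap_px[5], 3)
  # the rasterized image agrees with the analytic truth, column by column
  img <- unclass(out2$image)
  for (x in c(1, 5, 30)) {
    rows <- which(img[, x] > 0)
    expect_equal(max(rows) - min(rows) + 1, out2$ground_truth$total_px[x])
    expect_equal(length(rows), out2$ground_truth$fibre_px[x])
  }

  # column with no fascicle: all zero
  sp3 <- tract_spec(c(40L, 30L),
                    fascicles = list(list(top = c(rep(10, 20), rep(NA, 10)),
                                          bottom = c(rep(20, 20),
                                                     rep(NA, 10)))),
                    measurement_columns = c(c250 = 25), pixel_size = 1)
  gt3 <- make_tract_image(sp3)$ground_truth
  expect_equal(gt3$total_px[25], 0)
  expect_equal(gt3$fibre_px[25], 0)
})

test_that("overlapping fascicle intervals are rejected", {
  expect_error(
    tract_spec(c(40L, 30L),
               fascicles = list(list(top = 10, bottom = 15),
                                list(top = 14, bottom = 20)),
               measurement_columns = c(a = 1)),
    "overlapping")
})

test_that("zero group shift with one seed gives identical clouds", {
  pc <- make_pointclouds(small_cloud_spec(n = 500, shift = c(0, 0, 0)))
  expect_equal(pc$control$x_um, pc$shifted$x_um)
  expect_equal(pc$control$y_um, pc$shifted$y_um)
  expect_equal(pc$control$z_um, pc$shifted$z_um)
})

test_that("all generated points lie inside the region volume", {
  spec <- small_cloud_spec(n = 2000, shift = c(150, -50, 100), seed = 3)
  pc <- make_pointclouds(spec)
  for (cl in list(pc$control, pc$shifted)) {
    xyz <- as.matrix(cl[, c("x_um", "y_um", "z_um")])
    expect_true(all(in_volume(spec$volume, xyz)))
  }
})

test_that("an impossible group shift raises an error", {
  spec <- small_cloud_spec(n = 100, shift = c(5000, 0, 0))
  expect_error(make_pointclouds(spec), "shift")
})

test_that("planted shift is recovered by the sample means", {
  pc <- make_pointclouds(small_cloud_spec(n = 10000,
                                          shift = c(200, 0, 0), seed = 11))
  dx <- mean(pc$shifted$x_um) - mean(pc$control$x_um)
  expect_lt(abs(dx - 200), 20)
})
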