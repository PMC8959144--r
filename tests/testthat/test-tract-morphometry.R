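band_image <- function(intervals, h = 60, w = 40, pixel_size = 1,
                       section_index = 1L, ml = 0) {
  img <- matrix(0, h, w)
  for (iv in intervals) img[iv[1]:iv[2], ] <- 1
  section_image(img, pixel_size, 8L, section_index, ml)
}

test_that("column widths follow pixel interval arithmetic", {
  img <- band_image(list(c(10, 20)))
  expect_equal(width_at_column(img, 5), c(total = 11, fibre = 11, gap = 0))

  img2 <- band_image(list(c(10, 14), c(18, 20)))
  expect_equal(width_at_column(img2, 5), c(total = 11, fibre = 8, gap = 3))

  empty <- band_image(list())
  expect_equal(width_at_column(empty, 1), c(total = 0, fibre = 0, gap = 0))

  expect_error(width_at_column(img, 0), "outside")
  expect_error(width_at_column(img, 99), "outside")
})

test_that("widths scale with pixel size; decomposition always holds", {
  img1 <- band_image(list(c(5, 9), c(30, 44)), pixel_size = 1)
  img2 <- band_image(list(c(5, 9), c(30, 44)), pixel_size = 2)
  w1 <- width_at_column(img1, 10)
  w2 <- width_at_column(img2, 10)
  expect_equal(w2, 2 * w1)
  expect_equal(w1[["fibre"]] + w1[["gap"]], w1[["total"]])
})

test_that("profiles over a synthetic series equal generator truth", {
  specs <- lapply(1:4, function(i) {
    tract_spec(c(80L, 50L),
               fascicles = list(list(top = 10, bottom = 10 + 4 * i),
                                list(top = 40, bottom = 45 + i)),
               measurement_columns = c(rostral = 10, caudal = 40),
               pixel_size = 2.5, section_index = i,
               medio_lateral_pos = (i - 1) * 100)
  })
  outs <- lapply(specs, make_tract_image)
  images <- lapply(outs, `[[`, "image")
  columns <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(section_index = i, label = c("rostral", "caudal"),
               column = c(10, 40))
  }))
  prof <- profile_series(images, columns)
  expect_equal(nrow(prof), 8)
  for (i in 1:4) {
    mt <- outs[[i]]$measurement_truth
    for (lb in c("rostral", "caudal")) {
      row <- prof[prof$section_index == i & prof$label == lb, ]
      expect_equal(row$total_width, mt$total_um[mt$label == lb])
      expect_equal(row$fibre_width, mt$fibre_um[mt$label == lb])
      expect_equal(row$gap_width, mt$gap_um[mt$label == lb])
    }
  }
  # order invariance: permuting the input images changes nothing
  prof2 <- profile_series(images[c(3, 1, 4, 2)], columns)
  expect_equal(prof, prof2)
  # a label missing for one section is flagged NA, not fatal
  prof3 <- profile_series(images, columns[-1, ])
  expect_true(is.na(prof3$total_width[prof3$section_index == 1 &
                                        prof3$label == "rostral"]))
})

test_that("area under the profile matches closed forms and a Riemann sum", {
  # constant width w over n equally spaced positions: w * d * (n - 1)
  n <- 6; d <- 100; w <- 55
  prof <- data.frame(section_index = 1:n,
                     medio_lateral_pos = (0:(n - 1)) * d,
                     label = "rostral", total_width = w,
                     fibre_width = w, gap_width = 0)
  expect_equal(area_under_profile(prof, "rostral"), w * d * (n - 1))

  # triangle (0, h, 0): h * d
  h <- 80
  tri <- data.frame(section_index = 1:3, medio_lateral_pos = c(0, d, 2 * d),
                    label = "x", total_width = c(0, h, 0),
                    fibre_width = c(0, h, 0), gap_width = 0)
  expect_equal(area_under_profile(tri, "x"), h * d)

  # random profile vs brute-force fine-subdivision Riemann sum
  withr::with_seed(7, {
    x <- sort(runif(12, 0, 1000))
    y <- runif(12, 0, 300)
  })
  prof2 <- data.frame(section_index = 1:12, medio_lateral_pos = x,
                      label = "r", total_width = y, fibre_width = y,
                      gap_width = 0)
  auc <- area_under_profile(prof2, "r")
  # oracle: midpoint Riemann sum of the piecewise-linear interpolant
  riemann <- 0
  for (i in 1:11) {
    xs <- seq(x[i], x[i + 1], length.out = 20001)
    ys <- approx(x, y, xout = xs)$y
    riemann <- riemann + sum((ys[-1] + ys[-length(ys)]) / 2 * diff(xs))
  }
  expect_lt(abs(auc - riemann) / riemann, 1e-9)

  expect_error(area_under_profile(prof2[1, ], "r"), "at least 2")
  # missing entries are skipped with a warning
  prof2$total_width[3] <- NA
  expect_warning(area_under_profile(prof2, "r"), "skipped")
})

test_that("fasciculation index is fibre/total with documented degeneracy", {
  expect_equal(fasciculation_index(10, 10), 1.0)
  expect_equal(fasciculation_index(11, 8), 8 / 11)
  expect_true(is.na(fasciculation_index(0, 0)))
  expect_error(fasciculation_index(5, 8), "exceed")
  expect_equal(fasciculation_index(11, 8, orientation = "total_over_fibre"),
               11 / 8)
  # scale invariance: micrometre conversion cancels in the ratio
  expect_equal(fasciculation_index(22, 16), fasciculation_index(11, 8))
})

test_that("offset measurements use round-half-away-from-zero columns", {
  img <- band_image(list(c(10, 19), c(25, 29)), w = 400, pixel_size = 2.5)
  fm <- fasciculation_at_offsets(img, reference_column = 100,
                                 offsets_um = c(250, 500))
  expect_equal(fm$column, c(200, 300))
  expect_equal(fm$fasciculation_index, rep(15 / 20, 2))
  expect_equal(fm$total_width, rep(20 * 2.5, 2))
})
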