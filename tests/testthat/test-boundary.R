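test_that("segment_cell recovers clean two-level masks exactly", {
  m <- disc_mask(101, 51, 51, 30)
  img <- ifelse(m, 200, 10)
  seg <- segment_cell(img, pixel_size_um = 1)
  expect_identical(seg$mask, m)

  # 5-pixel speckle removed by the largest-component rule
  img2 <- img
  img2[3, 3:7] <- 200
  seg2 <- segment_cell(img2, pixel_size_um = 1)
  expect_identical(seg2$mask, m)

  # interior hole filled
  img3 <- img
  img3[48:52, 48:52] <- 10
  seg3 <- segment_cell(img3, pixel_size_um = 1)
  expect_identical(seg3$mask, m)

  expect_error(segment_cell(matrix(5, 50, 50), pixel_size_um = 1),
               "dynamic range")
  expect_error(segment_cell(ifelse(disc_mask(101, 51, 51, 2), 200, 10),
                            min_area_um2 = 50, pixel_size_um = 1),
               "min_area")
  # fixed threshold string form
  seg4 <- segment_cell(img, method = "fixed:100", pixel_size_um = 1)
  expect_identical(seg4$mask, m)
})

test_that("extract_boundary traces sub-pixel outlines with accurate perimeter", {
  # disc, radius 50 px at 0.2 um/px: perimeter 2*pi*10 um within 1%
  m <- disc_mask(128, 64.3, 64.3, 50)
  ct <- extract_boundary(m, 1000, pixel_size_um = 0.2)
  expect_lt(abs(ct$perimeter_um - 2 * pi * 10) / (2 * pi * 10), 0.01)

  # square mask: perimeter within 2% of 4*side (corners rounded)
  sq <- matrix(FALSE, 120, 120)
  sq[11:110, 11:110] <- TRUE
  ct2 <- extract_boundary(sq, 1000, pixel_size_um = 1)
  expect_lt(abs(ct2$perimeter_um - 400) / 400, 0.02)

  # two components rejected
  two <- disc_mask(128, 40, 40, 15) | disc_mask(128, 95, 95, 15)
  expect_error(extract_boundary(two, 200, pixel_size_um = 1),
               "more than one")
})

test_that("boundary intensity sampling is exact on constructed images", {
  ct <- resample_contour(circle_points(50, 512, 64, 64), 0.2, 400)
  # uniform image
  pr <- sample_boundary_intensity(matrix(7, 128, 128), ct, 0.5)
  expect_true(all(pr$raw == 7))

  # ring of value 100 painted on the contour, wider than the band
  img <- matrix(0, 128, 128)
  d <- sqrt((row(img) - 65)^2 + (col(img) - 65)^2)
  img[abs(d - 50) <= 4] <- 100
  pr2 <- sample_boundary_intensity(img, ct, band_width_um = 0.5)
  expect_lt(max(abs(pr2$raw - 100)) / 100, 0.05)

  # band clamped at the image edge warns
  ct_edge <- resample_contour(circle_points(60, 512, 64, 64), 0.2, 200)
  expect_warning(sample_boundary_intensity(matrix(1, 128, 128), ct_edge, 2),
                 "clamp")
})

test_that("band averages match a dense pixel-enumeration oracle", {
  # half-plane image: left 0, right 50
  img <- matrix(0, 120, 120)
  img[, 61:120] <- 50
  ct <- resample_contour(circle_points(40, 1024, 60, 60), 0.25, 300)
  pr <- sample_boundary_intensity(img, ct, band_width_um = 1.5)
  oracle <- oracle_band_average(img, ct$x, ct$y, 0.25, 1.5)
  expect_lt(max(abs(pr$raw - oracle)) / 50, 0.01)
})

test_that("boundary sampling is rotation-equivariant", {
  set.seed(11)
  img <- matrix(runif(128 * 128), 128, 128)
  img <- curvassay:::box_blur(img, 3, 3)
  ct <- resample_contour(circle_points(45, 1024, 64, 64), 0.2, 360)
  pr <- sample_boundary_intensity(img, ct, 1)
  # rotate image by 90 degrees: (r, c) -> (c, nr + 1 - r)
  img90 <- t(img)[, nrow(img):1]
  nr <- nrow(img)
  x90 <- (nr - 1) * 0.2 - ct$y
  y90 <- ct$x
  ct90 <- resample_contour(cbind(x90, y90) / 0.2, 0.2, 360)
  pr90 <- sample_boundary_intensity(img90, ct90, 1)
  # same multiset of values up to sample alignment: compare sorted profiles
  expect_lt(max(abs(sort(pr$raw) - sort(pr90$raw))) / diff(range(pr$raw)),
            0.01)
})

test_that("normalize_profile modes behave as documented", {
  mk <- function(v) structure(list(channel_name = "x", raw = v,
                                   normalized = NULL, band_width_um = 1),
                              class = "intensity_profile")
  expect_equal(normalize_profile(mk(c(0, 5, 10)))$normalized, c(0, 0.5, 1))
  expect_warning(out <- normalize_profile(mk(rep(3, 5))), "constant")
  expect_equal(out$normalized, rep(0.5, 5))
  # percentile mode clips an outlier to 1
  v <- c(rep(1:10, 20), 1000)
  out2 <- normalize_profile(mk(v), "percentile:1,99")
  expect_equal(max(out2$normalized), 1)
  expect_equal(out2$normalized[length(v)], 1)
  expect_true(all(out2$normalized >= 0 & out2$normalized <= 1))
  expect_error(normalize_profile(mk(1:5), "percentile:99,1"), "lo < hi")
  expect_error(normalize_profile(mk(1:5), "bogus"), "unknown")
})

test_that("phantom profiles are recovered with r > 0.95 at SNR 5", {
  for (seed in 1:3) {
    ph <- make_phantom_cell(gentle_phantom_spec(seed))
    res <- suppressWarnings(
      run_curvature(list(images = ph$images, pixel_size_um = 0.2)))
    near <- nearest_truth_index(res$contour, ph$truth)
    expect_gt(cor(res$profiles$spectrin$normalized, ph$truth$spectrin[near]),
              0.95)
    expect_gt(cor(res$profiles$actin$normalized, ph$truth$actin[near]),
              0.95)
  }
})
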