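test_that("resample_contour preserves perimeter, shape and orientation", {
  # unit square: perimeter preserved within 0.5%
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  ct <- resample_contour(sq, pixel_size_um = 1, n_samples = 400)
  expect_lt(abs(ct$perimeter_um - 4) / 4, 0.005)
  expect_equal(ct$n_samples, 400L)
  # uniform arc-length spacing (parameter spacing exact by construction)
  expect_lt(max(abs(diff(ct$s) - ct$perimeter_um / 400)), 1e-6 * ct$perimeter_um)

  # circle invariance: 64-point radius-10 circle resampled to 256
  ct2 <- resample_contour(circle_points(10, 64), 1, 256)
  expect_lt(max(abs(sqrt(ct2$x^2 + ct2$y^2) - 10)), 0.05)

  # clockwise input is flipped to positive shoelace area
  cw <- circle_points(5, 64)[64:1, ]
  ct3 <- resample_contour(cw, 1, 128)
  expect_gt(curvassay:::shoelace_area(ct3$x, ct3$y), 0)

  # micrometre conversion
  ct4 <- resample_contour(circle_points(50, 256), pixel_size_um = 0.2,
                          n_samples = 128)
  expect_lt(abs(ct4$perimeter_um - 2 * pi * 10) / (2 * pi * 10), 0.01)
})

test_that("resample_contour rejects degenerate input, warns on self-intersection", {
  expect_error(resample_contour(cbind(c(0, 0), c(0, 1))), "degenerate")
  expect_error(resample_contour(cbind(c(0, 0, 0), c(1, 1, 1))), "degenerate")
  bowtie <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_warning(resample_contour(bowtie, 1, 64), "self-intersect")
})

test_that("signed curvature matches analytic circles and ellipse tips", {
  circ5 <- resample_contour(circle_points(5, 1024), 1, 1000)
  cp <- signed_curvature(circ5)
  expect_lt(max(abs(cp$kappa - 0.2)) / 0.2, 0.01)

  circ2 <- resample_contour(circle_points(2, 1024), 1, 800)
  cp2 <- signed_curvature(circ2, presmooth_window_um = 0.5)
  expect_lt(max(abs(abs(cp2$kappa) - 0.5)) / 0.5, 0.01)
  expect_true(all(cp2$kappa > 0))  # convex ccw outline is positive

  # ellipse a=10, b=5: tip curvature a/b^2 = 0.4 within 2%
  ell <- resample_contour(ellipse_points(10, 5, 4000), 1, 2000)
  cpe <- signed_curvature(ell)
  tip <- which.min((ell$x - 10)^2 + ell$y^2)
  expect_lt(abs(cpe$kappa[tip] - 0.4) / 0.4, 0.02)

  # both estimator backends agree on smooth shapes
  cpc <- signed_curvature(ell, method = "central")
  expect_lt(abs(cpc$kappa[tip] - 0.4) / 0.4, 0.02)
})

test_that("signed_curvature rejects oversized presmooth windows", {
  ct <- resample_contour(circle_points(5, 256), 1, 256)
  expect_error(signed_curvature(ct, presmooth_window_um = 20), "perimeter")
})

test_that("smooth_abs_curvature implements a periodic moving average", {
  ct <- resample_contour(circle_points(5, 1024), 1, 500)
  cp <- signed_curvature(ct, abs_smooth_window_um = 0)
  h <- cp$spacing_um

  # constant profile unchanged by any window
  sm <- smooth_abs_curvature(cp, 2)
  expect_lt(max(abs(sm$kappa_abs_smoothed - 0.2)), 1e-3)

  # single spike: peak becomes value/k for a window of k samples
  spike <- cp
  spike$kappa <- rep(0, 500); spike$kappa[100] <- 10
  k <- 25  # divides the sample count, so the circular sinusoid is periodic
  sms <- smooth_abs_curvature(spike, k * h)
  expect_equal(max(sms$kappa_abs_smoothed), 10 / k, tolerance = 1e-9)

  # sinusoid with period equal to the window: flattened to its mean,
  # checked against a brute-force periodic convolution oracle
  sine <- cp
  sine$kappa <- 1 + 0.5 * sin(2 * pi * (0:499) / k)
  smo <- smooth_abs_curvature(sine, k * h)
  expect_lt(max(abs(smo$kappa_abs_smoothed - 1)), 0.01 * 0.5)
  oracle <- abs(oracle_periodic_moving_average(sine$kappa, k))
  expect_equal(smo$kappa_abs_smoothed, oracle, tolerance = 1e-12)

  expect_error(smooth_abs_curvature(cp, -1), "positive")
  expect_error(smooth_abs_curvature(cp, 0), "positive")
})

test_that("total turning of simple closed ccw contours is 2*pi", {
  shapes <- list(
    resample_contour(circle_points(5, 1024), 1, 800),
    resample_contour(ellipse_points(10, 5, 2048), 1, 1000)
  )
  # lumpy seeded star shapes via the phantom generator's exact outlines
  for (seed in 1:3) {
    ph <- make_phantom_cell(phantom_cell_spec(snr = Inf, seed = seed))
    shapes[[length(shapes) + 1]] <-
      resample_contour(cbind(ph$truth$x_um, ph$truth$y_um), 1, 1500)
  }
  for (ct in shapes) {
    # window small relative to the sharpest features (protrusion tips)
    tt <- total_turning(signed_curvature(ct, presmooth_window_um = 0.5))
    expect_lt(abs(tt - 2 * pi) / (2 * pi), 0.01)
  }
})

test_that("curvature is scale covariant and rigid-motion invariant", {
  base <- ellipse_points(8, 5, 2048)
  ct0 <- resample_contour(base, 1, 1000)
  cp0 <- signed_curvature(ct0, presmooth_window_um = 1)
  for (c_fac in c(0.5, 2, 10)) {
    ctc <- resample_contour(base * c_fac, 1, 1000)
    cpc <- signed_curvature(ctc, presmooth_window_um = 1 * c_fac)
    expect_lt(max(abs(cpc$kappa * c_fac - cp0$kappa)) / max(abs(cp0$kappa)),
              1e-6)
  }
  th <- 0.83
  rot <- cbind(base[, 1] * cos(th) - base[, 2] * sin(th) + 13.7,
               base[, 1] * sin(th) + base[, 2] * cos(th) - 4.2)
  cpr <- signed_curvature(resample_contour(rot, 1, 1000),
                          presmooth_window_um = 1)
  expect_lt(max(abs(cpr$kappa - cp0$kappa)) / max(abs(cp0$kappa)), 1e-9)
})

test_that("estimator agrees with an osculating-circle oracle on analytic shapes", {
  ell <- resample_contour(ellipse_points(8, 5, 4096), 1, 2000)
  cp <- signed_curvature(ell, presmooth_window_um = 1)
  m <- round(1 / cp$spacing_um / 2)  # oracle chord span ~ the SG window
  oracle <- oracle_three_point_curvature(ell$x, ell$y, m)
  expect_lt(max(abs(cp$kappa - oracle)) / max(abs(oracle)), 0.02)
})

test_that("profile CSV serialization round-trips", {
  pts <- ellipse_points(10, 6, 1024)
  ct <- resample_contour(cbind(pts[, 1] + 40, pts[, 2] + 40), 1, 400)
  cp <- signed_curvature(ct)
  img <- matrix(7, 80, 80)
  pr <- normalize_profile(sample_boundary_intensity(img + outer(1:80, 1:80) / 800,
                                                    ct, 1, "actin"))
  path <- tempfile(fileext = ".csv")
  write_profile_csv(ct, path, curvature = cp, intensities = list(actin = pr))
  back <- read_profile_csv(path, pixel_size_um = 1)
  expect_equal(back$contour$x, ct$x, tolerance = 1e-8)
  expect_equal(back$contour$y, ct$y, tolerance = 1e-8)
  expect_equal(back$contour$perimeter_um, ct$perimeter_um, tolerance = 1e-6)
  expect_equal(back$curvature$kappa, cp$kappa, tolerance = 1e-8)
  expect_equal(back$curvature$kappa_abs_smoothed, cp$kappa_abs_smoothed,
               tolerance = 1e-8)
  expect_true(all(c("actin_raw", "actin_norm") %in% names(back$table)))
  unlink(path)
})
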