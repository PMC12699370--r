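test_that("phantom generators are pure functions of spec + seed", {
  sp <- phantom_cell_spec(seed = 5)
  a <- make_phantom_cell(sp)
  b <- make_phantom_cell(sp)
  expect_identical(a$images, b$images)
  expect_identical(a$truth, b$truth)
  # different seed, different noise and shape
  c2 <- make_phantom_cell(phantom_cell_spec(seed = 6))
  expect_false(identical(a$images$spectrin, c2$images$spectrin))
})

test_that("circular phantom has constant analytic curvature", {
  none <- data.frame(theta = numeric(0), width = numeric(0),
                     length_um = numeric(0))
  sp <- phantom_cell_spec(base_radius_um = 10,
                          harmonics = data.frame(k = integer(0),
                                                 amp = numeric(0),
                                                 phase = numeric(0)),
                          protrusions = none, snr = Inf, seed = 1)
  ph <- make_phantom_cell(sp)
  expect_equal(ph$truth$kappa_per_um, rep(0.1, length(ph$truth$theta)),
               tolerance = 1e-12)
  # radius of the outline is exact
  r <- sqrt((ph$truth$x_um - ph$center_um["x"])^2 +
              (ph$truth$y_um - ph$center_um["y"])^2)
  expect_equal(unname(r), rep(10, length(r)), tolerance = 1e-12)
})

test_that("hard-threshold response is the indicator of |kappa| < kappa0", {
  sp <- phantom_cell_spec(kappa0_per_um = 0.2, response_steepness = Inf,
                          snr = Inf, seed = 3)
  ph <- make_phantom_cell(sp)
  k <- abs(ph$truth$kappa_per_um)
  expect_true(all(ph$truth$spectrin[k < 0.2] == 1))
  expect_true(all(ph$truth$spectrin[k > 0.2] == 0))
  expect_equal(ph$truth$actin, 1 - ph$truth$spectrin)
})

test_that("analytic truth curvature matches the geometry estimator within 3%", {
  for (seed in c(2, 9)) {
    ph <- make_phantom_cell(phantom_cell_spec(snr = Inf, seed = seed))
    ct <- resample_contour(cbind(ph$truth$x_um, ph$truth$y_um), 1, 2000)
    cp <- signed_curvature(ct, presmooth_window_um = 0.4)
    near <- nearest_truth_index(ct, ph$truth)
    err <- abs(cp$kappa - ph$truth$kappa_per_um[near])
    expect_lt(max(err) / max(abs(ph$truth$kappa_per_um)), 0.03)
  }
})

test_that("degenerate phantom outlines are rejected", {
  bad <- phantom_cell_spec(
    harmonics = data.frame(k = 6, amp = 0.9, phase = 0),
    protrusions = data.frame(theta = numeric(0), width = numeric(0),
                             length_um = numeric(0)),
    seed = 1)
  expect_error(make_phantom_cell(bad), "degenerate")
  expect_error(phantom_cell_spec(snr = -1), "positive")
})

test_that("deformation video is deterministic and flow-rate separable", {
  spec <- deformation_cohort_spec(n_cells_per_Q = 4, seed = 3)
  v1 <- make_deformation_video(spec)
  v2 <- make_deformation_video(spec)
  expect_identical(v1$frames, v2$frames)
  expect_identical(v1$truth, v2$truth)
  # generating one flow rate reproduces its slice of the full run
  v10 <- make_deformation_video(spec, flow_rates = 10)
  expect_identical(v10$frames, v1$frames[v1$frame_Q == 10])
  # truncation keeps every true peak at >= 1
  expect_true(all(v1$truth$true_peak_di >= 1))
})

test_that("gel generator paints programmed volumes with ROI metadata", {
  # all-zero lanes: pure flat background
  gel0 <- make_gel_image(data.frame(label = "x", B = 0, U = 0, d = 1),
                         background = 10, seed = 1)
  expect_true(all(gel0$image == 10))

  # noise-free round trip through the densitometry module within 2%
  gel <- make_gel_image(data.frame(label = "x", B = 100, U = 50, d = 2),
                        snr = Inf, seed = 1)
  B <- integrate_roi(gel$image, gel$rois[[1]]$bound,
                     ring_width = 8)$integrated_intensity
  U <- integrate_roi(gel$image, gel$rois[[1]]$unbound,
                     ring_width = 8)$integrated_intensity
  expect_lt(abs(binding_ratio(B, U, 2) - 0.5) / 0.5, 0.02)

  expect_identical(make_gel_image(data.frame(label = "x", B = 10, U = 5,
                                             d = 2), seed = 4)$image,
                   make_gel_image(data.frame(label = "x", B = 10, U = 5,
                                             d = 2), seed = 4)$image)
  expect_error(make_gel_image(data.frame(label = "x", B = -1, U = 0, d = 1)),
               "non-negative")
  expect_error(make_gel_image(data.frame(label = "x", B = 1, U = 1, d = 0.5)),
               ">= 1")
})

test_that("strip generator respects the template and affinity bounds", {
  # all-zero affinities: flat strip
  aff0 <- c("PtdIns(4,5)P2" = 0, "PA" = 0)
  st0 <- make_strip_image(aff0, background = 5, seed = 1)
  expect_true(all(st0$image == 5))

  # one lipid at 1: it is the unique maximum after spot integration
  aff <- c("PtdIns(4,5)P2" = 1, "PA" = 0)
  st <- make_strip_image(aff, snr = 20, seed = 2)
  recs <- lapply(seq_len(nrow(st$template)), function(i) {
    integrate_roi(st$image,
                  roi_disc(st$template$cx[i], st$template$cy[i],
                           st$template$r[i]),
                  label = st$template$label[i])
  })
  rel <- relative_spot_intensities(recs, blank_labels = "blank")
  expect_equal(rel$label[which.max(rel$relative)], "PtdIns(4,5)P2")
  expect_equal(max(rel$relative), 1)
  expect_lt(stats::quantile(rel$relative[rel$label != "PtdIns(4,5)P2"], 0.9),
            0.1)

  expect_error(make_strip_image(c(a = 2)), "\\[0, 1\\]")
  expect_error(make_strip_image(c(nonsense = 0.5)), "layout")
})
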