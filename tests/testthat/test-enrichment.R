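mk_prof <- function(v, name = "x") {
  structure(list(channel_name = name, raw = v, normalized = v,
                 band_width_um = 1), class = "intensity_profile")
}

mk_curv <- function(kappa, spacing = 0.1) {
  n <- length(kappa)
  structure(list(s = (0:(n - 1)) * spacing, kappa = kappa,
                 kappa_abs_smoothed = abs(kappa), smoothing_window_um = 0,
                 presmooth_window_um = 0, spacing_um = spacing,
                 perimeter_um = n * spacing), class = "curvature_profile")
}

test_that("classify_enriched applies floor, margin and run-length rules", {
  n <- 100
  lab <- classify_enriched(mk_prof(rep(1, n)), mk_prof(rep(0, n)))
  expect_true(all(lab$labels == "actin_enriched"))
  expect_equal(nrow(lab$runs), 1L)
  expect_equal(lab$runs$length, n)

  # equal channels: margin unmet everywhere
  lab2 <- classify_enriched(mk_prof(rep(0.7, n)), mk_prof(rep(0.7, n)))
  expect_true(all(lab2$labels == "unassigned"))

  # below the floor: dominant but dim channel stays unassigned
  lab3 <- classify_enriched(mk_prof(rep(0.2, n)), mk_prof(rep(0.05, n)))
  expect_true(all(lab3$labels == "unassigned"))

  # runs shorter than min_run_samples are dropped
  a <- rep(0, n); a[40:44] <- 1
  lab4 <- classify_enriched(mk_prof(a), mk_prof(rep(0, n)),
                            min_run_samples = 10)
  expect_true(all(lab4$labels == "unassigned"))
  lab5 <- classify_enriched(mk_prof(a), mk_prof(rep(0, n)),
                            min_run_samples = 5)
  expect_equal(sum(lab5$labels == "actin_enriched"), 5L)

  # runs wrap circularly across the contour origin
  a6 <- rep(0, n); a6[c(1:6, 95:100)] <- 1
  lab6 <- classify_enriched(mk_prof(a6), mk_prof(rep(0, n)),
                            min_run_samples = 10)
  expect_equal(sum(lab6$labels == "actin_enriched"), 12L)
  runs6 <- lab6$runs[lab6$runs$label == "actin_enriched", ]
  expect_equal(nrow(runs6), 1L)
  expect_gt(runs6$start, runs6$end)  # wrap marked by start > end

  expect_error(classify_enriched(mk_prof(rep(1, 10)), mk_prof(rep(0, 9))),
               "lengths differ")
})

test_that("swapping the channels swaps the labels exactly", {
  set.seed(3)
  a <- runif(300); s <- runif(300)
  l1 <- classify_enriched(mk_prof(a), mk_prof(s))
  l2 <- classify_enriched(mk_prof(s), mk_prof(a))
  swap <- c(actin_enriched = "spectrin_enriched",
            spectrin_enriched = "actin_enriched", unassigned = "unassigned")
  expect_identical(unname(swap[l1$labels]), l2$labels)
})

test_that("recovered run boundaries sit within one smoothing window of truth", {
  # hard-indicator response on a pure lobe shape: enriched regions are the
  # |kappa| < kappa0 stretches, with analytically known switch positions
  harm <- data.frame(k = 6, amp = 0.55 * 13 / 35, phase = 0)
  prot <- data.frame(theta = numeric(0), width = numeric(0),
                     length_um = numeric(0))
  ph <- make_phantom_cell(phantom_cell_spec(
    harmonics = harm, protrusions = prot, kappa0_per_um = 0.2,
    response_steepness = Inf, snr = 8, seed = 2))
  res <- suppressWarnings(
    run_curvature(list(images = ph$images, pixel_size_um = 0.2)))
  kt <- abs(ph$truth$kappa_per_um)
  true_s <- ph$truth$s_um[which(diff(kt < 0.2) != 0)]
  spacing <- res$contour$perimeter_um / res$contour$n_samples
  runs <- res$labels$runs[res$labels$runs$label != "unassigned", ]
  bnd <- c((runs$start - 1) * spacing, runs$end * spacing)
  L <- res$contour$perimeter_um
  err <- vapply(bnd, function(b) {
    min(abs(c(b - true_s, b - true_s + L, b - true_s - L)))
  }, numeric(1))
  expect_gt(length(bnd), 10)
  expect_lt(max(err), res$curvature$smoothing_window_um)
})

test_that("curvature_by_class pools and summarizes per class", {
  n <- 200
  cv <- mk_curv(rep(0.1, n))
  lab <- classify_enriched(mk_prof(rep(c(1, 0), each = n / 2)),
                           mk_prof(rep(c(0, 1), each = n / 2)))
  cbc <- curvature_by_class(cv, lab)
  expect_equal(cbc$summary$median_kappa, c(0.1, 0.1))
  expect_equal(cbc$summary$frac_below_cutoff, c(1, 1))
  expect_equal(sum(cbc$summary$n), n)

  # one class only: pooled set equals the full track; empty class -> NA
  lab_all <- classify_enriched(mk_prof(rep(1, n)), mk_prof(rep(0, n)))
  cv2 <- mk_curv(seq(0, 1, length.out = n))
  cbc2 <- curvature_by_class(cv2, lab_all)
  expect_equal(cbc2$values$actin_enriched, cv2$kappa_abs_smoothed)
  expect_true(is.na(cbc2$summary$median_kappa[2]))
  expect_equal(cbc2$summary$n[2], 0L)

  expect_error(curvature_by_class(mk_curv(rep(0.1, 50)), lab_all),
               "different lengths")
})

test_that("compare_classes matches closed-form limits and a permutation oracle", {
  n <- 200
  set.seed(8)
  v <- runif(n / 2, 0, 0.6)
  cv <- mk_curv(rep(v, each = 2))  # both classes see the same multiset
  lab <- classify_enriched(mk_prof(rep(c(1, 0), n / 2)),
                           mk_prof(rep(c(0, 1), n / 2)),
                           min_run_samples = 1)
  out <- suppressWarnings(compare_classes(curvature_by_class(cv, lab)))
  expect_gt(out$p_value, 0.9)
  expect_equal(out$effect_rank_biserial, 0)

  # completely separated supports: |effect| = 1
  cv2 <- mk_curv(rep(c(0.9, 0.1), n / 2))
  out2 <- suppressWarnings(compare_classes(curvature_by_class(cv2, lab)))
  expect_equal(abs(out2$effect_rank_biserial), 1)
  expect_lt(out2$p_value, 1e-10)

  # tiny class: undefined with warning
  small <- curvature_by_class(
    mk_curv(rep(0.2, 20)),
    classify_enriched(mk_prof(c(1, 1, rep(0, 18))), mk_prof(rep(0, 20)),
                      min_run_samples = 1))
  expect_warning(res_small <- compare_classes(small), "fewer than 3")
  expect_true(is.na(res_small$p_value))

  # seeded shifted samples: p within 10% of a 1e4-permutation oracle
  set.seed(42)
  x <- rnorm(25, 0.28, 0.25)
  y <- rnorm(25, 0.25, 0.25)
  cbc <- structure(list(values = list(actin_enriched = x,
                                      spectrin_enriched = y),
                        summary = NULL, cutoff_per_um = 0.2),
                   class = "curvature_by_class")
  p_pkg <- compare_classes(cbc)$p_value
  p_oracle <- oracle_permutation_ranksum(x, y, n_perm = 1e4, seed = 7)
  expect_lt(abs(p_pkg - p_oracle) / p_oracle, 0.10)
})

test_that("class_kappa_table emits long-format rows", {
  cv <- mk_curv(rep(0.3, 40))
  lab <- classify_enriched(mk_prof(rep(c(1, 0), each = 20)),
                           mk_prof(rep(c(0, 1), each = 20)))
  tab <- class_kappa_table(curvature_by_class(cv, lab))
  expect_equal(nrow(tab), 40)
  expect_setequal(unique(tab$class), c("actin_enriched", "spectrin_enriched"))
})
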