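# Seeded synthetic-data generators with analytic ground truth, one per
# pipeline stage: two-channel phantom cells (boundary curvature vs
# fluorescence), cross-flow deformation videos, gel lanes, lipid-strip
# spots. Every generator is a pure function of its spec and seed.

# ---------------------------------------------------------------------------
# Phantom cells
#
# The outline is a star-shaped radial curve
#   r(theta) = R0 (1 + sum_k a_k cos(k theta + phi_k)) + sum_j L_j G(theta)
# (G = Gaussian bumps emulating protrusions), which is always simple, has
# long flat-to-gently-curved stretches between protrusions, and admits exact
# curvature from the polar formula
#   kappa = (r^2 + 2 r'^2 - r r'') / (r^2 + r'^2)^(3/2).
# The spectrin channel responds to curvature through a logistic
#   S = 1 / (1 + exp(steepness (|kappa| - kappa0)))
# (flat-membrane preference with threshold kappa0; an indicator of
# |kappa| < kappa0 in the steep limit), and actin is its complement
# A = 1 - S. Default geometry is chosen so that a cohort of cells covers
# |kappa| from ~0 to >1 1/um with appreciable density throughout: cells
# ~26 um across (base kappa ~0.08 1/um), a dominant lobe mode whose
# curvature amplitude varies cell to cell (0.5-0.75 1/um), and several
# protrusions with tip radii down to ~1 um. Adherent cells imaged in
# curvature-localization experiments show the same mixture of flat arcs,
# lamellipodial lobes and filopodial protrusions.

#' Phantom cell specification
#'
#' @param base_radius_um mean cell radius R0.
#' @param harmonics data frame with columns `k`, `amp`, `phase`, or `NULL` to
#'   draw defaults from the seed: gentle modes 2 and 4 plus a dominant
#'   6-fold lobe mode with per-cell curvature amplitude ~ U(0.5, 0.75)
#'   1/um.
#' @param protrusions data frame with columns `theta`, `width` (rad),
#'   `length_um`, or `NULL` to draw 4-6 protrusions (lengths 2.5-5 um, angular
#'   widths 0.10-0.22 rad, i.e. tip radii down to ~1 um and enriched arcs
#'   wide enough to resolve at the default profile sampling density) from
#'   the seed.
#' @param kappa0_per_um spectrin-exclusion curvature threshold.
#' @param response_steepness logistic steepness in µm (per unit |kappa|);
#'   `NULL` (default) uses the scale-aware `6 / kappa0_per_um`, which keeps
#'   the relative transition width the same at every threshold; `Inf` gives
#'   a hard indicator.
#' @param snr boundary signal-to-noise ratio (signal amplitude 1 /
#'   noise sd); `Inf` disables noise.
#' @param pixel_size_um raster pixel size.
#' @param cytoplasm_fill,actin_fill interior fill levels of the spectrin and
#'   actin channels (the spectrin channel marks the whole cell body and is
#'   the default segmentation channel).
#' @param band_um painted boundary band width.
#' @param n_boundary dense ground-truth samples along the outline.
#' @param seed RNG seed; the generator is deterministic given spec + seed.
#' @return a `phantom_cell_spec` list.
#' @export
phantom_cell_spec <- function(base_radius_um = 13, harmonics = NULL,
                              protrusions = NULL, kappa0_per_um = 0.2,
                              response_steepness = NULL, snr = 5,
                              pixel_size_um = 0.2, cytoplasm_fill = 0.5,
                              actin_fill = 0.08, band_um = 0.8,
                              n_boundary = 3000L, seed = 1L) {
  if (base_radius_um <= 0 || pixel_size_um <= 0 || snr <= 0 ||
      kappa0_per_um <= 0 || band_um <= 0) {
    stop_config("phantom spec parameters must be positive")
  }
  structure(list(base_radius_um = base_radius_um, harmonics = harmonics,
                 protrusions = protrusions, kappa0_per_um = kappa0_per_um,
                 response_steepness = response_steepness %||%
                   6 / kappa0_per_um, snr = snr,
                 pixel_size_um = pixel_size_um,
                 cytoplasm_fill = cytoplasm_fill, actin_fill = actin_fill,
                 band_um = band_um, n_boundary = as.integer(n_boundary),
                 seed = as.integer(seed)),
            class = "phantom_cell_spec")
}

# r(theta) and derivatives for resolved shape parameters.
radial_shape <- function(theta, R0, harmonics, protrusions) {
  r <- rep(R0, length(theta))
  rp <- numeric(length(theta))
  rpp <- numeric(length(theta))
  if (!is.null(harmonics) && nrow(harmonics)) {
    for (i in seq_len(nrow(harmonics))) {
      k <- harmonics$k[i]; a <- harmonics$amp[i]; ph <- harmonics$phase[i]
      r <- r + R0 * a * cos(k * theta + ph)
      rp <- rp - R0 * a * k * sin(k * theta + ph)
      rpp <- rpp - R0 * a * k^2 * cos(k * theta + ph)
    }
  }
  if (!is.null(protrusions) && nrow(protrusions)) {
    for (i in seq_len(nrow(protrusions))) {
      d <- (theta - protrusions$theta[i] + pi) %% (2 * pi) - pi
      w <- protrusions$width[i]; L <- protrusions$length_um[i]
      g <- L * exp(-0.5 * (d / w)^2)
      r <- r + g
      rp <- rp - g * d / w^2
      rpp <- rpp + g * (d^2 / w^4 - 1 / w^2)
    }
  }
  list(r = r, rp = rp, rpp = rpp)
}

polar_curvature <- function(sh) {
  (sh$r^2 + 2 * sh$rp^2 - sh$r * sh$rpp) / (sh$r^2 + sh$rp^2)^1.5
}

#' Generate a two-channel phantom cell with analytic ground truth
#'
#' Paints the spectrin channel (cytoplasmic fill + curvature-dependent
#' boundary band) and the actin channel (faint fill + complementary boundary
#' band) into images at the requested pixel size and SNR, and returns the
#' exact outline, signed curvature, and per-channel boundary responses.
#'
#' @param spec a [phantom_cell_spec()].
#' @return list with `images` (named list `spectrin`, `actin` of matrices),
#'   `truth` (list: `theta`, `x_um`, `y_um`, `s_um`, `kappa_per_um`,
#'   `spectrin`, `actin` at `n_boundary` dense samples, counterclockwise),
#'   `center_um`, `spec` (with resolved harmonics/protrusions).
#' @export
make_phantom_cell <- function(spec) {
  stopifnot(inherits(spec, "phantom_cell_spec"))
  set.seed(spec$seed)
  R0 <- spec$base_radius_um
  harmonics <- spec$harmonics
  if (is.null(harmonics)) {
    # lobed outline: gentle elongation/asymmetry modes plus a dominant
    # 7-fold lobe mode whose per-cell curvature amplitude (first-order
    # a (k^2-1)/R0) is drawn from 0.45-0.75 1/um, so a cohort of cells
    # covers flat through moderately curved membrane densely
    a_dom <- stats::runif(1, 0.5, 0.75)
    harmonics <- data.frame(
      k = c(2, 4, 6),
      amp = c(0.05 * stats::runif(1, 0.5, 1.5),
              0.04 * stats::runif(1, 0.5, 1.5),
              a_dom * R0 / 35),
      phase = stats::runif(3, 0, 2 * pi))
  }
  protrusions <- spec$protrusions
  if (is.null(protrusions)) {
    np <- sample(4:6, 1)
    protrusions <- data.frame(
      theta = ((seq_len(np) - 1) * 2 * pi / np +
                 stats::runif(1, 0, 2 * pi) +
                 stats::runif(np, -0.25, 0.25)) %% (2 * pi),
      width = stats::runif(np, 0.10, 0.22),
      length_um = stats::runif(np, 2.5, 5))
  }
  theta <- seq(0, 2 * pi, length.out = spec$n_boundary + 1L)[-(spec$n_boundary + 1L)]
  sh <- radial_shape(theta, R0, harmonics, protrusions)
  if (min(sh$r) <= 0.15 * R0) {
    stop_data("phantom spec yields a degenerate (non-simple) outline")
  }
  kappa <- polar_curvature(sh)
  S <- if (is.infinite(spec$response_steepness)) {
    ifelse(abs(kappa) < spec$kappa0_per_um, 1,
           ifelse(abs(kappa) > spec$kappa0_per_um, 0, 0.5))
  } else {
    1 / (1 + exp(spec$response_steepness * (abs(kappa) - spec$kappa0_per_um)))
  }
  A <- 1 - S
  px <- spec$pixel_size_um
  half_um <- max(sh$r) + 2
  npix <- 2L * as.integer(ceiling(half_um / px)) + 1L
  c0 <- (npix + 1) / 2                      # center pixel index
  cx <- (c0 - 1) * px; cy <- (c0 - 1) * px  # center in µm (0-based coords)
  x <- cx + sh$r * cos(theta)
  y <- cy + sh$r * sin(theta)
  s <- c(0, cumsum(sqrt(sh$r^2 + sh$rp^2) * diff(theta)[1]))[seq_along(theta)]
  # interior mask: star-shaped outline, so a polar test is exact
  xs <- matrix((seq_len(npix) - 1) * px, npix, npix, byrow = TRUE)  # x = col
  ys <- matrix((seq_len(npix) - 1) * px, npix, npix)                # y = row
  thp <- atan2(ys - cy, xs - cx)
  rho <- sqrt((xs - cx)^2 + (ys - cy)^2)
  interior <- rho <= radial_shape(thp, R0, harmonics, protrusions)$r
  img_s <- spec$cytoplasm_fill * interior
  img_a <- spec$actin_fill * interior
  # cortical band painted on the interior side of the membrane: disc centers
  # offset inward along the normal by half the band width, so the band spans
  # [0, band_um] inside the outline and segmentation recovers the outline
  xp <- sh$rp * cos(theta) - sh$r * sin(theta)
  yp <- sh$rp * sin(theta) + sh$r * cos(theta)
  speed <- sqrt(xp^2 + yp^2)
  off <- spec$band_um / 2
  xb <- x - off * yp / speed   # inward normal for ccw = rotate tangent +90
  yb <- y + off * xp / speed
  img_s <- paint_band(img_s, xb / px + 1, yb / px + 1,
                      spec$cytoplasm_fill + S, spec$band_um / (2 * px))
  img_a <- paint_band(img_a, xb / px + 1, yb / px + 1,
                      spec$actin_fill + A, spec$band_um / (2 * px))
  if (is.finite(spec$snr)) {
    sd <- 1 / spec$snr
    img_s <- img_s + matrix(stats::rnorm(npix^2, 0, sd), npix, npix)
    img_a <- img_a + matrix(stats::rnorm(npix^2, 0, sd), npix, npix)
  }
  spec$harmonics <- harmonics
  spec$protrusions <- protrusions
  list(images = list(spectrin = img_s, actin = img_a),
       truth = list(theta = theta, x_um = x, y_um = y, s_um = s,
                    kappa_per_um = kappa, spectrin = S, actin = A),
       center_um = c(x = cx, y = cy), spec = spec)
}

# Paint values onto pixels within `radius_px` of continuous sample positions
# (rowc, colc); overlapping writes resolve to the maximum painted value.
paint_band <- function(img, colc, rowc, values, radius_px) {
  nr <- nrow(img); nc <- ncol(img)
  R <- as.integer(ceiling(radius_px))
  base_r <- round(rowc); base_c <- round(colc)
  ord <- order(values)  # ascending, so the largest value wins duplicate pixels
  for (dr in -R:R) for (dc in -R:R) {
    rr <- base_r + dr; cc <- base_c + dc
    use <- (rr - rowc)^2 + (cc - colc)^2 <= radius_px^2 &
      rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    u <- ord[use[ord]]
    if (!length(u)) next
    idx <- (cc[u] - 1) * nr + rr[u]
    img[idx] <- pmax(img[idx], values[u])
  }
  img
}

# ---------------------------------------------------------------------------
# Deformation videos

#' Deformation cohort specification
#'
#' @param flow_rates flow rates Q (µL/min).
#' @param di_mean mapping Q -> mean true peak DI: a function of Q or a named
#'   numeric vector (names = Q). Default `1 + 0.04 Q`, spanning ~1.2 at
#'   Q = 5 to 2.0 at Q = 25 as in soft-cell deformability experiments.
#' @param di_sd per-cell sd of the true peak DI (truncated at DI >= 1).
#' @param n_cells_per_Q cells per flow rate (cytometry experiments typically
#'   record tens to hundreds of cells per run; default 200).
#' @param noise_sd pixel noise sd (image scale is ~1).
#' @param size_jitter relative cell-diameter jitter (uniform +/-).
#' @param base_diameter_um undeformed cell diameter.
#' @param pixel_size_um pixel size.
#' @param frame_px square frame side in pixels.
#' @param ramp DI ramp profile over the transit: fractions in (0, 1\] of the
#'   way from DI = 1 to the peak, one frame each.
#' @param gap_frames blank frames inserted after each transit.
#' @param subpixel_jitter place cell centers at random sub-pixel offsets
#'   (TRUE, unbiased extents) or exactly on pixel corners (FALSE, exact
#'   extents for integer semi-axes).
#' @param cell_contrast,bg_level cell darkness and background level.
#' @param seed RNG seed.
#' @return a `deformation_cohort_spec` list.
#' @export
deformation_cohort_spec <- function(flow_rates = c(5, 10, 15, 20, 25),
                                    di_mean = function(Q) 1 + 0.04 * Q,
                                    di_sd = 0.1, n_cells_per_Q = 200L,
                                    noise_sd = 0.05, size_jitter = 0.1,
                                    base_diameter_um = 16, pixel_size_um = 0.5,
                                    frame_px = 64L,
                                    ramp = c(0.35, 0.7, 1, 0.7, 0.35),
                                    gap_frames = 1L, subpixel_jitter = TRUE,
                                    cell_contrast = 0.7, bg_level = 1,
                                    seed = 1L) {
  if (any(flow_rates <= 0) || base_diameter_um <= 0 || pixel_size_um <= 0 ||
      n_cells_per_Q < 1L) {
    stop_config("cohort spec parameters must be positive")
  }
  if (!any(ramp == 1)) stop_config("ramp must reach 1 (the peak frame)")
  structure(list(flow_rates = flow_rates, di_mean = di_mean, di_sd = di_sd,
                 n_cells_per_Q = as.integer(n_cells_per_Q),
                 noise_sd = noise_sd, size_jitter = size_jitter,
                 base_diameter_um = base_diameter_um,
                 pixel_size_um = pixel_size_um, frame_px = as.integer(frame_px),
                 ramp = ramp, gap_frames = as.integer(gap_frames),
                 subpixel_jitter = subpixel_jitter,
                 cell_contrast = cell_contrast, bg_level = bg_level,
                 seed = as.integer(seed)),
            class = "deformation_cohort_spec")
}

di_mean_at <- function(spec, Q) {
  if (is.function(spec$di_mean)) return(spec$di_mean(Q))
  v <- spec$di_mean[as.character(Q)]
  if (any(is.na(v))) stop_config("di_mean mapping missing a flow rate")
  unname(v)
}

#' Generate cross-flow junction video frames for one or more flow rates
#'
#' Each cell transits as a run of ellipse frames whose DI ramps up to a
#' per-cell true peak (Normal(mean DI(Q), di_sd) truncated at >= 1) and back
#' down, separated by blank frames. The ellipse is area-preserving: semi-axes
#' (D/2) sqrt(DI) along the outflow (row) axis and (D/2)/sqrt(DI) along the
#' inflow (col) axis. The per-Q RNG stream is derived from the spec seed and
#' Q only, so any subset of flow rates reproduces identical frames.
#'
#' @param spec a [deformation_cohort_spec()].
#' @param flow_rates subset of `spec$flow_rates` to generate.
#' @return list with `frames` (list of matrices, all flow rates
#'   concatenated), `frame_Q` (Q label per frame), and `truth` (data frame:
#'   `cell_id`, `Q`, `true_peak_di`, `diameter_um`).
#' @export
make_deformation_video <- function(spec, flow_rates = spec$flow_rates) {
  stopifnot(inherits(spec, "deformation_cohort_spec"))
  frames <- list()
  frame_Q <- numeric(0)
  truth <- list()
  fp <- spec$frame_px
  for (Q in flow_rates) {
    set.seed((spec$seed + round(1000 * Q)) %% .Machine$integer.max)
    mu <- di_mean_at(spec, Q)
    for (ci in seq_len(spec$n_cells_per_Q)) {
      peak <- NA_real_
      for (try in 1:100) {
        peak <- stats::rnorm(1, mu, spec$di_sd)
        if (peak >= 1) break
        peak <- NA_real_
      }
      if (is.na(peak)) peak <- 1
      D_px <- spec$base_diameter_um *
        stats::runif(1, 1 - spec$size_jitter, 1 + spec$size_jitter) /
        spec$pixel_size_um
      if (D_px * sqrt(peak) >= fp - 4) {
        stop_data("cell larger than the frame; increase frame_px")
      }
      ctr <- if (spec$subpixel_jitter) {
        (fp + 1) / 2 + stats::runif(2, -0.5, 0.5)
      } else {
        rep(fp / 2 + 0.5, 2)  # pixel corner
      }
      for (f in spec$ramp) {
        di_f <- 1 + (peak - 1) * f
        a <- D_px / 2 * sqrt(di_f)   # outflow = rows
        b <- D_px / 2 / sqrt(di_f)   # inflow = cols
        rr <- matrix(seq_len(fp), fp, fp)
        cc <- t(rr)
        inside <- ((rr - ctr[1]) / a)^2 + ((cc - ctr[2]) / b)^2 <= 1
        img <- spec$bg_level - spec$cell_contrast * inside
        if (spec$noise_sd > 0) {
          img <- img + matrix(stats::rnorm(fp^2, 0, spec$noise_sd), fp, fp)
        }
        frames[[length(frames) + 1L]] <- img
        frame_Q <- c(frame_Q, Q)
      }
      for (g in seq_len(spec$gap_frames)) {
        img <- matrix(spec$bg_level, fp, fp)
        if (spec$noise_sd > 0) {
          img <- img + matrix(stats::rnorm(fp^2, 0, spec$noise_sd), fp, fp)
        }
        frames[[length(frames) + 1L]] <- img
        frame_Q <- c(frame_Q, Q)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        cell_id = sprintf("Q%g_cell%03d", Q, ci), Q = Q,
        true_peak_di = peak, diameter_um = D_px * spec$pixel_size_um)
    }
  }
  list(frames = frames, frame_Q = frame_Q, truth = do.call(rbind, truth))
}

# ---------------------------------------------------------------------------
# Gel lanes and strip spots

#' Generate a synthetic sedimentation gel image
#'
#' One lane per record, with a bound-fraction band and an unbound-fraction
#' band whose integrated volumes equal the programmed as-loaded intensities
#' `B` and `U` (the dilution factor `d` is metadata carried into the ROI
#' template, as on a real gel where the unbound lane is loaded pre-diluted).
#'
#' @param lanes data frame with columns `label`, `B`, `U`, `d` (non-negative
#'   intensities, d >= 1).
#' @param band_sigma Gaussian band sd (px), `c(row, col)`.
#' @param lane_width_px horizontal lane pitch.
#' @param snr peak of the faintest nonzero band / noise sd; noise-free when
#'   all bands are zero.
#' @param background flat background level.
#' @param seed RNG seed.
#' @return list with `image`, `rois` (per lane: `label`, `bound`, `unbound`
#'   ROIs, `d`), `truth` (the `lanes` input).
#' @export
make_gel_image <- function(lanes, band_sigma = c(2, 5), lane_width_px = 40L,
                           snr = 20, background = 10, seed = 1L) {
  lanes <- as.data.frame(lanes)
  if (any(lanes$B < 0) || any(lanes$U < 0)) {
    stop_config("band intensities must be non-negative")
  }
  if (any(lanes$d < 1)) stop_config("dilution factors must be >= 1")
  set.seed(seed)
  nl <- nrow(lanes)
  nr <- 120L
  nc <- as.integer(lane_width_px * nl + 2L * lane_width_px)
  img <- matrix(background, nr, nc)
  yB <- 40; yU <- 85
  sr <- band_sigma[1]; sc <- band_sigma[2]
  add_band <- function(img, cx, cy, volume) {
    if (volume <= 0) return(img)
    amp <- volume / (2 * pi * sr * sc)
    rr <- max(1L, floor(cy - 5 * sr)):min(nrow(img), ceiling(cy + 5 * sr))
    cc <- max(1L, floor(cx - 5 * sc)):min(ncol(img), ceiling(cx + 5 * sc))
    g <- amp * exp(-0.5 * outer((rr - cy)^2 / sr^2, (cc - cx)^2 / sc^2, "+"))
    img[rr, cc] <- img[rr, cc] + g
    img
  }
  rois <- vector("list", nl)
  for (i in seq_len(nl)) {
    cx <- lane_width_px + (i - 0.5) * lane_width_px
    img <- add_band(img, cx, yB, lanes$B[i])
    img <- add_band(img, cx, yU, lanes$U[i])
    # +/- 2 sigma: captures the same fraction of every band, which cancels
    # exactly in the binding ratio, while keeping noise accumulation low
    hw <- ceiling(2 * sc); hh <- ceiling(2 * sr)
    rois[[i]] <- list(
      label = lanes$label[i],
      bound = roi_rect(round(cx - hw), round(cx + hw), yB - hh, yB + hh),
      unbound = roi_rect(round(cx - hw), round(cx + hw), yU - hh, yU + hh),
      d = lanes$d[i])
  }
  vols <- c(lanes$B, lanes$U)
  vols <- vols[vols > 0]
  if (length(vols) && is.finite(snr)) {
    # SNR is referenced to the faintest nonzero band, so every quantified
    # band has at least the requested peak signal-to-noise
    peak_min <- min(vols) / (2 * pi * sr * sc)
    img <- img + matrix(stats::rnorm(nr * nc, 0, peak_min / snr), nr, nc)
  }
  list(image = img, rois = rois, truth = lanes)
}

#' Default lipid-strip layout
#'
#' A 2 x 8 grid of 15 membrane lipids plus one blank, mirroring commercial
#' protein-lipid overlay strips.
#'
#' @param spacing_px vertical spot pitch; horizontal pitch is 1.5x.
#' @return data frame with `label`, `cx`, `cy` (pixel coordinates).
#' @export
lipid_strip_layout <- function(spacing_px = 28L) {
  labels <- c("LPA", "LPC", "PtdIns", "PtdIns(3)P", "PtdIns(4)P",
              "PtdIns(5)P", "PE", "PC", "S1P", "PtdIns(3,4)P2",
              "PtdIns(3,5)P2", "PtdIns(4,5)P2", "PtdIns(3,4,5)P3", "PA",
              "PS", "blank")
  col <- rep(1:2, each = 8L)
  row <- rep(1:8, times = 2L)
  data.frame(label = labels,
             cx = 24L + (col - 1L) * as.integer(round(1.5 * spacing_px)),
             cy = 20L + (row - 1L) * spacing_px)
}

#' Generate a synthetic lipid-strip overlay image
#'
#' Spots at template positions with peak intensity proportional to the
#' programmed relative affinity in \[0, 1\]; labels absent from `affinities`
#' (e.g. the blank) are painted at zero.
#'
#' @param affinities named numeric vector in \[0, 1\] (lipid -> relative
#'   bound intensity).
#' @param layout spot layout data frame (`label`, `cx`, `cy`); default
#'   [lipid_strip_layout()].
#' @param spot_sigma_px Gaussian spot sd.
#' @param peak intensity of an affinity-1 spot.
#' @param background flat background level.
#' @param snr peak / noise sd.
#' @param seed RNG seed.
#' @return list with `image`, `template` (layout plus ROI radius `r`),
#'   `truth` (the affinities).
#' @export
make_strip_image <- function(affinities, layout = lipid_strip_layout(),
                             spot_sigma_px = 3, peak = 100, background = 5,
                             snr = 20, seed = 1L) {
  if (any(affinities < 0 | affinities > 1)) {
    stop_config("affinities must lie in [0, 1]")
  }
  if (!all(names(affinities) %in% layout$label)) {
    stop_config("affinity names must appear in the layout")
  }
  set.seed(seed)
  nr <- as.integer(max(layout$cy) + 20L)
  nc <- as.integer(max(layout$cx) + 24L)
  img <- matrix(background, nr, nc)
  s <- spot_sigma_px
  for (i in seq_len(nrow(layout))) {
    aff <- affinities[layout$label[i]]
    if (is.na(aff) || aff <= 0) next
    amp <- peak * aff
    rr <- max(1L, floor(layout$cy[i] - 4 * s)):min(nr, ceiling(layout$cy[i] + 4 * s))
    cc <- max(1L, floor(layout$cx[i] - 4 * s)):min(nc, ceiling(layout$cx[i] + 4 * s))
    g <- amp * exp(-0.5 * outer((rr - layout$cy[i])^2, (cc - layout$cx[i])^2,
                                "+") / s^2)
    img[rr, cc] <- img[rr, cc] + g
  }
  painted <- any(affinities > 0)
  if (is.finite(snr) && peak > 0 && painted) {
    img <- img + matrix(stats::rnorm(nr * nc, 0, peak / snr), nr, nc)
  }
  template <- layout
  template$r <- 4 * s
  list(image = img, template = template, truth = affinities)
}
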