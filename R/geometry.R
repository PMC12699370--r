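# Contour representation and curvature estimation along closed cell outlines.
#
# Conventions. Coordinates are image pixel centers (x rightwards, y downwards)
# converted to micrometres. A contour is stored with positive shoelace area,
# which we call counterclockwise; with that orientation the discrete curvature
#   kappa = (x' y'' - y' x'') / (x'^2 + y'^2)^(3/2)
# is positive wherever the center of the osculating circle lies on the
# interior (cytoplasmic) side, so a convex cell outline has kappa > 0
# everywhere and invaginations have kappa < 0. Classification downstream uses
# |kappa| only, so headline results do not depend on this sign choice.

#' Resample a closed outline to uniform arc-length spacing
#'
#' Takes a raw pixel-coordinate polygon (e.g. a traced cell boundary),
#' converts it to micrometres, normalizes its orientation to positive
#' (counterclockwise) shoelace area, and resamples it to `n_samples` points
#' uniformly spaced in arc length along the polygon.
#'
#' @param points two-column matrix or data frame of (x, y) vertices in pixel
#'   units, ordered along the outline. A duplicated closing vertex is
#'   dropped; consecutive duplicate vertices are removed.
#' @param pixel_size_um physical size of one pixel in micrometres.
#' @param n_samples number of output samples.
#' @return an object of class `cell_contour`: list with `x`, `y` (µm), `s`
#'   (arc length per sample, µm), `perimeter_um`, `n_samples`,
#'   `pixel_size_um`, `closed`, `orientation`.
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' ct <- resample_contour(sq, pixel_size_um = 1, n_samples = 400)
#' ct$perimeter_um  # 4
#' @export
resample_contour <- function(points, pixel_size_um = 1, n_samples = 1000L) {
  if (pixel_size_um <= 0) stop_config("pixel_size_um must be positive")
  if (n_samples < 8L) stop_config("n_samples must be at least 8")
  p <- as.matrix(points)
  if (ncol(p) != 2L) stop_config("points must have two columns (x, y)")
  storage.mode(p) <- "double"
  # drop a duplicated closing vertex, then consecutive duplicates
  if (nrow(p) > 1L && all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  if (nrow(p) > 1L) {
    d <- sqrt(rowSums((p - p[c(2:nrow(p), 1L), , drop = FALSE])^2))
    keep <- d > 0
    p <- p[keep, , drop = FALSE]
  }
  if (nrow(p) < 3L) stop_data("degenerate contour: fewer than 3 distinct points")
  if (nrow(p) <= 2000L && polygon_self_intersects(p[, 1L], p[, 2L])) {
    warning("contour polygon self-intersects; proceeding (touching protrusions?)")
  }
  x <- p[, 1L] * pixel_size_um
  y <- p[, 2L] * pixel_size_um
  if (shoelace_area(x, y) < 0) {
    x <- rev(x); y <- rev(y)
  }
  xc <- c(x, x[1L]); yc <- c(y, y[1L])
  seg <- sqrt(diff(xc)^2 + diff(yc)^2)
  s_cum <- c(0, cumsum(seg))
  L <- s_cum[length(s_cum)]
  s_out <- (seq_len(n_samples) - 1L) * L / n_samples
  xo <- stats::approx(s_cum, xc, xout = s_out, ties = "ordered")$y
  yo <- stats::approx(s_cum, yc, xout = s_out, ties = "ordered")$y
  structure(list(x = xo, y = yo, s = s_out, perimeter_um = L,
                 n_samples = as.integer(n_samples),
                 pixel_size_um = pixel_size_um, closed = TRUE,
                 orientation = "ccw"),
            class = "cell_contour")
}

# Periodic Savitzky-Golay first/second derivatives: local quadratic
# least-squares fit over an odd window of k samples at uniform spacing h.
# For x ~ a + b j + c j^2 (j = -m..m): b = sum(j x_j)/sum(j^2),
# c = sum((j^2 - mean(j^2)) x_j) / sum((j^2 - mean(j^2))^2).
sg_derivatives_periodic <- function(v, k, h) {
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  k <- max(k, 5L)
  n <- length(v)
  if (k >= n) stop_config("derivative window covers the whole contour")
  m <- (k - 1L) %/% 2L
  j <- -m:m
  w1 <- j / sum(j^2)
  q <- j^2 - mean(j^2)
  w2 <- 2 * q / sum(q^2)
  d1 <- numeric(n); d2 <- numeric(n)
  for (t in seq_along(j)) {
    shifted <- v[((seq_len(n) - 1L + j[t]) %% n) + 1L]
    d1 <- d1 + w1[t] * shifted
    d2 <- d2 + w2[t] * shifted
  }
  list(d1 = d1 / h, d2 = d2 / h^2)
}

# O(n^2) segment-pair intersection test (proper crossings only; shared
# endpoints of adjacent segments are ignored). Used as a sanity warning.
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n
    j <- j[!(i == 1L & j == n)]  # skip segments adjacent to i
    if (!length(j)) next
    d1 <- cross(x[i], y[i], x2[i], y2[i], x[j], y[j])
    d2 <- cross(x[i], y[i], x2[i], y2[i], x2[j], y2[j])
    d3 <- cross(x[j], y[j], x2[j], y2[j], rep(x[i], length(j)), rep(y[i], length(j)))
    d4 <- cross(x[j], y[j], x2[j], y2[j], rep(x2[i], length(j)), rep(y2[i], length(j)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Signed curvature along a uniformly resampled closed contour
#'
#' Derivatives of the coordinate functions x(s), y(s) are estimated over a
#' window of width `presmooth_window_um` — by default with periodic
#' Savitzky-Golay local quadratic fits, whose flat passband preserves genuine
#' curvature peaks while suppressing sampling noise; alternatively by
#' moving-average presmoothing followed by periodic central differences.
#' Curvature follows the standard plane-curve formula
#' \eqn{\kappa = (x'y'' - y'x'')/(x'^2+y'^2)^{3/2}}. The smoothed
#' absolute-curvature track used for enrichment classification is computed
#' with [smooth_abs_curvature()] using `abs_smooth_window_um`.
#'
#' @param contour a `cell_contour` from [resample_contour()].
#' @param presmooth_window_um derivative-estimation window (µm); `0` falls
#'   back to plain central differences.
#' @param abs_smooth_window_um window (µm) for the smoothed |kappa| track.
#' @param method `"savitzky-golay"` (default) or `"central"` (smoothed
#'   central differences).
#' @return object of class `curvature_profile`: list with `s`, `kappa`
#'   (µm^-1), `kappa_abs_smoothed`, `smoothing_window_um`,
#'   `presmooth_window_um`, `spacing_um`, `perimeter_um`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 129)[-129]
#' circ <- resample_contour(cbind(5 * cos(th), 5 * sin(th)), 1, 512)
#' cp <- signed_curvature(circ, presmooth_window_um = 0.5)
#' mean(cp$kappa)  # ~ 0.2 = 1/R
#' @export
signed_curvature <- function(contour, presmooth_window_um = 1.5,
                             abs_smooth_window_um = 2,
                             method = c("savitzky-golay", "central")) {
  stopifnot(inherits(contour, "cell_contour"))
  method <- match.arg(method)
  if (presmooth_window_um < 0) stop_config("presmooth window must be >= 0")
  L <- contour$perimeter_um
  if (presmooth_window_um > L / 2) {
    stop_config("presmooth window larger than half the contour perimeter")
  }
  n <- contour$n_samples
  h <- L / n
  x <- contour$x
  y <- contour$y
  if (method == "savitzky-golay" && presmooth_window_um > 0) {
    # local quadratic fit over the window: derivatives come straight from
    # the fit, with a much flatter passband than moving-average presmoothing
    k <- window_samples(presmooth_window_um, h)
    dx <- sg_derivatives_periodic(x, k, h)
    dy <- sg_derivatives_periodic(y, k, h)
    xp <- dx$d1; xpp <- dx$d2; yp <- dy$d1; ypp <- dy$d2
  } else {
    if (presmooth_window_um > 0) {
      k <- window_samples(presmooth_window_um, h)
      x <- moving_average_periodic(x, k)
      y <- moving_average_periodic(y, k)
    }
    ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
    xp <- (x[ip] - x[im]) / (2 * h)
    yp <- (y[ip] - y[im]) / (2 * h)
    xpp <- (x[ip] - 2 * x + x[im]) / h^2
    ypp <- (y[ip] - 2 * y + y[im]) / h^2
  }
  kappa <- (xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
  prof <- structure(list(s = contour$s, kappa = kappa,
                         kappa_abs_smoothed = abs(kappa),
                         smoothing_window_um = 0,
                         presmooth_window_um = presmooth_window_um,
                         spacing_um = h, perimeter_um = L),
                    class = "curvature_profile")
  if (abs_smooth_window_um > 0) {
    prof <- smooth_abs_curvature(prof, abs_smooth_window_um)
  }
  prof
}

#' Smooth the absolute-curvature track of a curvature profile
#'
#' Replaces `kappa_abs_smoothed` with the absolute value of the periodic
#' moving average of the signed kappa over `window_um` (smooth first, then
#' take magnitude); endpoints wrap because the contour is closed. Smoothing
#' the signed curvature lets estimator noise cancel before the absolute
#' value, so flat stretches read near zero instead of acquiring a folded
#' noise floor.
#'
#' @param profile a `curvature_profile`.
#' @param window_um averaging window in µm (> 0). Rounded to the nearest odd
#'   sample count, never below one sample.
#' @return the profile with `kappa_abs_smoothed` and `smoothing_window_um`
#'   updated.
#' @export
smooth_abs_curvature <- function(profile, window_um) {
  stopifnot(inherits(profile, "curvature_profile"))
  if (!is.numeric(window_um) || window_um <= 0) {
    stop_config("smoothing window must be positive")
  }
  k <- window_samples(window_um, profile$spacing_um)
  profile$kappa_abs_smoothed <- abs(moving_average_periodic(profile$kappa, k))
  profile$smoothing_window_um <- window_um
  profile
}

#' Total discrete turning of a contour's curvature profile
#'
#' For a simple closed counterclockwise contour the integral of kappa over
#' arc length equals 2*pi; useful as an internal consistency check.
#'
#' @param profile a `curvature_profile`.
#' @return numeric scalar, the discrete integral of kappa ds.
#' @export
total_turning <- function(profile) {
  stopifnot(inherits(profile, "curvature_profile"))
  sum(profile$kappa) * profile$spacing_um
}

#' @export
print.cell_contour <- function(x, ...) {
  cat(sprintf("<cell_contour> %d samples, perimeter %.2f um, %s, pixel %.3g um\n",
              x$n_samples, x$perimeter_um, x$orientation, x$pixel_size_um))
  invisible(x)
}

#' @export
print.curvature_profile <- function(x, ...) {
  cat(sprintf(
    "<curvature_profile> %d samples, kappa in [%.3g, %.3g] 1/um, |kappa| window %.2g um\n",
    length(x$kappa), min(x$kappa), max(x$kappa), x$smoothing_window_um))
  invisible(x)
}

#' Assemble a per-sample data frame for a contour and its profiles
#'
#' Joins contour coordinates, curvature and any number of intensity profiles
#' into one data frame with the canonical column names used by the CSV
#' serialization (`index` is 0-based).
#'
#' @param contour a `cell_contour`.
#' @param curvature optional `curvature_profile`.
#' @param intensities optional named list of `intensity_profile` objects;
#'   each adds `<name>_raw` and (if normalized) `<name>_norm` columns.
#' @return data frame with columns `index`, `s_um`, `x_um`, `y_um`, and when
#'   available `kappa_per_um`, `kappa_abs_smoothed_per_um`, intensity columns.
#' @export
profile_table <- function(contour, curvature = NULL, intensities = list()) {
  stopifnot(inherits(contour, "cell_contour"))
  df <- data.frame(index = seq_len(contour$n_samples) - 1L,
                   s_um = contour$s, x_um = contour$x, y_um = contour$y)
  if (!is.null(curvature)) {
    stopifnot(inherits(curvature, "curvature_profile"))
    if (length(curvature$kappa) != contour$n_samples) {
      stop_data("curvature profile length does not match contour")
    }
    df$kappa_per_um <- curvature$kappa
    df$kappa_abs_smoothed_per_um <- curvature$kappa_abs_smoothed
  }
  for (nm in names(intensities)) {
    pr <- intensities[[nm]]
    stopifnot(inherits(pr, "intensity_profile"))
    df[[paste0(nm, "_raw")]] <- pr$raw
    if (!is.null(pr$normalized)) df[[paste0(nm, "_norm")]] <- pr$normalized
  }
  df
}

#' Write / read a contour profile table as CSV
#'
#' The CSV round-trips: [read_profile_csv()] reconstructs the `cell_contour`
#' and (if present) the `curvature_profile` from the table.
#'
#' @param contour,curvature,intensities as in [profile_table()].
#' @param path CSV file path.
#' @param pixel_size_um pixel size recorded when reading back.
#' @return `write_profile_csv` returns `path` invisibly; `read_profile_csv`
#'   returns a list with `contour`, `curvature` (or NULL) and `table`.
#' @export
write_profile_csv <- function(contour, path, curvature = NULL,
                              intensities = list()) {
  df <- profile_table(contour, curvature, intensities)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path, pixel_size_um = 1) {
  df <- utils::read.csv(path)
  need <- c("index", "s_um", "x_um", "y_um")
  if (!all(need %in% names(df))) stop_data("profile CSV missing required columns")
  n <- nrow(df)
  L <- df$s_um[n] * n / (n - 1)  # uniform spacing: s runs 0 .. L(1 - 1/n)
  ct <- structure(list(x = df$x_um, y = df$y_um, s = df$s_um,
                       perimeter_um = L, n_samples = n,
                       pixel_size_um = pixel_size_um, closed = TRUE,
                       orientation = "ccw"),
                  class = "cell_contour")
  cp <- NULL
  if ("kappa_per_um" %in% names(df)) {
    cp <- structure(list(s = df$s_um, kappa = df$kappa_per_um,
                         kappa_abs_smoothed = df$kappa_abs_smoothed_per_um %||%
                           abs(df$kappa_per_um),
                         smoothing_window_um = NA_real_,
                         presmooth_window_um = NA_real_,
                         spacing_um = L / n, perimeter_um = L),
                    class = "curvature_profile")
  }
  list(contour = ct, curvature = cp, table = df)
}
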