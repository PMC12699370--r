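# Independent oracle implementations. These deliberately share no code with
# the package: brute-force loops and textbook formulas only.

# Signed curvature from the circumscribed circle of three points spaced m
# samples apart along a closed contour.
oracle_three_point_curvature <- function(x, y, m) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    a <- ((i - 1 - m) %% n) + 1
    b <- i
    c <- ((i - 1 + m) %% n) + 1
    ax <- x[a]; ay <- y[a]; bx <- x[b]; by <- y[b]; cx <- x[c]; cy <- y[c]
    area2 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    la <- sqrt((bx - ax)^2 + (by - ay)^2)
    lb <- sqrt((cx - bx)^2 + (cy - by)^2)
    lc <- sqrt((cx - ax)^2 + (cy - ay)^2)
    2 * area2 / (la * lb * lc)
  }, numeric(1))
}

# Brute-force periodic moving average (direct convolution loop).
oracle_periodic_moving_average <- function(v, k) {
  n <- length(v)
  m <- (k - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- ((i - 1 + (-m:m)) %% n) + 1
    out[i] <- mean(v[idx])
  }
  out
}

# Dense pixel-enumeration band average: for each contour point, loop over
# every pixel in a bounding box and average those whose center lies in the
# disc.
oracle_band_average <- function(image, x_um, y_um, pixel_size_um, band_um) {
  r <- max(band_um / 2 / pixel_size_um, 0.51)
  nr <- nrow(image); nc <- ncol(image)
  vapply(seq_along(x_um), function(i) {
    rowc <- y_um[i] / pixel_size_um + 1
    colc <- x_um[i] / pixel_size_um + 1
    rs <- max(1, floor(rowc - r - 1)):min(nr, ceiling(rowc + r + 1))
    cs <- max(1, floor(colc - r - 1)):min(nc, ceiling(colc + r + 1))
    acc <- 0; cnt <- 0
    for (rr in rs) for (cc in cs) {
      if ((rr - rowc)^2 + (cc - colc)^2 <= r^2) {
        acc <- acc + image[rr, cc]; cnt <- cnt + 1
      }
    }
    acc / cnt
  }, numeric(1))
}

# Monte-Carlo permutation test on the rank-sum statistic.
oracle_permutation_ranksum <- function(x, y, n_perm = 1e4, seed = 1) {
  set.seed(seed)
  nx <- length(x)
  pooled <- c(x, y)
  r_obs <- sum(rank(pooled)[seq_len(nx)])
  mu <- nx * (length(pooled) + 1) / 2
  stat <- abs(r_obs - mu)
  hits <- 0L
  for (p in seq_len(n_perm)) {
    pr <- sum(rank(pooled)[sample.int(length(pooled), nx)])
    if (abs(pr - mu) >= stat - 1e-9) hits <- hits + 1L
  }
  hits / n_perm
}

# Dense polygon for an analytic shape.
circle_points <- function(R, n, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + R * cos(th), cy + R * sin(th))
}

ellipse_points <- function(a, b, n) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(a * cos(th), b * sin(th))
}

# Binary disc mask.
disc_mask <- function(n, cx, cy, r) {
  m <- matrix(FALSE, n, n)
  m[(row(m) - cy)^2 + (col(m) - cx)^2 <= r^2] <- TRUE
  m
}

# A gentle phantom whose programmed profiles vary on scales wider than the
# sampling band (used for fidelity properties).
gentle_phantom_spec <- function(seed, snr = 5, kappa0 = 0.2) {
  set.seed(seed)
  harm <- data.frame(k = c(2, 4, 6), amp = c(0.05, 0.04, 0.35 * 13 / 35),
                     phase = runif(3, 0, 2 * pi))
  prot <- data.frame(theta = sort(runif(3, 0, 2 * pi)),
                     width = runif(3, 0.25, 0.35),
                     length_um = runif(3, 3, 5))
  phantom_cell_spec(harmonics = harm, protrusions = prot,
                    kappa0_per_um = kappa0, snr = snr, seed = seed)
}

# Map each contour sample to the nearest dense ground-truth sample.
nearest_truth_index <- function(contour, truth) {
  vapply(seq_len(contour$n_samples), function(i) {
    which.min((truth$x_um - contour$x[i])^2 + (truth$y_um - contour$y[i])^2)
  }, integer(1))
}
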