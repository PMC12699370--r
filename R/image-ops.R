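# Low-level raster operations used by segmentation and densitometry.
# Kept in pure R: images in this pipeline are small (a few hundred pixels per
# side) and all loops below are vectorized over pixels or structuring-element
# offsets.

#' Otsu's threshold
#'
#' Histogram-based threshold maximizing between-class variance.
#'
#' @param image numeric matrix or vector.
#' @param n_bins number of histogram bins.
#' @return threshold value on the intensity scale of `image`.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) <= 0) stop_data("image has no dynamic range")
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  n <- w[n_bins]; mtot <- mu[n_bins]
  w0 <- w[-n_bins]; w1 <- n - w0
  m0 <- mu[-n_bins] / w0
  m1 <- (mtot - mu[-n_bins]) / w1
  sb <- w0 * w1 * (m0 - m1)^2
  sb[!is.finite(sb)] <- -Inf
  mids[which.max(sb)]
}

# Connected-component labeling by layered (vectorized) flood fill.
# connectivity 4 or 8. Returns an integer matrix, 0 = background.
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8L) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  todo <- which(mask)
  id <- 0L
  for (seed in todo) {
    if (lab[seed] != 0L) next
    id <- id + 1L
    frontier <- seed
    lab[frontier] <- id
    while (length(frontier)) {
      r <- ((frontier - 1L) %% nr) + 1L
      c <- ((frontier - 1L) %/% nr) + 1L
      nb <- integer(0)
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1L]; cc <- c + offs[k, 2L]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (any(ok)) nb <- c(nb, (cc[ok] - 1L) * nr + rr[ok])
      }
      nb <- unique(nb)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- id
      frontier <- nb
    }
  }
  lab
}

# Fill interior holes: background connected (4-connectivity) to the image
# border stays background, everything else becomes foreground.
fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- !mask
  reached <- matrix(FALSE, nr, nc)
  border <- unique(c(which(bg & row(bg) == 1L), which(bg & row(bg) == nr),
                     which(bg & col(bg) == 1L), which(bg & col(bg) == nc)))
  frontier <- border
  reached[frontier] <- TRUE
  while (length(frontier)) {
    r <- ((frontier - 1L) %% nr) + 1L
    c <- ((frontier - 1L) %/% nr) + 1L
    nb <- c((c - 1L) * nr + pmax(r - 1L, 1L), (c - 1L) * nr + pmin(r + 1L, nr),
            (pmax(c - 1L, 1L) - 1L) * nr + r, (pmin(c + 1L, nc) - 1L) * nr + r)
    nb <- unique(nb)
    nb <- nb[bg[nb] & !reached[nb]]
    reached[nb] <- TRUE
    frontier <- nb
  }
  mask | (bg & !reached)
}

# Separable box blur (k x k running mean) with replicate padding, applied
# `passes` times. Two passes of a 3x3 box approximate a small Gaussian.
box_blur <- function(image, k = 3L, passes = 1L) {
  if (passes < 1L) return(image)
  half <- (k - 1L) %/% 2L
  runmean <- function(v) {
    s <- cumsum(v)
    n <- length(v)
    (s[k:n] - c(0, s[seq_len(n - k)])) / k
  }
  blur1 <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    rp <- c(rep(1L, half), seq_len(nr), rep(nr, half))
    cp <- c(rep(1L, half), seq_len(nc), rep(nc, half))
    mp <- m[rp, cp, drop = FALSE]
    a <- apply(mp, 2L, runmean)   # smooth down columns -> nr x (nc + 2*half)
    t(apply(a, 1L, runmean))      # smooth along rows   -> nr x nc
  }
  for (i in seq_len(passes)) image <- blur1(image)
  image
}

# Grayscale erosion/dilation with a disc structuring element, via pmin/pmax
# over shifted copies (replicate edge handling).
disc_filter <- function(image, radius, op = c("min", "max")) {
  op <- match.arg(op)
  nr <- nrow(image); nc <- ncol(image)
  r <- as.integer(ceiling(radius))
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, , drop = FALSE]
  out <- NULL
  for (k in seq_len(nrow(offs))) {
    ri <- pmin(pmax(seq_len(nr) + offs$dr[k], 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + offs$dc[k], 1L), nc)
    shifted <- image[ri, ci, drop = FALSE]
    out <- if (is.null(out)) shifted
           else if (op == "min") pmin(out, shifted) else pmax(out, shifted)
  }
  out
}

# Rolling-ball style background: grayscale opening (erosion then dilation)
# with a disc of the given radius.
rolling_ball_background <- function(image, radius) {
  disc_filter(disc_filter(image, radius, "min"), radius, "max")
}
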