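# Gel band / strip spot densitometry and the dilution-corrected
# sedimentation binding ratio.
#
# The binding ratio follows the quantities defined for the sedimentation
# assay readout: B is the integrated intensity of the bound-fraction lane,
# U of the unbound-fraction lane, and d the dilution factor applied to the
# unbound fraction before loading; the bound fraction is
#   ratio = B / (B + d * U),
# the only dimensionally consistent bound fraction using a dilution factor
# on U.

#' Rectangle / disc region of interest
#'
#' Pixel coordinates are 1-based and inclusive, `x` = column, `y` = row.
#'
#' @param x0,x1,y0,y1 rectangle bounds.
#' @param cx,cy,r disc center and radius.
#' @return a `roi` list usable by [integrate_roi()].
#' @export
roi_rect <- function(x0, x1, y0, y1) {
  if (x1 < x0 || y1 < y0) stop_config("invalid rectangle ROI")
  structure(list(shape = "rect", x0 = x0, x1 = x1, y0 = y0, y1 = y1),
            class = "roi")
}

#' @rdname roi_rect
#' @export
roi_disc <- function(cx, cy, r) {
  if (r <= 0) stop_config("disc ROI radius must be positive")
  structure(list(shape = "disc", cx = cx, cy = cy, r = r), class = "roi")
}

roi_indices <- function(image, roi) {
  nr <- nrow(image); nc <- ncol(image)
  if (roi$shape == "rect") {
    if (roi$x0 < 1 || roi$y0 < 1 || roi$x1 > nc || roi$y1 > nr) {
      stop_data("ROI outside image")
    }
    g <- expand.grid(r = roi$y0:roi$y1, c = roi$x0:roi$x1)
  } else {
    if (roi$cx - roi$r < 1 || roi$cx + roi$r > nc ||
        roi$cy - roi$r < 1 || roi$cy + roi$r > nr) {
      stop_data("ROI outside image")
    }
    rr <- floor(roi$cy - roi$r):ceiling(roi$cy + roi$r)
    cc <- floor(roi$cx - roi$r):ceiling(roi$cx + roi$r)
    g <- expand.grid(r = rr, c = cc)
    g <- g[(g$r - roi$cy)^2 + (g$c - roi$cx)^2 <= roi$r^2, ]
  }
  (g$c - 1L) * nr + g$r
}

roi_bbox <- function(roi) {
  if (roi$shape == "rect") {
    c(y0 = roi$y0, y1 = roi$y1, x0 = roi$x0, x1 = roi$x1)
  } else {
    c(y0 = floor(roi$cy - roi$r), y1 = ceiling(roi$cy + roi$r),
      x0 = floor(roi$cx - roi$r), x1 = ceiling(roi$cx + roi$r))
  }
}

#' Integrated, background-subtracted intensity of an ROI
#'
#' Background is estimated either from the median of a border ring of width
#' `ring_width` pixels around the ROI bounding box (`"local-median"`,
#' default) or from a rolling-ball style grayscale opening of the whole
#' image (`list(model = "rolling-ball", radius = <px>)`). Net intensity is
#' clamped at zero with a flag when the background exceeds the signal.
#'
#' @param image 2D numeric matrix.
#' @param roi an [roi_rect()] or [roi_disc()].
#' @param background `"local-median"` or a list with `model = "rolling-ball"`
#'   and `radius`.
#' @param label label stored with the record.
#' @param ring_width width (px) of the local-median background ring.
#' @return object of class `densitometry_record`: list with `label`, `roi`,
#'   `integrated_intensity` (>= 0), `background_model`, `background_level`
#'   (per-pixel estimate for local-median, `NA` for rolling-ball), `n_pixels`,
#'   `clamped`.
#' @export
integrate_roi <- function(image, roi, background = "local-median",
                          label = "roi", ring_width = 5L) {
  if (!is.matrix(image)) stop_data("image must be a 2D matrix")
  stopifnot(inherits(roi, "roi"))
  idx <- roi_indices(image, roi)
  if (identical(background, "local-median")) {
    bb <- roi_bbox(roi)
    nr <- nrow(image); nc <- ncol(image)
    y0 <- max(1L, bb["y0"] - ring_width); y1 <- min(nr, bb["y1"] + ring_width)
    x0 <- max(1L, bb["x0"] - ring_width); x1 <- min(nc, bb["x1"] + ring_width)
    outer_idx <- as.vector(outer((y0:y1), (x0:x1) - 1L,
                                 function(r, c) c * nr + r))
    inner_idx <- as.vector(outer((bb["y0"]:bb["y1"]), (bb["x0"]:bb["x1"]) - 1L,
                                 function(r, c) c * nr + r))
    ring <- setdiff(outer_idx, inner_idx)
    if (!length(ring)) stop_data("no background ring pixels around ROI")
    bg_level <- stats::median(image[ring])
    net <- sum(image[idx] - bg_level)
    model <- "local-median"
  } else if (is.list(background) &&
             identical(background$model, "rolling-ball")) {
    radius <- background$radius %||% 10
    bg_img <- rolling_ball_background(image, radius)
    net <- sum(image[idx] - bg_img[idx])
    bg_level <- NA_real_
    model <- sprintf("rolling-ball-%g", radius)
  } else {
    stop_config("unknown background model")
  }
  clamped <- net < 0
  structure(list(label = label, roi = roi,
                 integrated_intensity = max(net, 0),
                 background_model = model, background_level = bg_level,
                 n_pixels = length(idx), clamped = clamped),
            class = "densitometry_record")
}

#' @export
print.densitometry_record <- function(x, ...) {
  cat(sprintf("<densitometry_record> '%s': %.4g over %d px (%s%s)\n",
              x$label, x$integrated_intensity, x$n_pixels,
              x$background_model, if (x$clamped) ", clamped" else ""))
  invisible(x)
}

#' Dilution-corrected bound fraction
#'
#' @param B integrated intensity of the bound-fraction lane (>= 0).
#' @param U integrated intensity of the unbound-fraction lane as loaded
#'   (>= 0).
#' @param d_dil dilution factor applied to the unbound fraction before
#'   loading (>= 1).
#' @return B / (B + d_dil * U), in \[0, 1\].
#' @export
binding_ratio <- function(B, U, d_dil = 1) {
  if (any(d_dil < 1)) stop_config("dilution factor must be >= 1")
  if (any(B < 0) || any(U < 0)) stop_data("intensities must be non-negative")
  if (any(B + d_dil * U <= 0)) stop_data("undefined binding ratio: B = U = 0")
  B / (B + d_dil * U)
}

#' Relative spot intensities for a lipid-strip overlay
#'
#' Subtracts the mean intensity of the blank spots from every spot (clamping
#' at zero) and rescales so the strongest spot equals 1.
#'
#' @param records list of `densitometry_record` objects, or a data frame with
#'   `label` and `integrated_intensity` columns.
#' @param blank_labels labels of blank (no-lipid) spots.
#' @return data frame with `label`, `integrated_intensity`, `relative`. If no
#'   spot exceeds the blank level, all relatives are 0 with a warning.
#' @export
relative_spot_intensities <- function(records, blank_labels = character()) {
  df <- if (is.data.frame(records)) {
    records[, c("label", "integrated_intensity")]
  } else {
    data.frame(
      label = vapply(records, `[[`, character(1), "label"),
      integrated_intensity = vapply(records, `[[`, numeric(1),
                                    "integrated_intensity"),
      stringsAsFactors = FALSE)
  }
  is_blank <- df$label %in% blank_labels
  if (all(is_blank)) stop_data("no non-blank spots")
  blank_mean <- if (any(is_blank)) mean(df$integrated_intensity[is_blank]) else 0
  net <- pmax(df$integrated_intensity - blank_mean, 0)
  out <- df[!is_blank, , drop = FALSE]
  netv <- net[!is_blank]
  if (max(netv) <= 0) {
    warning("all spots at or below blank level; relative intensities set to 0")
    out$relative <- 0
  } else {
    out$relative <- netv / max(netv)
  }
  rownames(out) <- NULL
  out
}
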