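# Deformation-index (DI = H/W) cytometry from cross-flow junction video
# frames. H is the cell extent along the outflow axis, W along the inflow
# axis, both at the frame of maximum deformation during a transit.

#' Detect a cell and measure its axis-aligned extents in one frame
#'
#' The frame (optionally cropped to a junction ROI) is background-subtracted,
#' thresholded with Otsu on the absolute difference, and the largest
#' connected component is kept. Extents are pixel counts (max - min + 1) of
#' the component along the declared outflow/inflow axes; with sub-pixel cell
#' placement this estimator of the diameter is unbiased. Frames with no
#' usable component, a component touching the ROI edge, or no contrast
#' return `NULL` (skip signal).
#'
#' @param frame 2D numeric matrix (bright-field: cell darker or brighter than
#'   background).
#' @param roi optional `list(r0, r1, c0, c1)` crop (1-based, inclusive).
#' @param axes named character vector mapping `outflow` and `inflow` to
#'   `"row"` or `"col"`.
#' @param background scalar or matrix background estimate; default is the
#'   median of the (cropped) frame, appropriate when the cell occupies a
#'   minority of pixels.
#' @param min_area_px components smaller than this are ignored.
#' @param contrast_min minimum ratio of the peak background-subtracted
#'   intensity to the frame's noise scale (MAD); frames below it are treated
#'   as empty. Set to 0 to disable.
#' @return `NULL` (skip) or list with `H`, `W` (pixels), `mask` (logical
#'   matrix in ROI coordinates), `bbox`.
#' @export
detect_cell_extents <- function(frame, roi = NULL,
                                axes = c(outflow = "row", inflow = "col"),
                                background = NULL, min_area_px = 20L,
                                contrast_min = 8) {
  if (!is.matrix(frame)) stop_data("frame must be a 2D matrix")
  if (!setequal(names(axes), c("outflow", "inflow")) ||
      !all(axes %in% c("row", "col")) || axes["outflow"] == axes["inflow"]) {
    stop_config("axes must map outflow/inflow to distinct 'row'/'col'")
  }
  if (!is.null(roi)) {
    frame <- frame[roi$r0:roi$r1, roi$c0:roi$c1, drop = FALSE]
    if (!is.null(background) && is.matrix(background)) {
      background <- background[roi$r0:roi$r1, roi$c0:roi$c1, drop = FALSE]
    }
  }
  bg <- background %||% stats::median(frame)
  d <- abs(frame - bg)
  if (diff(range(d)) <= 0) return(NULL)
  # contrast gate: an empty (noise-only) frame has max|d| of a few noise
  # scales; a frame holding a cell is an order of magnitude above. Without
  # this gate Otsu happily thresholds pure noise and fabricates detections,
  # merging adjacent transits.
  scale <- stats::mad(d)
  if (scale > 0 && max(d) < contrast_min * scale) return(NULL)
  thr <- otsu_threshold(d)
  mask <- d > thr
  if (!any(mask)) return(NULL)
  lab <- label_components(mask, 8L)
  sizes <- tabulate(lab[lab > 0L])
  if (max(sizes) < min_area_px) return(NULL)
  comp <- lab == which.max(sizes)
  rows <- range(row(comp)[comp]); cols <- range(col(comp)[comp])
  nr <- nrow(comp); nc <- ncol(comp)
  if (rows[1] == 1L || rows[2] == nr || cols[1] == 1L || cols[2] == nc) {
    return(NULL)  # touching the ROI edge: partial cell, skip
  }
  ext <- c(row = rows[2] - rows[1] + 1L, col = cols[2] - cols[1] + 1L)
  list(H = unname(ext[axes["outflow"]]), W = unname(ext[axes["inflow"]]),
       mask = comp, bbox = list(rows = rows, cols = cols))
}

#' Deformation index
#'
#' @param H cell extent along the outflow axis.
#' @param W cell extent along the inflow axis.
#' @return DI = H/W (dimensionless; 1 = undeformed sphere).
#' @export
deformation_index <- function(H, W) {
  if (any(W <= 0)) stop_data("undefined DI: W must be positive")
  if (any(H <= 0)) stop_data("undefined DI: H must be positive")
  H / W
}

#' Track transits and report per-cell maximum deformation
#'
#' Consecutive frames with a detection form one transit (cells pass the
#' junction one at a time in dilute suspension); per transit the DI is
#' computed for every frame and the maximum reported with its frame index.
#' Single-frame transits are accepted but flagged.
#'
#' @param frames list of 2D matrices, ordered in time.
#' @param roi,axes,background,min_area_px,contrast_min passed to
#'   [detect_cell_extents()].
#' @param Q flow rate label attached to every record (µL/min).
#' @param cell_prefix prefix for generated cell ids.
#' @return object of class `di_records`: data frame with columns `cell_id`,
#'   `Q`, `frame_index_at_max` (1-based over `frames`), `H`, `W`, `DI`,
#'   `n_frames`, `single_frame`.
#' @export
track_max_deformation <- function(frames, roi = NULL,
                                  axes = c(outflow = "row", inflow = "col"),
                                  Q = NA_real_, background = NULL,
                                  min_area_px = 20L, contrast_min = 8,
                                  cell_prefix = "cell") {
  dets <- lapply(frames, detect_cell_extents, roi = roi, axes = axes,
                 background = background, min_area_px = min_area_px,
                 contrast_min = contrast_min)
  present <- !vapply(dets, is.null, logical(1))
  out <- list()
  i <- 1L; cell <- 0L
  nfr <- length(frames)
  while (i <= nfr) {
    if (!present[i]) { i <- i + 1L; next }
    j <- i
    while (j < nfr && present[j + 1L]) j <- j + 1L
    cell <- cell + 1L
    di <- vapply(i:j, function(f) deformation_index(dets[[f]]$H, dets[[f]]$W),
                 numeric(1))
    kmax <- which.max(di)
    f <- (i:j)[kmax]
    single <- (j == i)
    if (single) warning("single-frame transit accepted (flagged)")
    out[[cell]] <- data.frame(
      cell_id = sprintf("%s%03d", cell_prefix, cell), Q = Q,
      frame_index_at_max = f, H = dets[[f]]$H, W = dets[[f]]$W,
      DI = di[kmax], n_frames = j - i + 1L, single_frame = single,
      stringsAsFactors = FALSE)
    i <- j + 1L
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cell_id = character(), Q = numeric(),
               frame_index_at_max = integer(), H = numeric(), W = numeric(),
               DI = numeric(), n_frames = integer(), single_frame = logical())
  class(res) <- c("di_records", class(res))
  res
}

#' Aggregate DI records into a DI-versus-flow-rate curve
#'
#' @param records a `di_records` data frame (or any data frame with `Q` and
#'   `DI` columns).
#' @param condition optional condition label (e.g. "vector",
#'   "spectrin bII") attached to the curve.
#' @return object of class `di_curve`: data frame with `Q`, `mean_DI`,
#'   `sd_DI` (0 with `sd_undefined = TRUE` when n = 1), `n`, sorted by
#'   increasing `Q`.
#' @export
aggregate_di_curve <- function(records, condition = NA_character_) {
  if (!all(c("Q", "DI") %in% names(records))) {
    stop_data("records must contain Q and DI columns")
  }
  if (!nrow(records)) stop_data("no DI records to aggregate")
  qs <- sort(unique(records$Q))
  rows <- lapply(qs, function(q) {
    di <- records$DI[records$Q == q]
    sdv <- if (length(di) > 1L) stats::sd(di) else 0
    data.frame(Q = q, mean_DI = mean(di), sd_DI = sdv, n = length(di),
               sd_undefined = length(di) == 1L)
  })
  curve <- do.call(rbind, rows)
  attr(curve, "condition") <- condition
  class(curve) <- c("di_curve", class(curve))
  curve
}
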