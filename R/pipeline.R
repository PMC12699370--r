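# End-to-end pipeline orchestration: YAML/list configs, provenance, and the
# run_* entry points used by the command-line executable.

#' Read and validate a run configuration
#'
#' Configurations are YAML mappings (or equivalent R lists). Top-level keys
#' not recognized by the requested pipeline are rejected, so typos fail fast.
#'
#' @param config path to a YAML file, or a named list.
#' @param allowed character vector of permitted top-level keys.
#' @return the validated config list.
#' @export
read_run_config <- function(config, allowed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_config(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a YAML mapping or a list")
  if (!is.null(allowed)) {
    unknown <- setdiff(names(config), allowed)
    if (length(unknown)) {
      stop_config(sprintf("unknown config keys: %s",
                          paste(unknown, collapse = ", ")))
    }
  }
  config
}

#' Write a provenance record for a pipeline run
#'
#' Machine-readable JSON with the package version, R version, seed, the full
#' configuration and its MD5 hash -- sufficient to reproduce deterministic
#' outputs byte-identically.
#'
#' @param out_dir output directory.
#' @param config the (validated) config list.
#' @param seed seed used, if any.
#' @param extra named list of additional fields.
#' @return the provenance file path, invisibly.
#' @export
write_provenance <- function(out_dir, config, seed = NULL, extra = list()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  prov <- c(list(package = "curvassay",
                 version = as.character(utils::packageVersion("curvassay")),
                 r_version = R.version.string,
                 seed = seed, config_md5 = h, config = config), extra)
  path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}

resolve_image <- function(x) {
  if (is.matrix(x)) x else read_image(x)
}

#' Run the boundary-curvature localization pipeline on one cell
#'
#' Segments the cell (spectrin channel by default, since it marks the whole
#' cell body), extracts the boundary, estimates curvature, samples and
#' normalizes both channel profiles, classifies enriched regions, and
#' summarizes curvature by class. Writes `profile.csv`, `regions.csv`,
#' `class_kappa.csv`, `summary.json` and `provenance.json` to `out_dir`
#' when given.
#'
#' @param config list or YAML path with keys: `images` (named list with
#'   `spectrin` and `actin`: file paths or matrices), `pixel_size_um`
#'   (required; never guessed), and optionally `segmentation`
#'   (`method`, `min_area_um2`, `smooth_passes`, `channel`), `geometry`
#'   (`n_samples`, `presmooth_window_um`, `abs_smooth_window_um`),
#'   `intensity` (`band_width_um`, `inward_offset_um`, `normalization`),
#'   `enrichment`
#'   (`dominance_margin`, `intensity_floor`, `min_run_samples`,
#'   `cutoff_per_um`), `out_dir`.
#' @return list with `contour`, `curvature`, `profiles`, `labels`,
#'   `by_class`, `comparison`, `summary`, invisibly.
#' @export
run_curvature <- function(config) {
  config <- read_run_config(config, c("images", "pixel_size_um",
                                      "segmentation", "geometry", "intensity",
                                      "enrichment", "out_dir"))
  if (is.null(config$pixel_size_um)) {
    stop_config("pixel_size_um is required and never guessed from image files")
  }
  px <- config$pixel_size_um
  if (px <= 0) stop_config("pixel_size_um must be positive")
  if (is.null(config$images)) stop_config("config must provide images")
  seg <- config$segmentation %||% list()
  geo <- config$geometry %||% list()
  ints <- config$intensity %||% list()
  enr <- config$enrichment %||% list()
  imgs <- lapply(config$images, resolve_image)
  if (!all(c("spectrin", "actin") %in% names(imgs))) {
    stop_config("images must include 'spectrin' and 'actin' channels")
  }
  seg_channel <- seg$channel %||% "spectrin"
  mask <- segment_cell(imgs[[seg_channel]], method = seg$method %||% "otsu",
                       min_area_um2 = seg$min_area_um2 %||% 20,
                       pixel_size_um = px,
                       smooth_passes = seg$smooth_passes %||% 0L)
  ct <- extract_boundary(mask, n_samples = geo$n_samples %||% 1000L)
  cv <- signed_curvature(ct,
                         presmooth_window_um = geo$presmooth_window_um %||% 1.5,
                         abs_smooth_window_um = geo$abs_smooth_window_um %||% 2)
  band <- ints$band_width_um %||% 1.0
  inoff <- ints$inward_offset_um %||% 0.4
  norm_mode <- ints$normalization %||% "minmax"
  profiles <- lapply(names(imgs), function(ch) {
    normalize_profile(
      sample_boundary_intensity(imgs[[ch]], ct, band, ch,
                                inward_offset_um = inoff),
      norm_mode)
  })
  names(profiles) <- names(imgs)
  labels <- classify_enriched(profiles$actin, profiles$spectrin,
                              dominance_margin = enr$dominance_margin %||% 0.1,
                              intensity_floor = enr$intensity_floor %||% 0.3,
                              min_run_samples = enr$min_run_samples %||% 10L)
  cutoff <- enr$cutoff_per_um %||% 0.2
  cbc <- curvature_by_class(cv, labels, cutoff_per_um = cutoff)
  cmp <- compare_classes(cbc)
  summary <- list(
    perimeter_um = ct$perimeter_um,
    total_turning = total_turning(cv),
    kappa_abs_mean = mean(abs(cv$kappa)),
    cutoff_per_um = cutoff,
    by_class = cbc$summary,
    comparison = cmp[c("p_value", "effect_rank_biserial", "n_actin",
                       "n_spectrin")])
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_profile_csv(ct, file.path(config$out_dir, "profile.csv"),
                      curvature = cv, intensities = profiles)
    runs <- labels$runs
    spacing <- ct$perimeter_um / ct$n_samples
    runs$start_um <- (runs$start - 1) * spacing
    runs$end_um <- (runs$end - 1) * spacing
    utils::write.csv(runs, file.path(config$out_dir, "regions.csv"),
                     row.names = FALSE)
    ck <- class_kappa_table(cbc)
    if (!is.null(ck)) {
      utils::write.csv(ck, file.path(config$out_dir, "class_kappa.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
    write_provenance(config$out_dir,
                     config[setdiff(names(config), "images")])
  }
  invisible(list(contour = ct, curvature = cv, profiles = profiles,
                 labels = labels, by_class = cbc, comparison = cmp,
                 summary = summary))
}

#' Run deformability cytometry over Q-labeled frame sets
#'
#' @param config list or YAML path with keys: `runs` (list; each element has
#'   `Q` and `frames` -- a list of matrices, a directory, or a vector of
#'   image paths), optional `roi` (`r0`, `r1`, `c0`, `c1`), `axes` (list
#'   with `outflow`, `inflow` in `"row"`/`"col"`), `min_area_px`,
#'   `condition`, `out_dir`.
#' @return list with `records` and `curve`, invisibly. Writes `records.csv`,
#'   `curve.csv` and `provenance.json` when `out_dir` is set.
#' @export
run_deform <- function(config) {
  config <- read_run_config(config, c("runs", "roi", "axes", "min_area_px",
                                      "condition", "out_dir"))
  if (is.null(config$runs) || !length(config$runs)) {
    stop_config("config must provide runs (Q-labeled frame sets)")
  }
  axes <- c(outflow = config$axes$outflow %||% "row",
            inflow = config$axes$inflow %||% "col")
  recs <- list()
  for (run in config$runs) {
    if (is.null(run$Q) || !is.numeric(run$Q)) {
      stop_config("each run needs a numeric flow rate Q")
    }
    frames <- run$frames
    if (is.character(frames) && length(frames) == 1L && dir.exists(frames)) {
      frames <- list.files(frames, full.names = TRUE)
    }
    if (is.character(frames)) frames <- lapply(sort(frames), read_image)
    if (!length(frames)) stop_data(sprintf("no frames for Q = %g", run$Q))
    recs[[length(recs) + 1L]] <- track_max_deformation(
      frames, roi = config$roi, axes = axes, Q = run$Q,
      min_area_px = config$min_area_px %||% 20L,
      cell_prefix = sprintf("Q%g_cell", run$Q))
  }
  records <- do.call(rbind, recs)
  if (!nrow(records)) stop_data("no cells detected in any run")
  curve <- aggregate_di_curve(records,
                              condition = config$condition %||% NA_character_)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(config$out_dir, "records.csv"),
                     row.names = FALSE)
    utils::write.csv(curve, file.path(config$out_dir, "curve.csv"),
                     row.names = FALSE)
    write_provenance(config$out_dir, config[setdiff(names(config), "runs")])
  }
  invisible(list(records = records, curve = curve))
}

#' Run densitometry: sedimentation gel or lipid strip
#'
#' Gel mode integrates bound/unbound band ROIs per lane and computes the
#' dilution-corrected binding ratio B/(B + dU); strip mode integrates spot
#' ROIs and reports blank-subtracted relative intensities.
#'
#' @param config list or YAML path. Common keys: `mode` (`"gel"` or
#'   `"strip"`), `image` (path or matrix), `background` (model for
#'   [integrate_roi()]), `out_dir`. Gel mode: `rois` (per lane: `label`,
#'   `bound`, `unbound` ROIs, `d`), optional `normalize_to` (lane label for
#'   an additional normalized column). Strip mode: `template` (data frame or
#'   CSV path with `label`, `cx`, `cy`, `r`), `blank_labels`.
#' @return data frame of results, invisibly. Writes `bands.csv` +
#'   `binding.csv` (gel) or `spots.csv` (strip) and `provenance.json` when
#'   `out_dir` is set.
#' @export
run_densito <- function(config) {
  config <- read_run_config(config, c("mode", "image", "background", "rois",
                                      "template", "blank_labels",
                                      "normalize_to", "out_dir"))
  mode <- config$mode %||% "gel"
  if (is.null(config$image)) stop_config("config must provide an image")
  img <- resolve_image(config$image)
  bg <- config$background %||% "local-median"
  out <- NULL
  records <- NULL
  if (mode == "gel") {
    if (is.null(config$rois)) stop_config("gel mode requires ROI definitions")
    rows <- lapply(config$rois, function(lane) {
      rb <- as_roi(lane$bound); ru <- as_roi(lane$unbound)
      B <- integrate_roi(img, rb, bg, label = paste0(lane$label, "_bound"))
      U <- integrate_roi(img, ru, bg, label = paste0(lane$label, "_unbound"))
      d <- lane$d %||% 1
      data.frame(label = lane$label, B = B$integrated_intensity,
                 U = U$integrated_intensity, d = d,
                 ratio = binding_ratio(B$integrated_intensity,
                                       U$integrated_intensity, d))
    })
    out <- do.call(rbind, rows)
    if (!is.null(config$normalize_to)) {
      ref <- out$ratio[out$label == config$normalize_to]
      if (!length(ref)) stop_config("normalize_to lane not found")
      out$ratio_normalized <- out$ratio / ref
    }
    records <- out[, c("label", "B", "U", "d")]
  } else if (mode == "strip") {
    tpl <- config$template
    if (is.null(tpl)) stop_config("strip mode requires a spot template")
    if (is.character(tpl)) tpl <- utils::read.csv(tpl)
    tpl <- as.data.frame(tpl)
    recs <- lapply(seq_len(nrow(tpl)), function(i) {
      integrate_roi(img, roi_disc(tpl$cx[i], tpl$cy[i], tpl$r[i]), bg,
                    label = tpl$label[i])
    })
    out <- relative_spot_intensities(recs,
                                     blank_labels = config$blank_labels %||%
                                       "blank")
    records <- data.frame(
      label = vapply(recs, `[[`, character(1), "label"),
      integrated_intensity = vapply(recs, `[[`, numeric(1),
                                    "integrated_intensity"))
  } else {
    stop_config("mode must be 'gel' or 'strip'")
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (mode == "gel") {
      utils::write.csv(records, file.path(config$out_dir, "bands.csv"),
                       row.names = FALSE)
      utils::write.csv(out, file.path(config$out_dir, "binding.csv"),
                       row.names = FALSE)
    } else {
      utils::write.csv(out, file.path(config$out_dir, "spots.csv"),
                       row.names = FALSE)
    }
    write_provenance(config$out_dir, config[setdiff(names(config), "image")])
  }
  invisible(out)
}

# Accept an roi object or a plain list from YAML.
as_roi <- function(x) {
  if (inherits(x, "roi")) return(x)
  if (!is.list(x)) stop_config("invalid ROI specification")
  if (!is.null(x$shape) && x$shape == "disc") {
    roi_disc(x$cx, x$cy, x$r)
  } else {
    roi_rect(x$x0, x$x1, x$y0, x$y1)
  }
}
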