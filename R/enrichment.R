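# Classification of actin- vs spectrin-enriched boundary regions and
# comparison of their local curvature distributions.
#
# A boundary sample is assigned to a channel when that channel's normalized
# intensity is above an absolute floor AND exceeds the other channel by a
# dominance margin; contiguous runs (circular, since the contour is closed)
# shorter than a minimum length are dropped. This makes the by-eye shading of
# enriched regions explicit and testable.

#' Classify enriched boundary regions from two normalized profiles
#'
#' @param actin,spectrin normalized `intensity_profile` objects of equal
#'   length ([normalize_profile()] must have been applied).
#' @param dominance_margin minimum normalized-intensity excess over the other
#'   channel.
#' @param intensity_floor minimum normalized intensity for assignment.
#' @param min_run_samples enriched runs shorter than this are reset to
#'   `unassigned`.
#' @return object of class `region_labels`: list with `labels` (character
#'   vector: `actin_enriched`, `spectrin_enriched`, `unassigned`), `runs`
#'   (data frame `start`, `end`, `label`, `length`; 1-based inclusive sample
#'   indices, `end < start` marks a run wrapping through the contour origin),
#'   and `params`.
#' @export
classify_enriched <- function(actin, spectrin, dominance_margin = 0.1,
                              intensity_floor = 0.3, min_run_samples = 10L) {
  stopifnot(inherits(actin, "intensity_profile"),
            inherits(spectrin, "intensity_profile"))
  a <- actin$normalized; s <- spectrin$normalized
  if (is.null(a) || is.null(s)) stop_data("profiles must be normalized first")
  if (length(a) != length(s)) stop_data("profile lengths differ")
  n <- length(a)
  lab <- rep("unassigned", n)
  lab[a >= intensity_floor & (a - s) >= dominance_margin] <- "actin_enriched"
  lab[s >= intensity_floor & (s - a) >= dominance_margin] <- "spectrin_enriched"
  lab <- drop_short_runs(lab, min_run_samples)
  structure(list(labels = lab, runs = circular_runs(lab),
                 params = list(dominance_margin = dominance_margin,
                               intensity_floor = intensity_floor,
                               min_run_samples = as.integer(min_run_samples))),
            class = "region_labels")
}

# Runs of equal labels on a circular index; a run crossing the wrap point is
# reported once with end < start.
circular_runs <- function(lab) {
  n <- length(lab)
  r <- rle(lab)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  df <- data.frame(start = starts, end = starts + r$lengths - 1L,
                   label = r$values, length = r$lengths,
                   stringsAsFactors = FALSE)
  if (nrow(df) > 1L && df$label[1L] == df$label[nrow(df)]) {
    df$start[1L] <- df$start[nrow(df)]
    df$length[1L] <- df$length[1L] + df$length[nrow(df)]
    df <- df[-nrow(df), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

drop_short_runs <- function(lab, min_run_samples) {
  if (min_run_samples <= 1L) return(lab)
  runs <- circular_runs(lab)
  n <- length(lab)
  for (i in seq_len(nrow(runs))) {
    if (runs$label[i] != "unassigned" && runs$length[i] < min_run_samples) {
      idx <- if (runs$end[i] >= runs$start[i]) runs$start[i]:runs$end[i]
             else c(runs$start[i]:n, 1:runs$end[i])
      lab[idx] <- "unassigned"
    }
  }
  lab
}

#' @export
print.region_labels <- function(x, ...) {
  tb <- table(factor(x$labels, c("actin_enriched", "spectrin_enriched",
                                 "unassigned")))
  cat(sprintf("<region_labels> %d samples: actin %d, spectrin %d, unassigned %d (%d runs)\n",
              length(x$labels), tb[1], tb[2], tb[3], nrow(x$runs)))
  invisible(x)
}

#' Pool smoothed |kappa| values by enrichment class
#'
#' Collects `kappa_abs_smoothed` at the samples of each enriched class and
#' summarizes them (median, quartiles, and the fraction of samples below a
#' curvature cutoff; the default cutoff 0.2 µm^-1 is the flat-membrane
#' preference threshold reported for spectrin).
#'
#' @param curvature a `curvature_profile`.
#' @param labels a `region_labels` of matching length.
#' @param cutoff_per_um |kappa| cutoff for the below-cutoff fraction.
#' @return object of class `curvature_by_class`: list with `values` (named
#'   list of |kappa| vectors), `summary` (data frame: class, n, median_kappa,
#'   q25, q75, frac_below_cutoff) and `cutoff_per_um`. Empty classes get an
#'   `NA` summary row rather than an error.
#' @export
curvature_by_class <- function(curvature, labels, cutoff_per_um = 0.2) {
  stopifnot(inherits(curvature, "curvature_profile"),
            inherits(labels, "region_labels"))
  if (length(curvature$kappa_abs_smoothed) != length(labels$labels)) {
    stop_data("curvature profile and labels have different lengths")
  }
  classes <- c("actin_enriched", "spectrin_enriched")
  vals <- lapply(classes, function(cl) {
    curvature$kappa_abs_smoothed[labels$labels == cl]
  })
  names(vals) <- classes
  summ <- do.call(rbind, lapply(classes, function(cl) {
    v <- vals[[cl]]
    if (!length(v)) {
      data.frame(class = cl, n = 0L, median_kappa = NA_real_, q25 = NA_real_,
                 q75 = NA_real_, frac_below_cutoff = NA_real_)
    } else {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(class = cl, n = length(v), median_kappa = q[2], q25 = q[1],
                 q75 = q[3], frac_below_cutoff = mean(v < cutoff_per_um))
    }
  }))
  rownames(summ) <- NULL
  structure(list(values = vals, summary = summ, cutoff_per_um = cutoff_per_um),
            class = "curvature_by_class")
}

#' @export
print.curvature_by_class <- function(x, ...) {
  cat(sprintf("<curvature_by_class> cutoff %.3g 1/um\n", x$cutoff_per_um))
  print(x$summary)
  invisible(x)
}

#' Rank-based comparison of class curvature distributions
#'
#' Two-sided Wilcoxon rank-sum test on |kappa| between the actin- and
#' spectrin-enriched classes, plus a rank-biserial effect size
#' (\eqn{r = 2 P(|\kappa|_{actin} > |\kappa|_{spectrin}) - 1}; +1 when all
#' actin values exceed all spectrin values, 0 for identical distributions).
#' Reported as descriptive support: the underlying study shows the
#' distributions without naming a test.
#'
#' @param cbc a `curvature_by_class`.
#' @return list with `statistic` (Mann-Whitney U for actin vs spectrin),
#'   `p_value`, `effect_rank_biserial`, `n_actin`, `n_spectrin`, `method`.
#'   If either class has fewer than 3 samples the result is `NA` with a
#'   warning.
#' @export
compare_classes <- function(cbc) {
  stopifnot(inherits(cbc, "curvature_by_class"))
  x <- cbc$values$actin_enriched
  y <- cbc$values$spectrin_enriched
  if (length(x) < 3L || length(y) < 3L) {
    warning("a class has fewer than 3 samples; comparison undefined")
    return(list(statistic = NA_real_, p_value = NA_real_,
                effect_rank_biserial = NA_real_,
                n_actin = length(x), n_spectrin = length(y),
                method = "wilcoxon rank-sum (undefined)"))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  u <- unname(wt$statistic)  # number of (x, y) pairs with x > y (+ ties/2)
  a <- u / (length(x) * length(y))
  list(statistic = u, p_value = wt$p.value, effect_rank_biserial = 2 * a - 1,
       n_actin = length(x), n_spectrin = length(y), method = wt$method)
}

#' Long-format per-class curvature table
#'
#' @param cbc a `curvature_by_class`.
#' @return data frame with columns `class` and `kappa_abs_per_um`, one row
#'   per enriched boundary sample.
#' @export
class_kappa_table <- function(cbc) {
  stopifnot(inherits(cbc, "curvature_by_class"))
  do.call(rbind, lapply(names(cbc$values), function(cl) {
    v <- cbc$values[[cl]]
    if (!length(v)) return(NULL)
    data.frame(class = cl, kappa_abs_per_um = v)
  }))
}
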