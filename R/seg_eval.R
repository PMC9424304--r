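#' Pixel confusion counts for the plumage class
#'
#' Tallies true positives (`p_ii`: plumage pixels predicted plumage), false
#' negatives (`p_ij`: plumage predicted non-plumage), false positives (`p_ji`)
#' and true negatives (`p_jj`) between a predicted and a ground-truth mask.
#'
#' @param pred,truth logical matrices of identical shape (TRUE = plumage)
#' @return object of class `confusion_counts` (named list of the 4 tallies)
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    uvp_stop("shape_error", "pred and truth masks differ in shape")
  }
  out <- list(
    p_ii = sum(pred & truth),
    p_ij = sum(!pred & truth),
    p_ji = sum(pred & !truth),
    p_jj = sum(!pred & !truth)
  )
  structure(out, class = "confusion_counts")
}

metric_ratio <- function(num, den, what) {
  if (den <= 0) {
    uvp_warn("undefined_metric", paste(what, "undefined (zero denominator)"))
    return(NA_real_)
  }
  num / den
}

#' Segmentation metrics from confusion counts
#'
#' Intersection over union, precision (positive predictive value) and recall
#' (sensitivity) of the plumage class:
#' `IOU = p_ii / (p_ii + p_ij + p_ji)`, `precision = p_ii / (p_ii + p_ji)`,
#' `recall = p_ii / (p_ii + p_ij)`. Undefined metrics (zero denominator) are
#' reported as `NA` with a classed warning, never coerced to 0.
#'
#' @param counts a `confusion_counts`
#' @return proportion in \[0, 1\], or NA when undefined
#' @export
iou <- function(counts) {
  with(counts, metric_ratio(p_ii, p_ii + p_ij + p_ji, "IOU"))
}

#' @rdname iou
#' @export
precision <- function(counts) {
  with(counts, metric_ratio(p_ii, p_ii + p_ji, "precision"))
}

#' @rdname iou
#' @export
recall <- function(counts) {
  with(counts, metric_ratio(p_ii, p_ii + p_ij, "recall"))
}

#' Mean IOU over the two pixel classes
#'
#' Unweighted mean of the plumage-class IOU and the non-plumage-class IOU
#' (computed from the same counts with the class roles swapped).
#'
#' @param counts a `confusion_counts`
#' @return proportion
#' @export
mean_iou <- function(counts) {
  other <- structure(list(p_ii = counts$p_jj, p_ij = counts$p_ji,
                          p_ji = counts$p_ij, p_jj = counts$p_ii),
                     class = "confusion_counts")
  mean(c(iou(counts), iou(other)))
}

#' Evaluate a batch of mask pairs
#'
#' Computes the per-image plumage-class metrics and batch summaries: means
#' (overall and per group), minima, and the fraction of images whose IOU /
#' precision / recall exceed 0.90, 0.75 and 0.50. Undefined (NA) metrics are
#' excluded from summaries and their count reported.
#'
#' @param preds,truths lists of logical masks, matched by position
#' @param groups optional grouping labels (e.g. specimen view), one per pair
#' @return list with `per_image` (tibble: id, group, iou, precision, recall),
#'   `summary` (tibble: group incl. "overall", metric, mean, min,
#'   frac_gt_90/75/50, n, n_undefined)
#' @export
evaluate_batch <- function(preds, truths, groups = NULL) {
  stopifnot(length(preds) == length(truths), length(preds) >= 1)
  if (is.null(groups)) groups <- rep("all", length(preds))
  per <- dplyr::bind_rows(lapply(seq_along(preds), function(i) {
    cc <- confusion(preds[[i]], truths[[i]])
    tibble::tibble(id = i, group = groups[[i]], iou = iou(cc),
                   precision = precision(cc), recall = recall(cc))
  }))
  long <- tidyr_pivot(per)
  summarise_grp <- function(d, label) {
    dplyr::summarise(
      dplyr::group_by(d, .data$metric),
      group = label,
      mean = mean(.data$value, na.rm = TRUE),
      min = suppressWarnings(min(.data$value, na.rm = TRUE)),
      frac_gt_90 = mean(.data$value > 0.90, na.rm = TRUE),
      frac_gt_75 = mean(.data$value > 0.75, na.rm = TRUE),
      frac_gt_50 = mean(.data$value > 0.50, na.rm = TRUE),
      n = sum(!is.na(.data$value)),
      n_undefined = sum(is.na(.data$value)),
      .groups = "drop"
    )
  }
  overall <- summarise_grp(long, "overall")
  by_group <- dplyr::bind_rows(lapply(split(long, long$group), function(d) {
    summarise_grp(d, d$group[1])
  }))
  list(per_image = per,
       summary = dplyr::bind_rows(overall, by_group))
}

# minimal long-format pivot (metric, value) without a tidyr dependency
tidyr_pivot <- function(per) {
  dplyr::bind_rows(lapply(c("iou", "precision", "recall"), function(m) {
    tibble::tibble(id = per$id, group = per$group, metric = m,
                   value = per[[m]])
  }))
}
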