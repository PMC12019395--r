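# Evaluation metrics and case-study statistics.
#
# Segmentation quality is summarised by mIoU = TP / (TP + FN + FP) with
# precision and recall alongside, and binned into low (mIoU <= 0.5, needs
# major revision), medium (0.5 < mIoU <= 0.7, may need fine-tuning) and
# high (mIoU > 0.7, usable without fine-tuning). Study-level statistics
# work on per-mouse medians of plaque area.

#' Pixel-level segmentation metrics against a ground truth
#'
#' Conventions: with no predicted positives, precision is 0 (with a
#' warning); with both masks empty, mIoU is 1 (an empty prediction of an
#' empty slide is perfect, which plaque-free slides require).
#'
#' @param pred,gt [binary_mask]s (or logical matrices) of equal shape.
#' @return an object of class `seg_metrics`: `tp`, `fp`, `fn`, `tn`,
#'   `miou`, `precision`, `recall`, `quality`.
#' @export
seg_metrics <- function(pred, gt) {
  p <- if (inherits(pred, "binary_mask")) pred$values else pred
  g <- if (inherits(gt, "binary_mask")) gt$values else gt
  if (!all(dim(p) == dim(g))) stop("shape mismatch")
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  miou <- if (tp + fn + fp == 0L) 1 else tp / (tp + fn + fp)
  precision <- if (tp + fp == 0L) {
    warning("no predicted positives; precision set to 0")
    0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 1 else tp / (tp + fn)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, miou = miou,
                 precision = precision, recall = recall,
                 quality = quality_bin(miou)),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("<seg_metrics: mIoU %.3f (%s), precision %.3f, recall %.3f>\n",
              x$miou, x$quality, x$precision, x$recall))
  invisible(x)
}

#' Quality bin of an mIoU value
#'
#' `low` for mIoU <= 0.5, `medium` for 0.5 < mIoU <= 0.7, `high` for
#' mIoU > 0.7 (both boundaries belong to the lower bin).
#'
#' @param miou value in `[0, 1]`.
#' @return `"low"`, `"medium"` or `"high"`.
#' @export
quality_bin <- function(miou) {
  if (any(miou < 0 | miou > 1)) stop("mIoU must lie in [0, 1]")
  ifelse(miou <= 0.5, "low", ifelse(miou <= 0.7, "medium", "high"))
}

#' Summarise a list of segmentation metrics as one method row
#'
#' @param metrics list of `seg_metrics`.
#' @return one-row data frame: mean and sample sd of precision, recall and
#'   mIoU, and the percentage of slides per quality bin (summing to 100
#'   before rounding). The `_sd` columns are sample standard deviations.
#' @export
summarize_method <- function(metrics) {
  if (length(metrics) == 0L) stop("empty metrics list")
  g <- function(f) vapply(metrics, `[[`, numeric(1), f)
  qual <- vapply(metrics, `[[`, character(1), "quality")
  n <- length(metrics)
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  data.frame(n = n,
             precision_mean = mean(g("precision")),
             precision_sd = sd0(g("precision")),
             recall_mean = mean(g("recall")), recall_sd = sd0(g("recall")),
             miou_mean = mean(g("miou")), miou_sd = sd0(g("miou")),
             pct_low = 100 * sum(qual == "low") / n,
             pct_medium = 100 * sum(qual == "medium") / n,
             pct_high = 100 * sum(qual == "high") / n)
}

#' Aggregate plaque results into per-mouse study records
#'
#' @param results list of `plaque_result`.
#' @param metadata data frame with columns `mouse_id`, `sex`, `genotype`,
#'   `diet` (one row per slide or per mouse; labels must be consistent
#'   within a mouse).
#' @return data frame with one row per mouse: group labels, slide count and
#'   the median plaque area in mm^2 (midpoint convention for even counts).
#' @export
per_mouse_aggregate <- function(results, metadata) {
  areas <- data.frame(mouse_id = vapply(results, `[[`, character(1),
                                        "mouse_id"),
                      area = vapply(results, `[[`, numeric(1),
                                    "plaque_area_mm2"))
  meta <- unique(metadata[, intersect(c("mouse_id", "sex", "genotype",
                                        "diet"), names(metadata))])
  if (anyDuplicated(meta$mouse_id)) {
    stop("inconsistent group labels within a mouse")
  }
  out <- do.call(rbind, lapply(split(areas, areas$mouse_id), function(d) {
    data.frame(mouse_id = d$mouse_id[1L], n_slides = nrow(d),
               median_area_mm2 = stats::median(d$area))
  }))
  out <- merge(out, meta, by = "mouse_id", all.x = TRUE, sort = TRUE)
  rownames(out) <- NULL
  out
}

#' Correlation and regression of predicted against reference plaque areas
#'
#' Ordinary least squares of prediction on reference (reference on the
#' x-axis), plus the Pearson correlation coefficient.
#'
#' @param pred_areas,ref_areas paired per-mouse vectors (same order,
#'   length >= 3).
#' @return list with `pearson_r`, `slope`, `intercept`, `n`.
#' @export
compare_to_reference <- function(pred_areas, ref_areas) {
  if (length(pred_areas) != length(ref_areas)) stop("unpaired vectors")
  if (length(pred_areas) < 3L) stop("need at least 3 paired mice")
  if (stats::sd(pred_areas) == 0 || stats::sd(ref_areas) == 0) {
    stop("zero variance in predictions or reference")
  }
  fit <- stats::lm(pred_areas ~ ref_areas)
  list(pearson_r = stats::cor(pred_areas, ref_areas),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]), n = length(pred_areas))
}

#' Pairwise group comparisons of per-mouse medians
#'
#' Two-sample Student's t-tests (equal variance, two-sided) between every
#' pair of groups defined by the interaction of the grouping columns;
#' Welch's correction is available by flag. Pairs with fewer than 2 mice in
#' either group are skipped with a warning.
#'
#' @param records per-mouse data frame from [per_mouse_aggregate].
#' @param grouping columns defining the groups (default sex + genotype +
#'   diet).
#' @param welch use Welch's unequal-variance t-test instead.
#' @return data frame: `group1`, `group2`, `n1`, `n2`, `t`, `p_value`.
#' @export
group_compare <- function(records, grouping = c("sex", "genotype", "diet"),
                          welch = FALSE) {
  grouping <- intersect(grouping, names(records))
  if (length(grouping) == 0L) stop("no grouping columns present")
  key <- interaction(records[, grouping, drop = FALSE], drop = TRUE,
                     sep = ":")
  groups <- split(records$median_area_mm2, key)
  nms <- names(groups)
  rows <- list()
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j <= i) next
      a <- groups[[i]]; b <- groups[[j]]
      if (length(a) < 2L || length(b) < 2L) {
        warning("skipping pair ", nms[i], " vs ", nms[j],
                ": fewer than 2 mice in a group")
        next
      }
      if (stats::var(a) == 0 && stats::var(b) == 0) {
        # degenerate case t.test refuses: constant groups
        tstat <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
        pval <- if (mean(a) == mean(b)) 1 else 0
      } else {
        tt <- stats::t.test(a, b, var.equal = !welch)
        tstat <- unname(tt$statistic)
        pval <- tt$p.value
      }
      rows[[length(rows) + 1L]] <-
        data.frame(group1 = nms[i], group2 = nms[j], n1 = length(a),
                   n2 = length(b), t = tstat, p_value = pval)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(group1 = character(), group2 = character(),
                      n1 = integer(), n2 = integer(), t = numeric(),
                      p_value = numeric()))
  }
  do.call(rbind, rows)
}
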