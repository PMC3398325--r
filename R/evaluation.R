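# Pixel-wise evaluation of a predicted tumour mask against ground truth.
#
# Counts follow the mask-subtraction scheme: FN = |truth \ pred|,
# FP = |pred \ truth|, TP = |pred| - FP (identical to |pred & truth|),
# TN = total - |pred| - FN. The four metrics are percentages; a zero
# denominator yields NA (undefined), never an error.

#' Pixel confusion counts from prediction and truth masks
#'
#' @param pred,truth Logical matrices of identical dimensions.
#' @return Object of class `confusion_counts`: list with `tp`, `fp`, `fn`,
#'   `tn`, `total`. Always satisfies `tp + fp + fn + tn == total`.
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot(is.logical(pred), is.logical(truth),
            is.matrix(pred), is.matrix(truth))
  if (!identical(dim(pred), dim(truth))) {
    stop_chromaseg(sprintf(
      "prediction (%d x %d) and truth (%d x %d) dimensions differ",
      nrow(pred), ncol(pred), nrow(truth), ncol(truth)),
      "chromaseg_shape_error")
  }
  total <- length(pred)
  fn <- sum(truth & !pred)
  fp <- sum(pred & !truth)
  n_pred <- sum(pred)
  tp <- n_pred - fp
  tn <- total - n_pred - fn
  out <- list(tp = tp, fp = fp, fn = fn, tn = tn, total = total)
  stopifnot(tp + fp + fn + tn == total, tp >= 0, tn >= 0)
  structure(out, class = "confusion_counts")
}

ratio_pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den

#' Per-image segmentation metrics
#'
#' `se = 100 * tp / (tp + fn)`, `sp = 100 * tn / (tn + fp)`,
#' `ppv = 100 * tp / (tp + fp)`, `npv = 100 * tn / (tn + fn)`; a zero
#' denominator gives `NA`.
#'
#' @param counts A `confusion_counts` object.
#' @param image_id Identifier carried into the record.
#' @param subtype Optional group label (e.g. `"nodular"`).
#' @return One-row `data.frame`: `image_id`, `subtype`, `tp`, `fp`, `fn`,
#'   `tn`, `se`, `sp`, `ppv`, `npv`.
#' @export
compute_metrics <- function(counts, image_id = NA_character_,
                            subtype = NA_character_) {
  stopifnot(inherits(counts, "confusion_counts"))
  data.frame(image_id = as.character(image_id),
             subtype = as.character(subtype),
             tp = counts$tp, fp = counts$fp, fn = counts$fn, tn = counts$tn,
             se  = ratio_pct(counts$tp, counts$tp + counts$fn),
             sp  = ratio_pct(counts$tn, counts$tn + counts$fp),
             ppv = ratio_pct(counts$tp, counts$tp + counts$fp),
             npv = ratio_pct(counts$tn, counts$tn + counts$fn),
             stringsAsFactors = FALSE)
}

#' Macro-averaged metric summary by subtype
#'
#' Per-image macro-averaging: the unweighted mean of each defined metric
#' over images, per subtype and pooled (`"All"`). Undefined (`NA`) metrics
#' are excluded from their mean; the number of images contributing to each
#' mean is reported. Pixel-pooled aggregation (summing counts before
#' computing metrics) is available via `pooled = TRUE` for sensitivity
#' analyses.
#'
#' @param records `data.frame` of per-image records from [compute_metrics()]
#'   (rows may be concatenated with `rbind`).
#' @param pooled If `TRUE`, additionally compute metrics from the pooled
#'   pixel counts (columns `pooled_se` etc.).
#' @return `data.frame` with columns `group`, `n`, `mean_se`, `mean_sp`,
#'   `mean_ppv`, `mean_npv`, `n_se`, `n_sp`, `n_ppv`, `n_npv` (counts of
#'   images with the metric defined).
#' @export
aggregate_metrics <- function(records, pooled = FALSE) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop_chromaseg("no metric records to aggregate", "chromaseg_argument_error")
  }
  metric_cols <- c("se", "sp", "ppv", "npv")
  stopifnot(all(c("subtype", metric_cols) %in% names(records)))
  groups <- unique(records$subtype)
  groups <- groups[!is.na(groups)]
  one <- function(label, rows) {
    out <- data.frame(group = label, n = nrow(rows))
    for (m in metric_cols) {
      vals <- rows[[m]]
      out[[paste0("mean_", m)]] <- if (all(is.na(vals))) NA_real_ else
        mean(vals, na.rm = TRUE)
      out[[paste0("n_", m)]] <- sum(!is.na(vals))
    }
    if (pooled) {
      tp <- sum(rows$tp); fp <- sum(rows$fp)
      fn <- sum(rows$fn); tn <- sum(rows$tn)
      out$pooled_se  <- ratio_pct(tp, tp + fn)
      out$pooled_sp  <- ratio_pct(tn, tn + fp)
      out$pooled_ppv <- ratio_pct(tp, tp + fp)
      out$pooled_npv <- ratio_pct(tn, tn + fn)
    }
    out
  }
  res <- do.call(rbind, c(
    lapply(groups, function(g) one(g, records[records$subtype %in% g, ])),
    list(one("All", records))))
  rownames(res) <- NULL
  res
}
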