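#' Pixel confusion counts for binary segmentation
#'
#' Tallies true/false positives/negatives over all pixels, with the FAZ
#' (label 1) as the positive class. These four counts underpin every
#' reported metric.
#'
#' @param pred predicted mask: matrix or (N, H, W) array with labels 0/1.
#' @param truth ground-truth mask of identical shape.
#' @return object of class `confusion_counts`: list with `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("shape mismatch: pred is ", paste(dim(pred), collapse = "x"),
         ", truth is ", paste(dim(truth), collapse = "x"))
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("mask labels must be 0 (background) or 1 (FAZ)")
  structure(list(
    tp = sum(pred == 1 & truth == 1),
    tn = sum(pred == 0 & truth == 0),
    fp = sum(pred == 1 & truth == 0),
    fn = sum(pred == 0 & truth == 1)
  ), class = "confusion_counts")
}

check_counts <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts") ||
              all(c("tp", "tn", "fp", "fn") %in% names(counts)))
  tot <- counts$tp + counts$tn + counts$fp + counts$fn
  if (tot <= 0) stop("confusion counts are all zero")
  tot
}

#' Mean intersection-over-union (percent)
#'
#' Average of the per-class IoU over background and FAZ:
#' `0.5 * [TP/(TP+FP+FN) + TN/(TN+FN+FP)] * 100`. A class absent from both
#' prediction and truth contributes IoU 1 (degenerate-union convention).
#'
#' @param counts a [confusion()] result.
#' @return percentage in `[0, 100]`.
#' @export
miou <- function(counts) {
  check_counts(counts)
  iou1 <- with(counts, if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn))
  iou0 <- with(counts, if (tn + fn + fp == 0) 1 else tn / (tn + fn + fp))
  100 * (iou0 + iou1) / 2
}

#' Pixel accuracy (percent)
#'
#' `(TP + TN) / (TP + FP + TN + FN) * 100`.
#'
#' @inheritParams miou
#' @return percentage in `[0, 100]`.
#' @export
acc <- function(counts) {
  tot <- check_counts(counts)
  100 * (counts$tp + counts$tn) / tot
}

#' Dice coefficient (percent)
#'
#' `2 TP / (2 TP + FP + FN) * 100`; returns 100 when both masks are empty.
#'
#' @inheritParams miou
#' @return percentage in `[0, 100]`.
#' @export
dice_coef <- function(counts) {
  check_counts(counts)
  den <- 2 * counts$tp + counts$fp + counts$fn
  if (den == 0) return(100)
  100 * 2 * counts$tp / den
}

#' Metric report over an image set
#'
#' Computes MIoU, accuracy and Dice with both aggregation conventions:
#' macro (mean of per-image metrics, the default headline numbers) and
#' micro (metrics of the pooled pixel counts). The report records which
#' convention its headline values use.
#'
#' @param pred list of predicted masks, or an (N, H, W) array.
#' @param truth ground-truth masks in the same form.
#' @param aggregate `"macro"` or `"micro"`, the headline convention.
#' @return object of class `metric_report`: list with `macro`, `micro`,
#'   `per_image` (data frame), `aggregate`, and headline `miou`, `acc`,
#'   `dice`.
#' @export
metric_report <- function(pred, truth, aggregate = c("macro", "micro")) {
  aggregate <- match.arg(aggregate)
  ps <- mask_list_any(pred)
  ys <- mask_list_any(truth)
  if (length(ps) != length(ys)) stop("pred and truth have different lengths")
  per <- lapply(seq_along(ps), function(n) {
    cc <- confusion(ps[[n]], ys[[n]])
    data.frame(image = n, miou = miou(cc), acc = acc(cc), dice = dice_coef(cc),
               tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn)
  })
  per <- do.call(rbind, per)
  macro <- c(miou = mean(per$miou), acc = mean(per$acc), dice = mean(per$dice))
  pooled <- structure(list(tp = sum(per$tp), tn = sum(per$tn),
                           fp = sum(per$fp), fn = sum(per$fn)),
                      class = "confusion_counts")
  micro <- c(miou = miou(pooled), acc = acc(pooled), dice = dice_coef(pooled))
  head <- if (aggregate == "macro") macro else micro
  structure(list(macro = macro, micro = micro, per_image = per,
                 aggregate = aggregate,
                 miou = unname(head["miou"]), acc = unname(head["acc"]),
                 dice = unname(head["dice"])),
            class = "metric_report")
}

mask_list_any <- function(x) {
  if (is.list(x)) return(x)
  mask_list(x)
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d image(s), headline aggregation: %s\n",
              nrow(x$per_image), x$aggregate))
  cat(sprintf("  macro: MIoU %.2f  ACC %.2f  Dice %.2f\n",
              x$macro["miou"], x$macro["acc"], x$macro["dice"]))
  cat(sprintf("  micro: MIoU %.2f  ACC %.2f  Dice %.2f\n",
              x$micro["miou"], x$micro["acc"], x$micro["dice"]))
  invisible(x)
}

#' Write a metric report to CSV and/or JSON
#'
#' The CSV holds one row per image; the JSON holds the macro and micro
#' summaries plus the aggregation label.
#'
#' @param report a [metric_report()] object.
#' @param csv_path per-image CSV path (or `NULL` to skip).
#' @param json_path summary JSON path (or `NULL` to skip).
#' @return the report, invisibly.
#' @export
write_metric_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "metric_report"))
  if (!is.null(csv_path))
    write.csv(report$per_image, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(aggregate = report$aggregate,
           macro = as.list(report$macro), micro = as.list(report$micro)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
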