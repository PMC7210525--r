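# Pixelwise evaluation of a predicted mask against a reference mask.

#' Pixelwise confusion counts
#'
#' @param pred,truth Logical matrices of the same shape.
#' @return An object of class `confusion_counts` with integer fields `tp`,
#'   `fp`, `tn`, `fn` summing to the number of pixels.
#' @export
confusion_counts <- function(pred, truth) {
  check_mask(pred, "pred")
  check_mask(truth, "truth")
  check_same_shape(pred, truth, "pred and truth")
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tn <- length(pred) - tp - fp - fn
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: tp = %d, fp = %d, tn = %d, fn = %d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Dice similarity coefficient
#'
#' `2 tp / (2 tp + fp + fn)`; 1 is perfect overlap, and values above 0.70
#' are conventionally read as excellent agreement. Undefined (an error of
#' class `octdme_undefined_metric_error`) when both masks are empty.
#'
#' @param counts A [confusion_counts()] object.
#' @return Numeric scalar in `[0, 1]`.
#' @export
dice <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  denom <- 2 * counts$tp + counts$fp + counts$fn
  if (denom == 0) {
    stop_octdme("Dice is undefined: both masks are empty",
                "octdme_undefined_metric_error")
  }
  2 * counts$tp / denom
}

#' Precision, sensitivity and specificity
#'
#' `precision = tp/(tp+fp)`, `sensitivity = tp/(tp+fn)`,
#' `specificity = tn/(tn+fp)`. A zero denominator marks only that component
#' as `NA` (undefined), not a hard failure.
#'
#' @param counts A [confusion_counts()] object.
#' @return List with `precision`, `sensitivity`, `specificity`.
#' @export
precision_sensitivity_specificity <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(
    precision = ratio(counts$tp, counts$tp + counts$fp),
    sensitivity = ratio(counts$tp, counts$tp + counts$fn),
    specificity = ratio(counts$tn, counts$tn + counts$fp)
  )
}

#' Full evaluation report for a mask pair
#'
#' Computes the confusion counts and all four metrics over the full image
#' grid. Undefined metrics are `NA` in the list and `null` in the JSON
#' serialization.
#'
#' @param pred,truth Logical matrices of the same shape.
#' @return List with `dice`, `precision`, `sensitivity`, `specificity`,
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
metrics_report <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  pss <- precision_sensitivity_specificity(cc)
  d <- tryCatch(dice(cc),
                octdme_undefined_metric_error = function(e) NA_real_)
  list(dice = d, precision = pss$precision, sensitivity = pss$sensitivity,
       specificity = pss$specificity,
       tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn)
}

#' Serialize a metrics report as JSON
#'
#' @param report A [metrics_report()] list.
#' @return A JSON string (undefined metrics as `null`).
#' @export
metrics_json <- function(report) {
  jsonlite::toJSON(report, auto_unbox = TRUE, na = "null", digits = NA)
}
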