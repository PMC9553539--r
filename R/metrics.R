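# Confusion-count bookkeeping and the five evaluation measures.

#' Confusion counts from binary predictions
#'
#' @param y_true,y_pred Binary vectors (0/1, logical, or a factor with two
#'   levels) of equal length.
#' @return Object of class `ppi_confusion`: named integer vector with
#'   elements `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length")
  }
  to01 <- function(v, what) {
    if (is.factor(v)) v <- as.character(v)
    if (is.logical(v)) v <- as.integer(v)
    v <- suppressWarnings(as.numeric(v))
    if (anyNA(v) || !all(v %in% c(0, 1))) {
      stop(what, " must be binary (0/1)")
    }
    as.integer(v)
  }
  yt <- to01(y_true, "y_true")
  yp <- to01(y_pred, "y_pred")
  out <- c(TP = sum(yt == 1L & yp == 1L),
           TN = sum(yt == 0L & yp == 0L),
           FP = sum(yt == 0L & yp == 1L),
           FN = sum(yt == 1L & yp == 0L))
  class(out) <- "ppi_confusion"
  out
}

#' Evaluation metrics from confusion counts
#'
#' Computes the five measures
#' \deqn{sensitivity = TP/(TP+FN),\ precision = TP/(TP+FP),}
#' \deqn{specificity = TN/(TN+FP),\ accuracy = (TP+TN)/n,}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}.}
#' A metric whose denominator is zero is reported as `NA` (never silently
#' zero) and listed in the `"undefined"` attribute, so downstream argmax
#' logic can treat it explicitly.
#'
#' @param counts A `ppi_confusion` vector, or any named vector/list with
#'   elements `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector of class `ppi_metrics` with elements
#'   `sensitivity`, `precision`, `specificity`, `accuracy`, `mcc`;
#'   attribute `"undefined"` names the metrics with zero denominators and
#'   attribute `"counts"` retains the input counts.
#' @examples
#' compute_metrics(c(TP = 411, TN = 404, FP = 96, FN = 89))
#' @export
compute_metrics <- function(counts) {
  cn <- as.list(counts)[c("TP", "TN", "FP", "FN")]
  if (anyNA(names(cn)) || any(vapply(cn, is.null, logical(1)))) {
    stop("counts must provide TP, TN, FP and FN")
  }
  tp <- as.numeric(cn$TP); tn <- as.numeric(cn$TN)
  fp <- as.numeric(cn$FP); fn <- as.numeric(cn$FN)
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be non-negative")
  n <- tp + tn + fp + fn
  if (n == 0) stop("counts are all zero")

  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  prec <- ratio(tp, tp + fp)
  spec <- ratio(tn, tn + fp)
  acc <- (tp + tn) / n
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / sqrt(mcc_den) else NA_real_

  out <- c(sensitivity = sens, precision = prec, specificity = spec,
           accuracy = acc, mcc = mcc)
  undef <- names(out)[is.na(out)]
  attr(out, "undefined") <- undef
  attr(out, "counts") <- c(TP = tp, TN = tn, FP = fp, FN = fn)
  class(out) <- "ppi_metrics"
  out
}

#' @export
print.ppi_metrics <- function(x, digits = 4, ...) {
  v <- unclass(x)
  attributes(v) <- list(names = names(v))
  print(round(v, digits))
  undef <- attr(x, "undefined")
  if (length(undef)) cat("undefined (zero denominator):",
                         paste(undef, collapse = ", "), "\n")
  invisible(x)
}
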