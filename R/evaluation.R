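# Diagnostic evaluation: empirical ROC curve, trapezoidal area, the
# Hanley-McNeil standard error, and plain accuracy. The positive class is
# "abnormal" (+1), following the clinical true-positive convention.

#' Empirical ROC curve and area
#'
#' Sweeps a decision threshold over all distinct score values (ties step the
#' curve diagonally), computing sensitivity against 1 - specificity, and
#' integrates the area by the trapezoidal rule. Equivalent to the rank-sum
#' (Mann-Whitney) estimator with half-credit for tied positive/negative
#' pairs.
#'
#' @param scores Numeric decision values (larger = more abnormal).
#' @param labels Labels +1 (abnormal, positive) / -1 (normal).
#' @return An object of class `roc_result`: `curve` data frame
#'   (`threshold`, `tpr`, `fpr`), `az`, `se` (Hanley-McNeil), `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1 / -1")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == -1)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC needs both classes present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == -1) / n_neg,
                numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), tpr = c(0, tpr),
                      fpr = c(0, fpr))
  az <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                 utils::tail(curve$tpr, -1)) / 2)
  structure(
    list(curve = curve, az = az,
         se = auc_standard_error(az, n_pos, n_neg),
         n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: Az = %.4f (SE %.4f), %d positive / %d negative\n",
              x$az, x$se, x$n_pos, x$n_neg))
  invisible(x)
}

#' Hanley-McNeil standard error of an ROC area
#'
#' `SE = sqrt((A(1-A) + (n_pos - 1)(Q1 - A^2) + (n_neg - 1)(Q2 - A^2)) /
#' (n_pos * n_neg))` with `Q1 = A / (2 - A)` and
#' `Q2 = 2 A^2 / (1 + A)`.
#'
#' @param az Area under the curve, in `[0, 1]`.
#' @param n_pos,n_neg Class sizes (>= 1).
#' @return Standard error of the area estimate.
#' @export
auc_standard_error <- function(az, n_pos, n_neg) {
  if (az < 0 || az > 1) stop("area must lie in [0, 1]")
  if (n_pos < 1 || n_neg < 1) stop("class counts must be >= 1")
  q1 <- az / (2 - az)
  q2 <- 2 * az^2 / (1 + az)
  sqrt((az * (1 - az) + (n_pos - 1) * (q1 - az^2) +
          (n_neg - 1) * (q2 - az^2)) / (n_pos * n_neg))
}

#' Classification accuracy
#'
#' @param predictions,labels Equal-length vectors of class labels.
#' @return Fraction of agreeing entries.
#' @export
accuracy <- function(predictions, labels) {
  if (length(predictions) == 0) stop("empty input")
  if (length(predictions) != length(labels)) stop("length mismatch")
  mean(predictions == labels)
}

#' Export an ROC curve as CSV
#'
#' Columns `threshold,tpr,fpr`.
#'
#' @param roc A [roc_auc()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roc_csv <- function(roc, path) {
  stopifnot(inherits(roc, "roc_result"))
  utils::write.csv(roc$curve, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
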