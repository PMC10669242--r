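# ---------------------------------------------------------------------------
# Evaluation metrics: classification accuracy (%) and mean intersection over
# union from dataset-aggregated per-class confusion counts.
# ---------------------------------------------------------------------------

#' Classification accuracy in percent
#'
#' @param predictions,truth equal-length vectors of class indices.
#' @return \code{100 * matches / total}.
#' @examples
#' accuracy(c(0, 1, 2, 2), c(0, 1, 2, 0))  # 75
#' @export
accuracy <- function(predictions, truth) {
  if (length(predictions) == 0L) stop("empty input", call. = FALSE)
  if (length(predictions) != length(truth))
    stop("predictions and truth must have equal length", call. = FALSE)
  100 * mean(predictions == truth)
}

#' Per-class confusion counts
#'
#' Accumulates true positives, false positives and false negatives per class
#' over all pixels of all supplied maps (dataset-level aggregation).
#'
#' @param pred_maps,true_maps class-index maps (values in \code{0:(C-1)});
#'   a matrix, an array, or a list of matrices.
#' @param C number of classes (>= 2).
#' @return data.frame with columns \code{class} (0-based), \code{tp},
#'   \code{fp}, \code{fn}.
#' @export
confusion_counts <- function(pred_maps, true_maps, C) {
  if (C < 2L) stop("C must be >= 2", call. = FALSE)
  p <- unlist(lapply(if (is.list(pred_maps)) pred_maps else list(pred_maps),
                     as.integer), use.names = FALSE)
  t <- unlist(lapply(if (is.list(true_maps)) true_maps else list(true_maps),
                     as.integer), use.names = FALSE)
  if (length(p) != length(t))
    stop("prediction and truth shapes do not match", call. = FALSE)
  if (any(p >= C) || any(t >= C) || any(p < 0) || any(t < 0))
    stop(sprintf("labels must lie in [0, %d)", C), call. = FALSE)
  tab <- table(factor(t, levels = 0:(C - 1)), factor(p, levels = 0:(C - 1)))
  tp <- diag(tab)
  data.frame(class = 0:(C - 1), tp = as.numeric(tp),
             fp = as.numeric(colSums(tab) - tp),
             fn = as.numeric(rowSums(tab) - tp))
}

#' Mean intersection over union
#'
#' Computes \code{mean_c TP_c / (TP_c + FP_c + FN_c)} from confusion counts
#' aggregated over the whole dataset. A class absent from both prediction and
#' truth (all three counts zero) is excluded from the mean to avoid 0/0; the
#' exclusion is recorded in the \code{"excluded"} attribute.
#'
#' @inheritParams confusion_counts
#' @return mIoU in \code{[0, 1]}.
#' @examples
#' mean_iou(matrix(c(0, 1, 0, 1), 2), matrix(c(0, 1, 1, 1), 2), C = 2)  # 7/12
#' @export
mean_iou <- function(pred_maps, true_maps, C) {
  cc <- confusion_counts(pred_maps, true_maps, C)
  denom <- cc$tp + cc$fp + cc$fn
  present <- denom > 0
  iou <- cc$tp[present] / denom[present]
  out <- mean(iou)
  attr(out, "excluded") <- cc$class[!present]
  out
}
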