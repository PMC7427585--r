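# Segmentation accuracy metrics: pixel confusion counts, the derived scores
# (IoU/Jaccard, Sorensen-Dice, pixel accuracy, precision, recall, F1), and
# average precision at an IoU threshold (PASCAL VOC style, all-point
# interpolation).

#' Pixelwise confusion counts between predicted and truth masks
#'
#' @param pred,truth 0/1 matrices of identical dimensions.
#' @return named numeric vector (tp, fp, tn, fn); the four counts sum to
#'   the pixel count.
#' @export
confusionCounts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have identical dimensions")
  p <- pred == 1L; t <- truth == 1L
  c(tp = sum(p & t), fp = sum(p & !t), tn = sum(!p & !t), fn = sum(!p & t))
}

#' Segmentation scores from confusion counts
#'
#' Computes IoU = TP/(TP+FP+FN), Dice = 2TP/(2TP+FP+FN), pixel accuracy =
#' (TP+TN)/total, precision = TP/(TP+FP), recall = TP/(TP+FN), and
#' F1 = 2 precision recall / (precision + recall). F1 equals Dice exactly,
#' and Dice = 2 IoU / (1 + IoU). A score whose denominator is zero is 1
#' when both masks are empty and 0 otherwise, keeping metrics defined on
#' empty pots.
#'
#' @param counts named vector from [confusionCounts()], or a 0/1 matrix
#'   (then `truth` must be given and counts are computed first).
#' @param truth optional truth mask when `counts` is a predicted mask.
#' @return named numeric vector: iou, dice, pixelAcc, precision, recall, f1.
#' @examples
#' segScores(c(tp = 1, fp = 3, tn = 9, fn = 3))
#' @export
segScores <- function(counts, truth = NULL) {
  if (!is.null(truth)) counts <- confusionCounts(counts, truth)
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  bothEmpty <- (tp + fp + fn) == 0
  rat <- function(num, den) if (den == 0) as.numeric(bothEmpty) else num / den
  precision <- rat(tp, tp + fp)
  recall <- rat(tp, tp + fn)
  f1 <- if (precision + recall == 0) as.numeric(bothEmpty)
        else 2 * precision * recall / (precision + recall)
  c(iou = rat(tp, tp + fp + fn),
    dice = rat(2 * tp, 2 * tp + fp + fn),
    pixelAcc = (tp + tn) / (tp + tn + fp + fn),
    precision = precision, recall = recall, f1 = f1)
}

#' Intersection over union of two masks
#'
#' @param a,b 0/1 matrices of identical dimensions.
#' @return |A intersect B| / |A union B|; 1 when both masks are empty.
#' @export
maskIoU <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must have identical dimensions")
  inter <- sum(a == 1L & b == 1L)
  union <- sum(a == 1L | b == 1L)
  if (union == 0) 1 else inter / union
}

#' Average precision at an IoU threshold
#'
#' Predictions are sorted by descending confidence; each is a true positive
#' when its best IoU against a not-yet-matched truth instance reaches the
#' threshold (greedy matching), otherwise a false positive. The
#' precision-recall curve is accumulated over that ordering and AP is the
#' area under the envelope of maximum precision at recall >= r (all-point
#' interpolation).
#'
#' @param predictions list of predicted 0/1 masks.
#' @param scores numeric confidences, one per prediction.
#' @param truths non-empty list of ground-truth 0/1 masks (one per
#'   instance).
#' @param iouThreshold matching threshold (default 0.5, the AP at 0.5 IoU
#'   measure).
#' @return AP in \[0, 1\].
#' @examples
#' t1 <- matrix(0L, 4, 4); t1[1:2, 1:2] <- 1L
#' apAtIoU(list(t1), scores = 0.9, truths = list(t1))   # 1
#' @export
apAtIoU <- function(predictions, scores, truths, iouThreshold = 0.5) {
  if (!length(truths)) stop("truth list must be non-empty")
  if (length(predictions) != length(scores))
    stop("need one score per prediction")
  if (!length(predictions)) return(0)
  ord <- order(-scores)
  matched <- rep(FALSE, length(truths))
  tpSeq <- logical(length(predictions))
  for (k in seq_along(ord)) {
    p <- predictions[[ord[k]]]
    ious <- vapply(seq_along(truths), function(j)
      if (matched[j]) -1 else maskIoU(p, truths[[j]]), numeric(1))
    j <- which.max(ious)
    if (ious[j] >= iouThreshold) { matched[j] <- TRUE; tpSeq[k] <- TRUE }
  }
  cumTp <- cumsum(tpSeq)
  recall <- cumTp / length(truths)
  precision <- cumTp / seq_along(tpSeq)
  # envelope of maximum precision for recall >= r, integrated over recall
  mrec <- c(0, recall)
  mpre <- c(0, precision)
  for (i in rev(seq_len(length(mpre) - 1))) mpre[i] <- max(mpre[i], mpre[i + 1])
  sum(diff(mrec) * mpre[-1])
}

#' Score a set of predicted masks and write a per-image CSV
#'
#' Convenience evaluation over matched prediction/truth pairs: one score
#' row per image plus the set-level AP at 0.5 IoU.
#'
#' @param predictions named list of predicted 0/1 masks.
#' @param truths list of truth masks, same length and order.
#' @param scores confidences for the AP computation (default all 1).
#' @param file optional CSV path (columns image_id, iou, dice, pixel_acc,
#'   precision, recall, f1).
#' @return list with `perImage` (data.frame) and `ap50`.
#' @export
evaluateSegmentation <- function(predictions, truths, scores = NULL, file = NULL) {
  stopifnot(length(predictions) == length(truths))
  if (is.null(scores)) scores <- rep(1, length(predictions))
  ids <- names(predictions)
  if (is.null(ids)) ids <- sprintf("image%03d", seq_along(predictions))
  perImage <- do.call(rbind, lapply(seq_along(predictions), function(i) {
    s <- segScores(confusionCounts(predictions[[i]], truths[[i]]))
    data.frame(image_id = ids[i], iou = s[["iou"]], dice = s[["dice"]],
               pixel_acc = s[["pixelAcc"]], precision = s[["precision"]],
               recall = s[["recall"]], f1 = s[["f1"]],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(file)) write.csv(perImage, file, row.names = FALSE)
  list(perImage = perImage,
       ap50 = apAtIoU(predictions, scores, truths, iouThreshold = 0.5))
}
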