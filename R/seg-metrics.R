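# Segmentation evaluation: per-class pixel confusion counts, IoU = TP/(TP+FP+FN),
# Dice = 2TP/(2TP+FP+FN), and their class means (mIoU, mDice).  The mean by
# default runs over the three foreground structures (k = 3); background can
# be included (k = 4).

#' Per-class pixel confusion counts
#'
#' Exact pixel-set arithmetic for one class on one mask pair: TP = pixels of
#' the class in both masks, FP = predicted but not true, FN = true but not
#' predicted, TN = the rest.
#'
#' @param pred,truth integer label matrices of identical shape.
#' @param classId class code counted as positive.
#' @return Named integer vector \code{c(tp, fp, fn, tn)}.
#' @export
#' @examples
#' p <- matrix(0L, 4, 4); p[1:2, 1:2] <- 1L
#' t <- matrix(0L, 4, 4); t[1:2, 1:3] <- 1L
#' pixelConfusion(p, t, 1)
pixelConfusion <- function(pred, truth, classId) {
  if (!identical(dim(pred), dim(truth))) stop("mask shapes differ")
  pp <- pred == classId
  tt <- truth == classId
  tp <- sum(pp & tt)
  c(tp = tp, fp = sum(pp) - tp, fn = sum(tt) - tp,
    tn = length(pred) - sum(pp | tt))
}

#' @rdname iou
#' @export
iou <- function(confusion) {
  den <- confusion[["tp"]] + confusion[["fp"]] + confusion[["fn"]]
  if (den == 0) 1 else confusion[["tp"]] / den
}

#' IoU and Dice from confusion counts
#'
#' \code{iou}: TP/(TP+FP+FN); \code{dice}: 2TP/(2TP+FP+FN).  The
#' empty-vs-empty case (zero denominator) returns 1 by convention: a class
#' absent from both masks is a correct outcome.
#'
#' @param confusion counts from \code{\link{pixelConfusion}} (any vector or
#'   list with \code{tp}, \code{fp}, \code{fn}).
#' @return numeric in [0,1].
#' @name iou
#' @export
dice <- function(confusion) {
  den <- 2 * confusion[["tp"]] + confusion[["fp"]] + confusion[["fn"]]
  if (den == 0) 1 else 2 * confusion[["tp"]] / den
}

#' Mean segmentation metrics over a class set
#'
#' Arithmetic means of per-class IoU and Dice.  By default the mean runs
#' over the foreground classes only (background excluded, k = classes - 1);
#' set \code{includeBackground} for the k-class mean with background.
#'
#' @param perClass numeric matrix with one row per class (background first)
#'   and columns \code{IoU}, \code{Dice}; typically rows 0..K-1 of class
#'   codes.
#' @param includeBackground include the first row in the mean.
#' @return A \linkS4class{SegReport}.
#' @export
meanMetrics <- function(perClass, includeBackground = FALSE) {
  if (nrow(perClass) < 1L) stop("empty class set")
  sel <- if (includeBackground) seq_len(nrow(perClass))
         else setdiff(seq_len(nrow(perClass)), 1L)
  if (length(sel) == 0L) stop("empty class set after excluding background")
  new("SegReport", perClass = perClass,
      mIoU = mean(perClass[sel, "IoU"]),
      mDice = mean(perClass[sel, "Dice"]),
      includeBackground = includeBackground, k = length(sel))
}

#' Evaluate predicted masks against ground truth
#'
#' Computes per-class IoU/Dice and their means over a set of mask pairs.
#' \code{aggregate = "macro"} (default) computes metrics per image and
#' averages over images; \code{"global"} pools confusion counts over all
#' images first.
#'
#' @param preds,truths lists of integer label matrices (or single matrices).
#' @param numClasses total classes including background (default 4).
#' @param includeBackground include background in the means.
#' @param aggregate \code{"macro"} or \code{"global"}.
#' @return A \linkS4class{SegReport}.
#' @export
evaluateSegmentation <- function(preds, truths, numClasses = 4L,
                                 includeBackground = FALSE,
                                 aggregate = c("macro", "global")) {
  aggregate <- match.arg(aggregate)
  if (is.matrix(preds)) preds <- list(preds)
  if (is.matrix(truths)) truths <- list(truths)
  stopifnot(length(preds) == length(truths), length(preds) > 0)
  classes <- seq_len(numClasses) - 1L
  if (aggregate == "macro") {
    acc <- matrix(0, numClasses, 2, dimnames = list(classes, c("IoU", "Dice")))
    for (i in seq_along(preds)) {
      for (c in classes) {
        cf <- pixelConfusion(preds[[i]], truths[[i]], c)
        acc[c + 1L, "IoU"] <- acc[c + 1L, "IoU"] + iou(cf)
        acc[c + 1L, "Dice"] <- acc[c + 1L, "Dice"] + dice(cf)
      }
    }
    perClass <- acc / length(preds)
  } else {
    perClass <- t(vapply(classes, function(c) {
      tot <- c(tp = 0, fp = 0, fn = 0, tn = 0)
      for (i in seq_along(preds))
        tot <- tot + pixelConfusion(preds[[i]], truths[[i]], c)
      c(IoU = iou(tot), Dice = dice(tot))
    }, numeric(2)))
    dimnames(perClass) <- list(classes, c("IoU", "Dice"))
  }
  meanMetrics(perClass, includeBackground)
}
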