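# Detection evaluation at box-IoU threshold 0.5: greedy confidence-ordered
# one-to-one matching, precision/recall/F1, PR curve with all-point
# (precision-envelope) interpolated AP, category-mean mAP, ROC AUC as the
# normalized Mann-Whitney statistic, and the paired comparison used for
# before/after reader studies.

#' Intersection over union of two boxes
#'
#' Boxes are in normalized center form \code{c(cx, cy, w, h)}.
#'
#' @param a,b numeric length-4 vectors (or named) in [0,1] coordinates.
#' @return numeric IoU in [0,1].
#' @export
#' @examples
#' boxIou(c(0.25, 0.5, 0.5, 1), c(0.5, 0.5, 0.5, 1))  # 1/3
boxIou <- function(a, b) {
  ax0 <- a[[1]] - a[[3]] / 2; ax1 <- a[[1]] + a[[3]] / 2
  ay0 <- a[[2]] - a[[4]] / 2; ay1 <- a[[2]] + a[[4]] / 2
  bx0 <- b[[1]] - b[[3]] / 2; bx1 <- b[[1]] + b[[3]] / 2
  by0 <- b[[2]] - b[[4]] / 2; by1 <- b[[2]] + b[[4]] / 2
  iw <- max(0, min(ax1, bx1) - max(ax0, bx0))
  ih <- max(0, min(ay1, by1) - max(ay0, by0))
  inter <- iw * ih
  un <- a[[3]] * a[[4]] + b[[3]] * b[[4]] - inter
  if (un <= 0) 0 else inter / un
}

.asBoxDf <- function(x, needConf = FALSE) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L))
    return(data.frame(category = character(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric(), confidence = numeric()))
  stopifnot(is.data.frame(x))
  if (needConf && is.null(x$confidence)) stop("detections need a confidence column")
  x
}

#' Match detections to ground-truth boxes
#'
#' Per category, detections are taken in order of descending confidence;
#' each claims the not-yet-claimed ground-truth box of highest IoU at or
#' above the threshold (one-to-one).  Claimed detections are TP, unclaimed
#' detections FP, unclaimed truths FN.
#'
#' @param dets data.frame of detections (\code{category, cx, cy, w, h,
#'   confidence}).
#' @param truths data.frame of ground-truth boxes (\code{category, cx, cy,
#'   w, h}).
#' @param iouThreshold IoU threshold in (0, 1], default 0.5.
#' @return list with \code{confusion} (named tp/fp/fn), \code{matches}
#'   (data.frame det row, truth row, iou), and per-detection logical
#'   \code{detTp} in confidence order within category.
#' @export
matchDetections <- function(dets, truths, iouThreshold = 0.5) {
  stopifnot(iouThreshold > 0, iouThreshold <= 1)
  dets <- .asBoxDf(dets, needConf = TRUE)
  truths <- .asBoxDf(truths)
  matches <- data.frame(det = integer(), truth = integer(), iou = numeric())
  detTp <- logical(nrow(dets))
  claimed <- logical(nrow(truths))
  for (cat in unique(c(dets$category, truths$category))) {
    di <- which(dets$category == cat)
    di <- di[order(-dets$confidence[di])]
    ti <- which(truths$category == cat)
    for (d in di) {
      if (!length(ti)) break
      ious <- vapply(ti, function(t)
        boxIou(dets[d, c("cx", "cy", "w", "h")],
               truths[t, c("cx", "cy", "w", "h")]), numeric(1))
      ious[claimed[ti]] <- -1
      best <- which.max(ious)
      if (ious[best] >= iouThreshold) {
        claimed[ti[best]] <- TRUE
        detTp[d] <- TRUE
        matches <- rbind(matches, data.frame(det = d, truth = ti[best],
                                             iou = ious[best]))
      }
    }
  }
  list(confusion = c(tp = sum(detTp), fp = sum(!detTp),
                     fn = sum(!claimed)),
       matches = matches, detTp = detTp)
}

#' @rdname detPrecision
#' @export
detPrecision <- function(confusion) {
  den <- confusion[["tp"]] + confusion[["fp"]]
  if (den == 0) 0 else confusion[["tp"]] / den
}

#' @rdname detPrecision
#' @export
detRecall <- function(confusion) {
  den <- confusion[["tp"]] + confusion[["fn"]]
  if (den == 0) 0 else confusion[["tp"]] / den
}

#' Precision, recall and F1 from detection confusion counts
#'
#' P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R) = 2TP/(2TP+FP+FN); zero
#' denominators return 0.
#'
#' @param confusion vector or list with \code{tp}, \code{fp}, \code{fn}.
#' @return numeric in [0,1].
#' @name detPrecision
#' @export
detF1 <- function(confusion) {
  den <- 2 * confusion[["tp"]] + confusion[["fp"]] + confusion[["fn"]]
  if (den == 0) 0 else 2 * confusion[["tp"]] / den
}

#' F1 as the harmonic mean of precision and recall
#'
#' @param precision,recall numerics in [0,1].
#' @return 2PR/(P+R); 0 when both are 0.
#' @export
#' @examples
#' f1Score(0.795, 0.743)  # 0.768 to 3 decimals
f1Score <- function(precision, recall) {
  s <- precision + recall
  ifelse(s == 0, 0, 2 * precision * recall / s)
}

#' Precision-recall curve over a detection sweep
#'
#' Detections (pooled or single-category) are sorted by descending
#' confidence; at each prefix the precision and recall against the given
#' truths are recorded.  Matching marks each detection TP or FP with the
#' full-list greedy matcher, so the sweep is consistent with
#' \code{\link{matchDetections}}.
#'
#' @param dets,truths as in \code{\link{matchDetections}}.
#' @param iouThreshold IoU threshold.
#' @return data.frame with columns \code{confidence}, \code{recall},
#'   \code{precision}, ordered by descending confidence.
#' @export
prCurve <- function(dets, truths, iouThreshold = 0.5) {
  truths <- .asBoxDf(truths)
  if (nrow(truths) == 0L) stop("PR curve needs at least one ground-truth box")
  dets <- .asBoxDf(dets, needConf = TRUE)
  mm <- matchDetections(dets, truths, iouThreshold)
  ord <- order(-dets$confidence)
  tp <- cumsum(mm$detTp[ord])
  fp <- cumsum(!mm$detTp[ord])
  data.frame(confidence = dets$confidence[ord],
             recall = tp / nrow(truths),
             precision = tp / pmax(tp + fp, 1))
}

#' Average precision from a PR curve
#'
#' Area under the precision envelope with all-point interpolation (the
#' precision at each recall is the maximum precision at any recall at least
#' as large); \code{method = "11point"} gives the 11-point average instead.
#'
#' @param curve data.frame from \code{\link{prCurve}}.
#' @param method \code{"all"} (default) or \code{"11point"}.
#' @return numeric AP in [0,1].
#' @export
averagePrecision <- function(curve, method = c("all", "11point")) {
  method <- match.arg(method)
  if (nrow(curve) == 0L) return(0)
  r <- c(0, curve$recall)
  p <- c(0, curve$precision)
  # precision envelope: max precision at any recall >= r
  env <- rev(cummax(rev(p)))
  if (method == "11point")
    return(mean(vapply(seq(0, 1, 0.1), function(t) {
      ok <- curve$recall >= t
      if (!any(ok)) 0 else max(curve$precision[ok])
    }, numeric(1))))
  sum(diff(r) * env[-1])
}

#' Mean average precision over categories
#'
#' @param perCategoryAp named numeric vector or list of per-category AP
#'   values.
#' @return their arithmetic mean.
#' @export
#' @examples
#' meanAp(c(0.71, 0.868, 0.802, 0.827))  # 0.802 to 3 decimals
meanAp <- function(perCategoryAp) {
  v <- unlist(perCategoryAp)
  if (length(v) == 0L) stop("empty AP map")
  mean(v)
}

#' Detection metrics per category and pooled
#'
#' Convenience wrapper: matches per category, reports P/R/F1 per category
#' and pooled ("All"), AP per category and their mean (mAP).
#'
#' @param dets,truths as in \code{\link{matchDetections}}.
#' @param iouThreshold IoU threshold, default 0.5.
#' @return list with \code{table} (data.frame category/P/R/F1/AP) and
#'   \code{map} (mean AP).
#' @export
detectionReport <- function(dets, truths, iouThreshold = 0.5) {
  dets <- .asBoxDf(dets, needConf = TRUE)
  truths <- .asBoxDf(truths)
  cats <- sort(unique(truths$category))
  rows <- lapply(cats, function(cat) {
    dc <- dets[dets$category == cat, , drop = FALSE]
    tc <- truths[truths$category == cat, , drop = FALSE]
    mm <- matchDetections(dc, tc, iouThreshold)
    ap <- if (nrow(tc)) averagePrecision(prCurve(dc, tc, iouThreshold)) else NA
    data.frame(category = cat,
               precision = detPrecision(mm$confusion),
               recall = detRecall(mm$confusion),
               f1 = detF1(mm$confusion), ap = ap)
  })
  mmAll <- matchDetections(dets, truths, iouThreshold)
  tab <- rbind(data.frame(category = "All",
                          precision = detPrecision(mmAll$confusion),
                          recall = detRecall(mmAll$confusion),
                          f1 = detF1(mmAll$confusion),
                          ap = NA),
               do.call(rbind, rows))
  map <- meanAp(tab$ap[-1])
  tab$ap[1] <- map
  list(table = tab, map = map)
}

#' ROC AUC as the normalized Mann-Whitney statistic
#'
#' AUC = P(score of a random positive > score of a random negative), ties
#' counted one half; computed from midranks, so it is invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores numeric vector.
#' @param labels binary vector (0/1 or logical); both values must occur.
#' @return numeric AUC in [0,1].
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both label values must be present")
  r <- rank(scores)          # midranks handle ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired two-sided t test on before/after vectors
#'
#' t on n-1 degrees of freedom from the difference vector before - after,
#' so an improvement (after > before) yields a negative t.  Identical
#' vectors (zero-variance differences) are flagged degenerate.
#'
#' @param before,after equal-length numeric vectors (n >= 2).
#' @return list with \code{t}, \code{p} (two-sided), \code{df},
#'   \code{degenerate}.
#' @export
pairedTTest <- function(before, after) {
  if (length(before) != length(after)) stop("length mismatch")
  if (length(before) < 2L) stop("need at least two pairs")
  d <- before - after
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1L,
                degenerate = TRUE))
  tt <- t.test(before, after, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Per-side fracture diagnosis from detections
#'
#' Turns box output for one image into a binary fracture call per side: for
#' each side, the highest-confidence detection among that side's two
#' categories decides; no detection means a negative (non-fracture) call.
#'
#' @param dets data.frame of detections for one image.
#' @return named logical vector \code{c(R = , L = )}, with the deciding
#'   confidences as attribute \code{"confidence"}.
#' @export
diagnosisFromDetections <- function(dets) {
  dets <- .asBoxDf(dets, needConf = TRUE)
  out <- c(R = FALSE, L = FALSE)
  conf <- c(R = NA_real_, L = NA_real_)
  for (side in c("R", "L")) {
    sel <- dets[.categorySide(dets$category) == side, , drop = FALSE]
    if (nrow(sel)) {
      top <- sel[which.max(sel$confidence), ]
      out[side] <- .categoryIsFracture(top$category)
      conf[side] <- top$confidence
    }
  }
  attr(out, "confidence") <- conf
  out
}
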