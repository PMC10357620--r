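## Detection metrics: IoU, VOC-style greedy matching, precision/recall/F1 at
## a confidence threshold, and average precision from the full PR curve.
## Boxes use the continuous 0-based convention (x_min, y_min, x_max, y_max);
## area = (x_max - x_min) * (y_max - y_min).

boxes_frame <- function(x) {
  need <- c("x_min", "y_min", "x_max", "y_max")
  if (is.numeric(x) && length(x) == 4L) {
    x <- as.data.frame(as.list(stats::setNames(as.numeric(x), need)))
  }
  x <- as.data.frame(x)
  if (!all(need %in% names(x))) stop("boxes need columns x_min, y_min, x_max, y_max")
  if (nrow(x) && any(x$x_max <= x$x_min | x$y_max <= x$y_min))
    stop("degenerate box: require x_max > x_min and y_max > y_min")
  x
}

#' Intersection over union of two boxes
#'
#' @param a,b boxes: numeric `(x_min, y_min, x_max, y_max)` or one-row data
#'   frames with those columns.
#' @return IoU in `[0, 1]`; 0 for disjoint boxes.
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 5, 15, 15))  # 25/175
#' @export
iou <- function(a, b) {
  a <- boxes_frame(a); b <- boxes_frame(b)
  drop(iou_matrix(a, b))
}

## nA x nB IoU matrix
iou_matrix <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B)
  if (nA == 0L || nB == 0L) return(matrix(0, nA, nB))
  ix <- pmax(0, outer(A$x_max, B$x_max, pmin) - outer(A$x_min, B$x_min, pmax))
  iy <- pmax(0, outer(A$y_max, B$y_max, pmin) - outer(A$y_min, B$y_min, pmax))
  inter <- ix * iy
  areaA <- (A$x_max - A$x_min) * (A$y_max - A$y_min)
  areaB <- (B$x_max - B$x_min) * (B$y_max - B$y_min)
  inter / (outer(areaA, areaB, `+`) - inter)
}

#' Greedy matching of detections to ground truth
#'
#' Detections with `score >= score_thr` are processed in descending score
#' order; each is matched to the still-unmatched ground-truth box of highest
#' IoU, provided that IoU reaches `iou_thr` (ties broken by ground-truth
#' index). A matched detection is a true positive, an unmatched detection a
#' false positive, and every unmatched ground truth a false negative.
#'
#' @param dets data frame with box columns and `score`.
#' @param gts data frame of ground-truth boxes.
#' @param iou_thr IoU threshold (default 0.5).
#' @param score_thr confidence threshold (default 0).
#' @return list with counts `TP`, `FP`, `FN`, logical `det_matched` (per kept
#'   detection, in descending-score order), `gt_matched`, and the kept
#'   detections' order.
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5, score_thr = 0) {
  gts <- boxes_frame(gts)
  if (is.null(dets) || nrow(as.data.frame(dets)) == 0L) {
    return(list(TP = 0L, FP = 0L, FN = nrow(gts),
                det_matched = logical(0), gt_matched = logical(nrow(gts))))
  }
  dets <- as.data.frame(dets)
  if (!"score" %in% names(dets)) stop("detections need a score column")
  if (any(!is.finite(dets$score) | dets$score < 0 | dets$score > 1))
    stop("scores must be finite and in [0, 1]")
  dets <- dets[dets$score >= score_thr, , drop = FALSE]
  ord <- order(-dets$score)
  dets <- dets[ord, , drop = FALSE]
  nd <- nrow(dets); ng <- nrow(gts)
  gt_matched <- logical(ng)
  det_matched <- logical(nd)
  if (nd > 0L && ng > 0L) {
    M <- iou_matrix(boxes_frame(dets), gts)
    for (i in seq_len(nd)) {
      cand <- M[i, ]
      cand[gt_matched] <- -1
      j <- which.max(cand)
      if (length(j) && cand[j] >= iou_thr) {
        gt_matched[j] <- TRUE
        det_matched[i] <- TRUE
      }
    }
  }
  list(TP = sum(det_matched), FP = sum(!det_matched), FN = sum(!gt_matched),
       det_matched = det_matched, gt_matched = gt_matched, order = ord)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 P R / (P + R)`; 0 when `P + R == 0`. Accepts either
#' proportions or percentages (values > 1 are divided by 100).
#'
#' @param P,R precision and recall.
#' @return F1 in `[0, 1]`.
#' @examples
#' f1_score(95.92, 83.63)  # 0.8935
#' @export
f1_score <- function(P, R) {
  if (any(P > 1)) P <- P / 100
  if (any(R > 1)) R <- R / 100
  ifelse(P + R > 0, 2 * P * R / (P + R), 0)
}

#' Precision, recall and F1 from a match result
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`; any
#' zero-denominator case yields 0.
#'
#' @param m a [match_detections()] result (or any list with TP, FP, FN).
#' @return list `(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(m) {
  P <- if (m$TP + m$FP > 0) m$TP / (m$TP + m$FP) else 0
  R <- if (m$TP + m$FN > 0) m$TP / (m$TP + m$FN) else 0
  list(precision = P, recall = R, f1 = f1_score(P, R))
}

#' Average precision at a fixed IoU threshold
#'
#' Ranks all detections across the dataset by descending score, applies
#' greedy per-image matching at `iou_thr` while sweeping down the ranking,
#' and integrates the precision envelope over recall. All-point
#' (continuous) interpolation is the default; classic 11-point interpolation
#' is available. With a single class this equals MAP at that threshold.
#'
#' @param dets data frame with `image_id`, box columns and `score`.
#' @param gts data frame with `image_id` and box columns.
#' @param iou_thr IoU threshold (default 0.5).
#' @param interpolation `"all_point"` (default) or `"eleven_point"`.
#' @return list `(ap, pr_curve)`; `pr_curve` is a data frame of
#'   `(recall, precision)` points in rank order. Zero ground truths give
#'   `ap = 0`.
#' @export
average_precision <- function(dets, gts, iou_thr = 0.5,
                              interpolation = c("all_point", "eleven_point")) {
  interpolation <- match.arg(interpolation)
  gts <- as.data.frame(gts)
  ngt <- nrow(gts)
  empty <- list(ap = 0, pr_curve = data.frame(recall = numeric(0),
                                              precision = numeric(0)))
  if (ngt == 0L) return(empty)
  dets <- as.data.frame(dets)
  if (nrow(dets) == 0L) return(empty)
  ord <- order(-dets$score)
  dets <- dets[ord, , drop = FALSE]
  gt_by_img <- split(seq_len(ngt), gts$image_id)
  matched <- logical(ngt)
  tp <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    idx <- gt_by_img[[as.character(dets$image_id[i])]]
    idx <- idx[!matched[idx]]
    if (length(idx)) {
      iv <- drop(iou_matrix(boxes_frame(dets[i, ]), boxes_frame(gts[idx, ])))
      j <- which.max(iv)
      if (iv[j] >= iou_thr) {
        matched[idx[j]] <- TRUE
        tp[i] <- TRUE
      }
    }
  }
  ctp <- cumsum(tp)
  recall <- ctp / ngt
  precision <- ctp / seq_along(ctp)
  penv <- rev(cummax(rev(precision)))
  ap <- if (interpolation == "all_point") {
    sum(diff(c(0, recall)) * penv)
  } else {
    mean(vapply(seq(0, 1, by = 0.1), function(t) {
      ok <- recall >= t
      if (any(ok)) max(precision[ok]) else 0
    }, numeric(1)))
  }
  list(ap = ap, pr_curve = data.frame(recall = recall, precision = precision))
}

#' Full detection metrics report
#'
#' Combines threshold metrics (precision/recall/F1 at `score_thr`, summed
#' over images) with threshold-free average precision at `iou_thr`.
#'
#' @inheritParams average_precision
#' @param score_thr confidence threshold for the single-number P/R/F1
#'   (default 0.5).
#' @return object of class `metrics_report`: list with `precision`, `recall`,
#'   `f1`, `ap50`, `counts` and `pr_curve`.
#' @export
evaluate_detections <- function(dets, gts, iou_thr = 0.5, score_thr = 0.5,
                                interpolation = "all_point") {
  dets <- as.data.frame(dets); gts <- as.data.frame(gts)
  ids <- unique(c(as.character(dets$image_id), as.character(gts$image_id)))
  TP <- FP <- FN <- 0L
  for (id in ids) {
    m <- match_detections(dets[as.character(dets$image_id) == id, , drop = FALSE],
                          gts[as.character(gts$image_id) == id,
                              c("x_min", "y_min", "x_max", "y_max"), drop = FALSE],
                          iou_thr = iou_thr, score_thr = score_thr)
    TP <- TP + m$TP; FP <- FP + m$FP; FN <- FN + m$FN
  }
  prf <- precision_recall_f1(list(TP = TP, FP = FP, FN = FN))
  ap <- average_precision(dets, gts, iou_thr = iou_thr,
                          interpolation = interpolation)
  structure(c(prf, list(ap50 = ap$ap, counts = list(TP = TP, FP = FP, FN = FN),
                        pr_curve = ap$pr_curve)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Detection metrics: P=%.4f R=%.4f F1=%.4f AP@0.5=%.4f (TP=%d FP=%d FN=%d)\n",
              x$precision, x$recall, x$f1, x$ap50,
              x$counts$TP, x$counts$FP, x$counts$FN))
  invisible(x)
}
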