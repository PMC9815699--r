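#' Intersection over union of two boxes
#'
#' @param a,b boxes as `c(x1, y1, x2, y2)`.
#' @return Scalar in `[0, 1]`; degenerate zero-area boxes give 0 by
#'   convention.
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- max(0, a[3] - a[1]) * max(0, a[4] - a[2]) +
           max(0, b[3] - b[1]) * max(0, b[4] - b[2]) - inter
  if (union <= 0) return(0)
  inter / union
}

iou_matrix <- function(dets, truths) {
  ix <- pmax(0, outer(dets$x2, truths$x2, pmin) -
                outer(dets$x1, truths$x1, pmax))
  iy <- pmax(0, outer(dets$y2, truths$y2, pmin) -
                outer(dets$y1, truths$y1, pmax))
  inter <- ix * iy
  area_d <- pmax(0, dets$x2 - dets$x1) * pmax(0, dets$y2 - dets$y1)
  area_t <- pmax(0, truths$x2 - truths$x1) * pmax(0, truths$y2 - truths$y1)
  union <- outer(area_d, area_t, "+") - inter
  m <- ifelse(union > 0, inter / union, 0)
  matrix(m, nrow(dets), nrow(truths))
}

#' Greedy IoU matching of detections against ground truth
#'
#' Detections are processed in descending confidence (ties broken by input
#' order); each is a true positive if its best-IoU not-yet-matched truth box
#' reaches the threshold, otherwise a false positive.  Each truth box is
#' matched at most once; unmatched truths are false negatives.
#'
#' @param dets data.frame with `conf`, `x1`, `y1`, `x2`, `y2` (one image,
#'   one class).
#' @param truths data.frame with `x1`, `y1`, `x2`, `y2`.
#' @param iou_threshold matching threshold.
#' @return List with logical vector `tp` (per detection, in input order),
#'   `fn` count, and the threshold used.
#' @export
match_detections <- function(dets, truths, iou_threshold = 0.5) {
  nd <- nrow(dets)
  nt <- nrow(truths)
  tp <- logical(nd)
  if (nd > 0 && nt > 0) {
    ord <- order(-dets$conf)
    iou <- iou_matrix(dets, truths)
    used <- logical(nt)
    for (i in ord) {
      cand <- which(!used)
      if (length(cand) == 0) break
      j <- cand[which.max(iou[i, cand])]
      if (iou[i, j] >= iou_threshold) {
        tp[i] <- TRUE
        used[j] <- TRUE
      }
    }
  }
  list(tp = tp, fn = nt - sum(tp), iou_threshold = iou_threshold)
}

#' Precision, recall and F1 from match counts
#'
#' Precision = TP / (TP + FP), recall = TP / (TP + FN), and F1 is their
#' harmonic mean, `2 P R / (P + R)`.  Undefined ratios (empty denominators)
#' are reported as 0.
#'
#' @param tp,fp,fn non-negative counts.
#' @return Named vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' F1 score from precision and recall
#' @param precision,recall values in `[0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Average precision for one class
#'
#' Sweeps the precision-recall curve over the confidence ranking of all
#' detections of one class across images and integrates the area under the
#' precision envelope (all-points interpolation, the exact discretization
#' of the continuous integral over recall).
#'
#' @param dets data.frame with `image_id`, `conf`, `x1`, `y1`, `x2`, `y2`
#'   (one class).
#' @param truths data.frame with `image_id`, `x1`, `y1`, `x2`, `y2`.
#' @param iou_threshold matching threshold.
#' @return AP in `[0, 1]`, or `NA` when the class has no ground truth (AP
#'   undefined, reported as missing rather than zero).
#' @export
average_precision <- function(dets, truths, iou_threshold = 0.5) {
  npos <- nrow(truths)
  if (npos == 0) return(NA_real_)
  if (nrow(dets) == 0) return(0)
  tp_all <- logical(nrow(dets))
  for (img in unique(dets$image_id)) {
    di <- which(dets$image_id == img)
    ti <- truths[truths$image_id == img, , drop = FALSE]
    mr <- match_detections(dets[di, , drop = FALSE], ti, iou_threshold)
    tp_all[di] <- mr$tp
  }
  ord <- order(-dets$conf)  # stable: ties keep input order
  tp <- cumsum(tp_all[ord])
  fp <- cumsum(!tp_all[ord])
  recall <- tp / npos
  precision <- tp / (tp + fp)
  # precision envelope from the right, then area under the step curve
  env <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * env)
}

#' Mean average precision over classes
#' @param aps numeric vector of per-class APs; `NA` entries (classes without
#'   ground truth) are excluded from the mean.
#' @export
mean_ap <- function(aps) {
  aps <- aps[!is.na(aps)]
  stopifnot(length(aps) >= 1)
  mean(aps)
}

#' Full detection evaluation
#'
#' Per-class precision/recall/F1 at a reference IoU threshold and
#' confidence cut, per-class AP, mAP at 0.5 and the 10-threshold average
#' mAP@0.5:0.95 (0.05 steps, both ends inclusive).
#'
#' @param dets data.frame with `image_id`, `class_id`, `conf`, `x1`, `y1`,
#'   `x2`, `y2` (pixel corners).
#' @param truths data.frame with `image_id`, `class_id`, `x1`, `y1`, `x2`,
#'   `y2`.
#' @param classes integer class ids to evaluate.
#' @param iou_threshold reference threshold for the P/R/F1 tallies.
#' @param conf_threshold confidence cut for the P/R/F1 tallies (AP uses all
#'   detections).
#' @return A `metrics_report` list: `per_class` data.frame, `map50`,
#'   `map50_95`, and the per-threshold mAP vector.
#' @export
evaluate_detections <- function(dets, truths, classes = c(0L, 1L),
                                iou_threshold = 0.5, conf_threshold = 0.25) {
  thresholds <- seq(0.5, 0.95, by = 0.05)
  per_class <- list()
  ap_by_thr <- matrix(NA_real_, nrow = length(classes),
                      ncol = length(thresholds))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    dc <- dets[dets$class_id == cl, , drop = FALSE]
    tc <- truths[truths$class_id == cl, , drop = FALSE]
    for (ti in seq_along(thresholds)) {
      ap_by_thr[ci, ti] <- average_precision(dc, tc, thresholds[ti])
    }
    dconf <- dc[dc$conf >= conf_threshold, , drop = FALSE]
    tp <- 0L; fp <- 0L; fn <- 0L
    imgs <- union(unique(dconf$image_id), unique(tc$image_id))
    for (img in imgs) {
      mr <- match_detections(dconf[dconf$image_id == img, , drop = FALSE],
                             tc[tc$image_id == img, , drop = FALSE],
                             iou_threshold)
      tp <- tp + sum(mr$tp)
      fp <- fp + sum(!mr$tp)
      fn <- fn + mr$fn
    }
    prf <- precision_recall_f1(tp, fp, fn)
    per_class[[ci]] <- data.frame(
      class_id = cl, tp = tp, fp = fp, fn = fn,
      precision = prf["precision"], recall = prf["recall"], f1 = prf["f1"],
      ap50 = ap_by_thr[ci, 1], row.names = NULL)
  }
  map_by_thr <- apply(ap_by_thr, 2, function(a) {
    a <- a[!is.na(a)]
    if (length(a) == 0) NA_real_ else mean(a)
  })
  structure(list(per_class = do.call(rbind, per_class),
                 map50 = map_by_thr[1],
                 map50_95 = mean(map_by_thr, na.rm = TRUE),
                 map_by_threshold = stats::setNames(map_by_thr,
                                                    sprintf("%.2f",
                                                            thresholds)),
                 iou_threshold = iou_threshold,
                 conf_threshold = conf_threshold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Detection metrics\n")
  df <- x$per_class
  df$precision <- round(df$precision, 3)
  df$recall <- round(df$recall, 3)
  df$f1 <- round(df$f1, 3)
  df$ap50 <- round(df$ap50, 3)
  print(df, row.names = FALSE)
  cat(sprintf("mAP@0.5      %.3f\nmAP@0.5:0.95 %.3f\n",
              x$map50, x$map50_95))
  invisible(x)
}

#' mAP averaged over IoU thresholds 0.5 to 0.95
#' @inheritParams evaluate_detections
#' @export
map_range <- function(dets, truths, classes = c(0L, 1L)) {
  evaluate_detections(dets, truths, classes)$map50_95
}

#' Convert normalized YOLO boxes to pixel-corner boxes
#' @param boxes data.frame with cx, cy, w, h (normalized) and any other
#'   columns, which are preserved.
#' @param width,height image size in pixels.
#' @export
yolo_to_xyxy <- function(boxes, width, height) {
  out <- boxes
  out$x1 <- (boxes$cx - boxes$w / 2) * width
  out$y1 <- (boxes$cy - boxes$h / 2) * height
  out$x2 <- (boxes$cx + boxes$w / 2) * width
  out$y2 <- (boxes$cy + boxes$h / 2) * height
  out$cx <- NULL; out$cy <- NULL; out$w <- NULL; out$h <- NULL
  out
}
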