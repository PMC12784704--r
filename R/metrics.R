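## Detection evaluation: greedy confidence-ordered matching, precision /
## recall, all-point interpolated average precision, mAP50 and mAP50-95.
##
## Matching protocol: per class, predictions sorted by decreasing confidence
## (ties broken by input order); each prediction greedily takes the unmatched
## ground truth of highest IoU provided IoU >= threshold.  Unmatched
## predictions are false positives, unmatched truths false negatives.

check_boxes <- function(b, what) {
  if (nrow(b) == 0L) return(invisible(TRUE))
  bad <- b$x2 <= b$x1 | b$y2 <= b$y1 | !is.finite(b$x1 + b$y1 + b$x2 + b$y2)
  if (any(bad)) stop(sprintf("%s: malformed box (x2<=x1, y2<=y1 or non-finite)", what))
  invisible(TRUE)
}

#' Match predictions to ground truth at one IoU threshold
#'
#' @param preds data.frame with `class_id`, `confidence`, `x1`,`y1`,`x2`,`y2`.
#' @param truths data.frame with `class_id`, `x1`,`y1`,`x2`,`y2`.
#' @param iou_thresh minimum IoU for a valid match.
#' @return list with per-class counts (`TP`, `FP`, `FN`), the overall
#'   `precision` and `recall`, and `matches` (logical per prediction, in
#'   confidence order within class).
#' @export
match_detections <- function(preds, truths, iou_thresh = 0.5) {
  check_boxes(preds, "match_detections: preds")
  check_boxes(truths, "match_detections: truths")
  classes <- sort(union(preds$class_id, truths$class_id))
  tp <- fp <- fn <- stats::setNames(integer(length(classes)), classes)
  for (cl in classes) {
    p <- preds[preds$class_id == cl, , drop = FALSE]
    p <- p[order(-p$confidence), , drop = FALSE]
    t <- truths[truths$class_id == cl, , drop = FALSE]
    used <- logical(nrow(t))
    for (i in seq_len(nrow(p))) {
      best <- 0; bj <- 0L
      for (j in seq_len(nrow(t))) {
        if (used[j]) next
        v <- box_iou(as.numeric(p[i, c("x1", "y1", "x2", "y2")]),
                     as.numeric(t[j, c("x1", "y1", "x2", "y2")]))
        if (v > best) { best <- v; bj <- j }
      }
      if (bj > 0L && best >= iou_thresh) {
        used[bj] <- TRUE
        tp[as.character(cl)] <- tp[as.character(cl)] + 1L
      } else fp[as.character(cl)] <- fp[as.character(cl)] + 1L
    }
    fn[as.character(cl)] <- sum(!used)
  }
  TP <- sum(tp); FP <- sum(fp); FN <- sum(fn)
  list(classes = classes, TP_class = tp, FP_class = fp, FN_class = fn,
       TP = TP, FP = FP, FN = FN,
       precision = if (TP + FP > 0L) TP / (TP + FP) else NA_real_,
       recall = if (TP + FN > 0L) TP / (TP + FN) else NA_real_)
}

#' Average precision from a ranked match vector
#'
#' All-point interpolation: the area under the precision envelope
#' (precision made monotonically non-increasing from the right) as a function
#' of recall.  `interpolation = "101pt"` switches to the 101-point average.
#'
#' @param matched logical vector, one entry per prediction ranked by
#'   decreasing confidence (`TRUE` = matches a ground truth).
#' @param n_truth number of ground-truth boxes.
#' @param interpolation `"all"` (default) or `"101pt"`.
#' @return average precision in `[0, 1]`; `NA` (with a warning) when
#'   `n_truth` is 0.
#' @export
average_precision <- function(matched, n_truth, interpolation = c("all", "101pt")) {
  interpolation <- match.arg(interpolation)
  if (n_truth == 0L) {
    warning("average_precision: no ground truth; AP undefined")
    return(NA_real_)
  }
  if (length(matched) == 0L) return(0)
  tp <- cumsum(matched)
  fp <- cumsum(!matched)
  rec <- tp / n_truth
  prec <- tp / (tp + fp)
  ## precision envelope
  mrec <- c(0, rec, 1)
  mpre <- c(1, prec, 0)
  for (i in (length(mpre) - 1L):1L) mpre[i] <- max(mpre[i], mpre[i + 1L])
  if (interpolation == "101pt") {
    r <- seq(0, 1, length.out = 101L)
    return(mean(vapply(r, function(x) mpre[which(mrec >= x)[1L]], numeric(1L))))
  }
  idx <- which(mrec[-1L] != mrec[-length(mrec)])
  sum((mrec[idx + 1L] - mrec[idx]) * mpre[idx + 1L])
}

ap_for_class <- function(preds, truths, cl, iou_thresh, interpolation = "all") {
  p <- preds[preds$class_id == cl, , drop = FALSE]
  p <- p[order(-p$confidence), , drop = FALSE]
  t <- truths[truths$class_id == cl, , drop = FALSE]
  if (nrow(t) == 0L) return(NA_real_)
  used <- logical(nrow(t))
  matched <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    best <- 0; bj <- 0L
    if (!is.na(p$image[1L])) tt <- which(t$image == p$image[i] & !used) else tt <- which(!used)
    for (j in tt) {
      v <- box_iou(as.numeric(p[i, c("x1", "y1", "x2", "y2")]),
                   as.numeric(t[j, c("x1", "y1", "x2", "y2")]))
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0L && best >= iou_thresh) { used[bj] <- TRUE; matched[i] <- TRUE }
  }
  average_precision(matched, nrow(t), interpolation)
}

#' Detection metrics over a prediction / ground-truth set
#'
#' Computes per-class AP at IoU 0.5, mAP50 (mean over classes with ground
#' truth), and mAP50-95 (averaged over IoU thresholds 0.50 to 0.95 in steps
#' of 0.05), plus precision and recall at IoU 0.5.
#'
#' @param preds data.frame with `class_id`, `confidence`, boxes, and
#'   optionally `image` (scene id) for multi-image evaluation.
#' @param truths data.frame with `class_id`, boxes, optionally `image`.
#' @param n_classes number of classes (AP averaged over classes present in
#'   the ground truth).
#' @param interpolation AP interpolation, `"all"` or `"101pt"`.
#' @return a `metrics_result` list.
#' @export
map_range <- function(preds, truths, n_classes = 4L, interpolation = "all") {
  check_boxes(preds, "map_range: preds")
  check_boxes(truths, "map_range: truths")
  if (is.null(preds$image)) preds$image <- NA_integer_
  if (is.null(truths$image)) truths$image <- NA_integer_
  classes <- 0:(n_classes - 1L)
  present <- classes[classes %in% truths$class_id]
  if (length(present) == 0L) stop("map_range: empty truth set; mAP undefined")
  thr <- seq(0.5, 0.95, by = 0.05)
  ap_mat <- matrix(NA_real_, length(present), length(thr),
                   dimnames = list(present, sprintf("%.2f", thr)))
  for (ci in seq_along(present)) for (ti in seq_along(thr))
    ap_mat[ci, ti] <- ap_for_class(preds, truths, present[ci], thr[ti], interpolation)
  mm <- match_detections(preds, truths, 0.5)
  structure(list(ap50_class = stats::setNames(ap_mat[, 1L], present),
                 mAP50 = mean(ap_mat[, 1L]),
                 mAP50_95 = mean(colMeans(ap_mat)),
                 precision = mm$precision, recall = mm$recall,
                 n_classes = length(present)),
            class = "metrics_result")
}

#' @export
print.metrics_result <- function(x, ...) {
  cat(sprintf("<metrics: P=%.3f R=%.3f mAP50=%.3f mAP50-95=%.3f (%d classes)>\n",
              x$precision, x$recall, x$mAP50, x$mAP50_95, x$n_classes))
  invisible(x)
}

#' Read YOLO-format labels
#'
#' Ground-truth files have one `class cx cy w h` line per box (normalised);
#' prediction files carry six columns, `class conf cx cy w h`.
#'
#' @param path label file (may be empty or missing: zero boxes).
#' @param img_size image side in pixels for conversion to corner format.
#' @return data.frame with `class_id`, boxes in pixels, and `confidence` if
#'   present.
#' @export
read_yolo_txt <- function(path, img_size = 1) {
  if (!file.exists(path) || file.size(path) == 0L)
    return(data.frame(class_id = integer(), x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric()))
  m <- as.matrix(utils::read.table(path))
  off <- if (ncol(m) >= 6L) 1L else 0L      # prediction files carry confidence in col 2
  out <- data.frame(class_id = as.integer(m[, 1L]),
                    x1 = (m[, 2L + off] - m[, 4L + off] / 2) * img_size,
                    y1 = (m[, 3L + off] - m[, 5L + off] / 2) * img_size,
                    x2 = (m[, 2L + off] + m[, 4L + off] / 2) * img_size,
                    y2 = (m[, 3L + off] + m[, 5L + off] / 2) * img_size)
  if (off == 1L) out <- cbind(out[1L], confidence = m[, 2L], out[-1L])
  out
}

#' Write metrics as JSON
#' @param metrics a `metrics_result`.
#' @param path output file.
#' @export
metrics_to_json <- function(metrics, path) {
  jsonlite::write_json(unclass(metrics), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
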