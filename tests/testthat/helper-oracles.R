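`%||%` <- function(a, b) if (is.null(a)) b else a

## Independent reference implementations used as oracles.  These deliberately
## share no code with the package paths they check.

rand_fm <- function(n, c, h, w, seed = 1) {
  set.seed(seed)
  feature_map(array(rnorm(n * c * h * w), dim = c(n, c, h, w)))
}

## direct (quadruple-loop-free but naive) cross-correlation, stride 1
oracle_conv2d <- function(x_nchw, w_kkio, pad = 0, dilation = 1) {
  d <- dim(x_nchw); k <- dim(w_kkio)[1]; cin <- dim(w_kkio)[3]; cout <- dim(w_kkio)[4]
  h <- d[3]; wd <- d[4]
  xp <- array(0, dim = c(d[1], d[2], h + 2 * pad, wd + 2 * pad))
  xp[, , pad + seq_len(h), pad + seq_len(wd)] <- x_nchw
  ke <- dilation * (k - 1) + 1
  ho <- h + 2 * pad - ke + 1; wo <- wd + 2 * pad - ke + 1
  out <- array(0, dim = c(d[1], cout, ho, wo))
  for (b in seq_len(d[1])) for (co in seq_len(cout)) for (i in seq_len(ho)) for (j in seq_len(wo)) {
    acc <- 0
    for (ci in seq_len(cin)) for (ki in seq_len(k)) for (kj in seq_len(k))
      acc <- acc + xp[b, ci, i + (ki - 1) * dilation, j + (kj - 1) * dilation] * w_kkio[ki, kj, ci, co]
    out[b, co, i, j] <- acc
  }
  out
}

## exhaustive-suppression NMS: repeated full scans until a fixpoint
oracle_nms <- function(det, iou_thresh) {
  if (nrow(det) == 0L) return(det)
  det <- det[order(-det$confidence), , drop = FALSE]
  status <- rep("unknown", nrow(det))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(det))) {
      if (status[i] != "unknown") next
      higher <- which(seq_len(nrow(det)) < i & status == "keep" &
                        det$class_id == det$class_id[i])
      sup <- FALSE
      for (j in higher)
        if (box_iou(as.numeric(det[i, c("x1", "y1", "x2", "y2")]),
                    as.numeric(det[j, c("x1", "y1", "x2", "y2")])) > iou_thresh) sup <- TRUE
      unknown_higher <- any(seq_len(nrow(det)) < i & status == "unknown")
      if (sup) { status[i] <- "drop"; changed <- TRUE }
      else if (!unknown_higher) { status[i] <- "keep"; changed <- TRUE }
    }
    if (!changed) break
  }
  det[status == "keep", , drop = FALSE]
}

## naive matcher: per class, confidence-descending, best unmatched IoU
oracle_match <- function(preds, truths, thr) {
  TP <- 0L; FP <- 0L; FN <- 0L
  for (cl in sort(union(preds$class_id, truths$class_id))) {
    p <- preds[preds$class_id == cl, , drop = FALSE]
    p <- p[order(-p$confidence), , drop = FALSE]
    t <- truths[truths$class_id == cl, , drop = FALSE]
    taken <- rep(FALSE, nrow(t))
    for (i in seq_len(nrow(p))) {
      ious <- rep(-1, nrow(t))
      for (j in seq_len(nrow(t))) if (!taken[j])
        ious[j] <- box_iou(as.numeric(p[i, c("x1", "y1", "x2", "y2")]),
                           as.numeric(t[j, c("x1", "y1", "x2", "y2")]))
      j <- if (length(ious)) which.max(ious) else 0L
      if (j > 0L && ious[j] >= thr) { taken[j] <- TRUE; TP <- TP + 1L } else FP <- FP + 1L
    }
    FN <- FN + sum(!taken)
  }
  list(TP = TP, FP = FP, FN = FN)
}

## trapezoid-on-envelope average precision
oracle_ap <- function(matched, n_truth) {
  tp <- cumsum(matched); fp <- cumsum(!matched)
  rec <- c(0, tp / n_truth); prec <- c(1, tp / (tp + fp))
  env <- prec
  for (i in (length(env) - 1):1) env[i] <- max(env[i], env[i + 1])
  a <- 0
  for (i in 2:length(rec)) a <- a + (rec[i] - rec[i - 1]) * env[i]
  a
}

rand_boxes <- function(n, img = 100, classes = 0:3, seed = NULL, conf = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  x1 <- runif(n, 0, img * 0.7); y1 <- runif(n, 0, img * 0.7)
  d <- data.frame(class_id = sample(classes, n, replace = TRUE),
                  x1 = x1, y1 = y1,
                  x2 = x1 + runif(n, img * 0.05, img * 0.3),
                  y2 = y1 + runif(n, img * 0.05, img * 0.3))
  if (conf) d <- cbind(d[1], confidence = runif(n), d[-1])
  d
}

pico_model <- function(seed = 3L) assemble(preset_config("sdb-yolo-pico"), seed = seed)

tiny_dataset <- function(n = 8L, seed = 42L) {
  spec <- scene_spec(image_size = 64L, n_animals = c(1L, 3L),
                     blur_range = c(1L, 1L), seed = seed)
  generate_scenes(spec, n)
}
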