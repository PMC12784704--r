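## Detection metrics against independent oracles.

test_that("perfect predictions give zero errors and unit scores", {
  t <- rand_boxes(5L, seed = 200, conf = FALSE)
  p <- cbind(t[1], confidence = 0.9, t[-1])
  mm <- match_detections(p, t, 0.5)
  expect_identical(mm$FP, 0L)
  expect_identical(mm$FN, 0L)
  expect_equal(mm$precision, 1)
  r <- map_range(p, t, 4L)
  expect_equal(r$mAP50, 1)
  expect_equal(r$mAP50_95, 1)
})

test_that("precision follows the TP / (TP + FP) definition", {
  ## 9 matched + 1 unmatched prediction -> precision 0.9
  t <- rand_boxes(9L, seed = 201, conf = FALSE)
  p <- cbind(t[1], confidence = seq(0.99, 0.91, length.out = 9), t[-1])
  stray <- data.frame(class_id = t$class_id[1], confidence = 0.5,
                      x1 = 90, y1 = 90, x2 = 99, y2 = 99)
  mm <- match_detections(rbind(p, stray), t, 0.5)
  expect_identical(mm$TP, 9L)
  expect_identical(mm$FP, 1L)
  expect_equal(mm$precision, 0.9)
  expect_equal(mm$recall, 1)
})

test_that("all-wrong-class predictions score zero AP", {
  t <- rand_boxes(4L, seed = 202, conf = FALSE); t$class_id <- 0L
  p <- cbind(t[1], confidence = 0.9, t[-1]); p$class_id <- 1L
  r <- map_range(p, t, 4L)
  expect_equal(r$mAP50, 0)
})

test_that("average precision matches the trapezoid-on-envelope oracle", {
  ## single perfect detection
  expect_equal(average_precision(TRUE, 1L), 1)
  ## 5-point hand case
  matched <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  expect_equal(average_precision(matched, 4L), oracle_ap(matched, 4L))
  set.seed(203)
  for (i in 1:20) {
    m <- runif(12) > 0.4
    nt <- sample(6:15, 1)
    expect_equal(average_precision(m, nt), oracle_ap(m, nt), tolerance = 1e-12)
  }
  expect_warning(average_precision(c(TRUE), 0L), "undefined")
})

test_that("jittered boxes pass at IoU .5 but fail at tight thresholds", {
  t <- data.frame(class_id = 0L, x1 = 10, y1 = 10, x2 = 50, y2 = 50)
  ## shift by 8px: IoU = 32*32-ish /(...) ~ 0.52... compute: inter 32x40, union 2*1600-1280
  p <- data.frame(class_id = 0L, confidence = 0.9, x1 = 18, y1 = 10, x2 = 58, y2 = 50)
  iou <- box_iou(c(18, 10, 58, 50), c(10, 10, 50, 50))
  expect_gt(iou, 0.5); expect_lt(iou, 0.95)
  r <- map_range(p, t, 4L)
  expect_equal(r$mAP50, 1)
  expect_lt(r$mAP50_95, 1)
  expect_gte(r$mAP50_95, r$mAP50 * 0.1)
})

test_that("threshold-averaged score never exceeds the IoU-.5 score", {
  set.seed(204)
  for (i in 1:10) {
    t <- rand_boxes(6L, seed = 300 + i, conf = FALSE)
    p <- rand_boxes(8L, seed = 400 + i)
    r <- tryCatch(map_range(p, t, 4L), error = function(e) NULL)
    if (!is.null(r)) expect_lte(r$mAP50_95, r$mAP50 + 1e-12)
  }
})

test_that("N classes with AP (1,1,0,0) average to one half", {
  ts <- list(); ps <- list()
  for (cl in 0:3) {
    t <- rand_boxes(3L, seed = 500 + cl, conf = FALSE); t$class_id <- cl
    if (cl < 2) p <- cbind(t[1], confidence = 0.9, t[-1])
    else { p <- cbind(t[1], confidence = 0.9, t[-1]); p$x1 <- p$x1 + 1000; p$x2 <- p$x2 + 1000 }
    ts[[cl + 1]] <- t; ps[[cl + 1]] <- p
  }
  r <- map_range(do.call(rbind, ps), do.call(rbind, ts), 4L)
  expect_equal(r$mAP50, 0.5)
})

test_that("matcher agrees with the naive oracle over many random scenes", {
  for (i in 1:50) {
    t <- rand_boxes(sample(3:8, 1), seed = 600 + i, conf = FALSE)
    p <- rand_boxes(sample(4:15, 1), seed = 700 + i)
    ours <- match_detections(p, t, 0.5)
    orac <- oracle_match(p, t, 0.5)
    expect_identical(ours$TP, orac$TP)
    expect_identical(ours$FP, orac$FP)
    expect_identical(ours$FN, orac$FN)
  }
})

test_that("counts are invariant to the ordering of equal-confidence ties", {
  t <- rand_boxes(5L, seed = 801, conf = FALSE)
  p <- rand_boxes(6L, seed = 802)
  p$confidence <- 0.7            # all tied
  ref <- match_detections(p, t, 0.5)
  for (i in 1:6) {
    perm <- sample(nrow(p))
    mm <- match_detections(p[perm, ], t, 0.5)
    expect_identical(mm$TP, ref$TP)
    expect_identical(mm$FP, ref$FP)
  }
})

test_that("malformed boxes are rejected", {
  bad <- data.frame(class_id = 0L, confidence = 0.5, x1 = 10, y1 = 10, x2 = 5, y2 = 20)
  expect_error(match_detections(bad, rand_boxes(2, seed = 1, conf = FALSE), 0.5), "malformed")
})
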