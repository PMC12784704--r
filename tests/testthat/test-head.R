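## Distribution-focal decoding, box mapping, head output shapes, NMS.

test_that("side-distribution expectation matches hand values", {
  onehot <- rep(0, 17); onehot[8] <- 1
  expect_equal(dfl_expectation(onehot), 7)
  expect_equal(dfl_expectation(rep(1 / 17, 17)), 8)
  two <- rep(0, 17); two[4] <- 0.5; two[6] <- 0.5
  expect_equal(dfl_expectation(two), 4)
  expect_error(dfl_expectation(c(0.5, 0.2)), "sum to 1")
  expect_error(dfl_expectation(c(1.2, -0.2)), "non-negative")
})

test_that("expectation is bounded and monotone under rightward mass shifts", {
  set.seed(50)
  for (i in 1:20) {
    p <- runif(17); p <- p / sum(p)
    e <- dfl_expectation(p)
    expect_gte(e, 0); expect_lte(e, 16)
    ## move mass from a lower bin to a higher bin
    lo <- which(p > 1e-3)[1]; hi <- min(lo + sample(1:3, 1), 17)
    q <- p; d <- min(p[lo], 0.1); q[lo] <- q[lo] - d; q[hi] <- q[hi] + d
    expect_gte(dfl_expectation(q), e)
  }
})

test_that("distance-to-box mapping and its inverse round-trip exactly", {
  a <- anchor_point(10, 10, 1L)
  expect_equal(as.numeric(dist2bbox(c(2, 3, 4, 5), a)), c(8, 7, 14, 15))
  z <- dist2bbox(c(0, 0, 0, 0), a)
  expect_false(isTRUE(attr(z, "valid") %||% TRUE))
  expect_error(dist2bbox(c(-1, 0, 0, 0), a), "non-negative")
  set.seed(51)
  for (i in 1:25) {
    anc <- anchor_point(runif(1, 2, 30), runif(1, 2, 30), sample(c(8L, 16L, 32L), 1))
    d <- runif(4, 0.1, 2)
    box <- dist2bbox(d, anc)
    expect_equal(bbox2dist(as.numeric(box), anc), d, tolerance = 1e-6)
  }
})

test_that("head output shapes follow resolution and bin count", {
  ## 640 input: 80^2 + 40^2 + 20^2 = 8400 anchor cells
  hw <- list(c(80, 80), c(40, 40), c(20, 20))
  anc <- make_anchors(hw, c(8L, 16L, 32L))
  expect_identical(nrow(anc), 8400L)
  ## regression channels = 4 * bins
  m <- efficient_head(4L, c(32L, 64L, 64L))
  expect_identical(dim(m$children$reg1$params$w$v)[4], 4L * 16L)
  xs <- list(ag(array(rnorm(8 * 8 * 32), dim = c(8, 8, 32, 1))),
             ag(array(rnorm(4 * 4 * 64), dim = c(4, 4, 64, 1))),
             ag(array(rnorm(2 * 2 * 64), dim = c(2, 2, 64, 1))))
  out <- mod_forward(m, xs)
  expect_identical(dim(out[[1]]$reg$v), c(8L, 8L, 64L, 1L))
  expect_identical(dim(out[[1]]$cls$v), c(8L, 8L, 4L, 1L))
  expect_identical(dim(out[[3]]$reg$v), c(2L, 2L, 64L, 1L))
  ## resolution grid: anchors scale quadratically
  for (s in c(320L, 640L)) {
    hw2 <- lapply(c(8L, 16L, 32L), function(st) c(s %/% st, s %/% st))
    expect_identical(nrow(make_anchors(hw2, c(8L, 16L, 32L))),
                     as.integer(sum((s / c(8, 16, 32))^2)))
  }
})

test_that("greedy NMS suppresses duplicates and keeps disjoint boxes", {
  d <- data.frame(class_id = c(0L, 0L), confidence = c(0.9, 0.8),
                  x1 = c(10, 10), y1 = c(10, 10), x2 = c(20, 20), y2 = c(20, 20))
  expect_identical(nrow(nms_greedy(d, 0.45)), 1L)
  d2 <- data.frame(class_id = c(0L, 0L), confidence = c(0.9, 0.8),
                   x1 = c(0, 50), y1 = c(0, 50), x2 = c(10, 60), y2 = c(10, 60))
  expect_identical(nrow(nms_greedy(d2, 0.45)), 2L)
  ## same boxes, different classes: both survive
  d3 <- d; d3$class_id <- c(0L, 1L)
  expect_identical(nrow(nms_greedy(d3, 0.45)), 2L)
  ## empty input is fine
  expect_identical(nrow(nms_greedy(d[0, ], 0.45)), 0L)
})

test_that("greedy NMS equals the exhaustive-suppression oracle on random scenes", {
  for (s in 1:8) {
    det <- rand_boxes(20L, seed = 100 + s)
    ours <- nms_greedy(det, 0.45)
    orac <- oracle_nms(det, 0.45)
    expect_equal(ours[order(ours$confidence), ], orac[order(orac$confidence), ],
                 ignore_attr = TRUE)
  }
})

test_that("postprocess decodes, thresholds and serialises detections", {
  set.seed(55)
  m <- pico_model(seed = 8L)
  x <- array(runif(1 * 3 * 64 * 64), dim = c(1, 3, 64, 64))
  raw <- forward_model(m, x)
  det <- postprocess(raw, attr(raw, "strides"), conf_thresh = 0.05, iou_thresh = 0.45)
  if (nrow(det)) {
    expect_true(all(det$confidence >= 0.05 & det$confidence <= 1))
    expect_true(all(det$x2 > det$x1 & det$y2 > det$y1))
  }
  expect_error(postprocess(raw, attr(raw, "strides"), conf_thresh = 1.5), "thresholds")
  tmp <- tempfile(fileext = ".txt")
  detections_to_txt(det, tmp, 64)
  if (nrow(det)) {
    back <- read_yolo_txt(tmp, 64)
    expect_equal(back$x1, det$x1, tolerance = 1e-3)
  }
})
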