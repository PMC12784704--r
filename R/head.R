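## Detection heads and box decoding.
##
## Both heads are anchor-free: every feature-map cell of the three scales
## predicts 4 side distances as discrete distributions over `bins` bins
## (decoded by expectation, the distribution-focal representation) plus one
## logit per class.

#' Expectation of a discrete box-side distribution
#'
#' The predicted side offset is `sum_i i * p_i` over bins `0..K`, the
#' expectation of the normalised distribution `p`.
#'
#' @param p numeric vector of bin probabilities (length K+1), or a matrix with
#'   one distribution per row.
#' @return the expected offset(s), in `[0, K]`.
#' @examples
#' dfl_expectation(c(0, 0, 0, 0, 0, 0, 0, 1, rep(0, 9)))  # one-hot at 7 -> 7
#' dfl_expectation(rep(1 / 17, 17))                        # uniform 0..16 -> 8
#' @export
dfl_expectation <- function(p) {
  if (is.matrix(p)) {
    if (any(p < -1e-9)) stop("dfl_expectation: probabilities must be non-negative")
    if (any(abs(rowSums(p) - 1) > 1e-6)) stop("dfl_expectation: distributions must sum to 1")
    return(as.numeric(p %*% (seq_len(ncol(p)) - 1)))
  }
  if (any(p < -1e-9)) stop("dfl_expectation: probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("dfl_expectation: distribution must sum to 1")
  sum((seq_along(p) - 1) * p)
}

#' Anchor point on a feature grid
#' @param cx,cy cell-centre coordinates in feature-grid units.
#' @param stride pixels per grid cell.
#' @export
anchor_point <- function(cx, cy, stride) {
  list(cx = cx, cy = cy, stride = stride)
}

#' Decode side distances to a corner-format box
#'
#' `x1 = cx - l`, `y1 = cy - t`, `x2 = cx + r`, `y2 = cy + b`, scaled by the
#' anchor stride to pixel units.  A zero-area box is returned with attribute
#' `valid = FALSE`.
#'
#' @param d numeric length-4 vector `(l, t, r, b)`, all `>= 0`.
#' @param anchor an [anchor_point()].
#' @return numeric `(x1, y1, x2, y2)` in pixels.
#' @export
dist2bbox <- function(d, anchor) {
  if (length(d) != 4L || any(d < 0)) stop("dist2bbox: distances must be 4 non-negative values")
  box <- c(anchor$cx - d[1L], anchor$cy - d[2L], anchor$cx + d[3L], anchor$cy + d[4L]) * anchor$stride
  if ((box[3L] - box[1L]) <= 0 || (box[4L] - box[2L]) <= 0) attr(box, "valid") <- FALSE
  box
}

#' Inverse of [dist2bbox()]: box corners to side distances at an anchor
#' @param box numeric `(x1, y1, x2, y2)` in pixels.
#' @inheritParams dist2bbox
#' @export
bbox2dist <- function(box, anchor) {
  b <- box / anchor$stride
  c(anchor$cx - b[1L], anchor$cy - b[2L], b[3L] - anchor$cx, b[4L] - anchor$cy)
}

## ---- baseline (stock v11) detection head -----------------------------------

detect_v11_head <- function(nc, ch, reg_max = 16L) {
  c2 <- max(16L, ch[1L] %/% 4L, reg_max * 4L)
  c3 <- max(ch[1L], min(nc, 100L))
  children <- list()
  for (i in seq_along(ch)) {
    x <- ch[i]
    children[[paste0("box", i, "_1")]] <- conv_block(x, c2, 3L)
    children[[paste0("box", i, "_2")]] <- conv_block(c2, c2, 3L)
    children[[paste0("box", i, "_3")]] <- conv_block(c2, 4L * reg_max, 1L, norm = "none",
                                                     act = "none", bias = TRUE)
    children[[paste0("cls", i, "_1")]] <- conv_block(x, x, 3L, g = x)
    children[[paste0("cls", i, "_2")]] <- conv_block(x, c3, 1L)
    children[[paste0("cls", i, "_3")]] <- conv_block(c3, c3, 3L, g = c3)
    children[[paste0("cls", i, "_4")]] <- conv_block(c3, c3, 1L)
    children[[paste0("cls", i, "_5")]] <- conv_block(c3, nc, 1L, norm = "none",
                                                     act = "none", bias = TRUE)
  }
  bins <- ag(as.numeric(0:(reg_max - 1L)))
  attr(bins, "fixed") <- TRUE
  new_module("detect_v11", params = list(dfl_bins = bins), children = children,
             nc = nc, ch = ch, reg_max = reg_max, nl = length(ch))
}

#' @export
mod_forward.detect_v11 <- function(m, x, ...) {
  lapply(seq_len(m$nl), function(i) {
    xi <- x[[i]]
    reg <- mod_forward(m$children[[paste0("box", i, "_3")]],
                       mod_forward(m$children[[paste0("box", i, "_2")]],
                                   mod_forward(m$children[[paste0("box", i, "_1")]], xi)))
    cls <- xi
    for (s in 1:5) cls <- mod_forward(m$children[[paste0("cls", i, "_", s)]], cls)
    list(reg = reg, cls = cls)
  })
}

#' @export
mod_profile.detect_v11 <- function(m, shp, ...) {
  entries <- list()
  for (i in seq_len(m$nl)) {
    s <- shp[[i]]
    for (nm in paste0("box", i, "_", 1:3)) {
      pr <- mod_profile(m$children[[nm]], s); entries <- c(entries, pr$entries)
    }
    sc <- s
    for (nm in paste0("cls", i, "_", 1:5)) {
      pr <- mod_profile(m$children[[nm]], sc); entries <- c(entries, pr$entries)
      sc <- pr$out
    }
  }
  entries <- c(entries, list(profile_row("dfl_bins", 1L, m$reg_max, 1L, 1L, 1L,
                                         0L, m$reg_max, m$reg_max, 0L,
                                         note = "fixed bin buffer")))
  list(entries = entries, out = NULL)
}

## ---- EfficientHead ----------------------------------------------------------

## Per-scale grouped 3x3 stem (32 channels per group) with GroupNorm, then
## decoupled 1x1 regression (4 * bins channels) and classification (nc) heads.
efficient_head <- function(nc, ch, reg_max = 16L, group_ch = 32L) {
  children <- list()
  for (i in seq_along(ch)) {
    x <- ch[i]
    if (x %% group_ch != 0L)
      stop(sprintf("efficient_head: %d channels not divisible into %d-channel groups", x, group_ch))
    children[[paste0("stem", i)]] <- conv_block(x, x, 3L, g = x %/% group_ch, norm = "gn")
    children[[paste0("reg", i)]] <- conv_block(x, 4L * reg_max, 1L, norm = "none",
                                               act = "none", bias = TRUE)
    children[[paste0("cls", i)]] <- conv_block(x, nc, 1L, norm = "none",
                                               act = "none", bias = TRUE)
  }
  bins <- ag(as.numeric(0:(reg_max - 1L)))
  attr(bins, "fixed") <- TRUE
  new_module("efficient_head", params = list(dfl_bins = bins), children = children,
             nc = nc, ch = ch, reg_max = reg_max, nl = length(ch))
}

#' @export
mod_forward.efficient_head <- function(m, x, ...) {
  lapply(seq_len(m$nl), function(i) {
    s <- mod_forward(m$children[[paste0("stem", i)]], x[[i]])
    list(reg = mod_forward(m$children[[paste0("reg", i)]], s),
         cls = mod_forward(m$children[[paste0("cls", i)]], s))
  })
}

#' @export
mod_profile.efficient_head <- function(m, shp, ...) {
  entries <- list()
  for (i in seq_len(m$nl)) {
    s <- shp[[i]]
    st <- mod_profile(m$children[[paste0("stem", i)]], s)
    rg <- mod_profile(m$children[[paste0("reg", i)]], st$out)
    cl <- mod_profile(m$children[[paste0("cls", i)]], st$out)
    entries <- c(entries, st$entries, rg$entries, cl$entries)
  }
  entries <- c(entries, list(profile_row("dfl_bins", 1L, m$reg_max, 1L, 1L, 1L,
                                         0L, m$reg_max, m$reg_max, 0L,
                                         note = "fixed bin buffer")))
  list(entries = entries, out = NULL)
}

## ---- decoding and non-maximum suppression ----------------------------------

#' Anchor grid for a set of feature scales
#'
#' @param hw list of `c(h, w)` per scale.
#' @param strides integer vector of strides (pixels per cell).
#' @return data.frame with `cx`, `cy` (grid units, cell centres) and `stride`.
#' @export
make_anchors <- function(hw, strides) {
  out <- lapply(seq_along(hw), function(i) {
    h <- hw[[i]][1L]; w <- hw[[i]][2L]
    data.frame(cx = rep(seq_len(w) - 0.5, each = h),
               cy = rep(seq_len(h) - 0.5, times = w),
               stride = strides[i])
  })
  do.call(rbind, out)
}

#' Intersection-over-union of two corner-format boxes
#' @param a,b numeric `(x1, y1, x2, y2)`.
#' @export
box_iou <- function(a, b) {
  iw <- max(0, min(a[3L], b[3L]) - max(a[1L], b[1L]))
  ih <- max(0, min(a[4L], b[4L]) - max(a[2L], b[2L]))
  inter <- iw * ih
  ua <- (a[3L] - a[1L]) * (a[4L] - a[2L]) + (b[3L] - b[1L]) * (b[4L] - b[2L]) - inter
  if (ua <= 0) 0 else inter / ua
}

#' Class-wise greedy non-maximum suppression
#'
#' Detections are processed in order of decreasing confidence (ties broken by
#' input order); a detection is suppressed if it overlaps an already kept
#' detection of the same class by more than `iou_thresh`.
#'
#' @param det data.frame with `class_id`, `confidence`, `x1`, `y1`, `x2`, `y2`.
#' @param iou_thresh IoU threshold in (0, 1).
#' @return the kept subset, ordered by decreasing confidence.
#' @export
nms_greedy <- function(det, iou_thresh = 0.45) {
  if (nrow(det) == 0L) return(det)
  ord <- order(-det$confidence)
  det <- det[ord, , drop = FALSE]
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (det$class_id[j] != det$class_id[i]) next
      if (box_iou(as.numeric(det[i, c("x1", "y1", "x2", "y2")]),
                  as.numeric(det[j, c("x1", "y1", "x2", "y2")])) > iou_thresh) {
        ok <- FALSE; break
      }
    }
    keep[i] <- ok
  }
  det[keep, , drop = FALSE]
}

#' Decode raw head outputs into detections
#'
#' Applies the logistic to class logits, decodes each side distribution by
#' [dfl_expectation()] and maps distances to pixel boxes with [dist2bbox()],
#' then filters by confidence and runs class-wise greedy NMS.
#'
#' @param raw list of per-scale outputs as returned by the model forward pass
#'   (each element `list(reg=, cls=)` of internal tensors or arrays).
#' @param strides stride per scale.
#' @param conf_thresh,iou_thresh thresholds in (0, 1).
#' @param sample which batch element to decode.
#' @return data.frame of detections (`class_id` 0-based, `confidence`,
#'   `x1`,`y1`,`x2`,`y2` in pixels).
#' @export
postprocess <- function(raw, strides, conf_thresh = 0.25, iou_thresh = 0.45, sample = 1L) {
  if (conf_thresh <= 0 || conf_thresh >= 1 || iou_thresh <= 0 || iou_thresh >= 1)
    stop("postprocess: thresholds must lie in (0, 1)")
  rows <- list()
  for (i in seq_along(raw)) {
    reg <- raw[[i]]$reg; cls <- raw[[i]]$cls
    if (is_ag(reg)) reg <- reg$v
    if (is_ag(cls)) cls <- cls$v
    d <- dim(reg); h <- d[1L]; w <- d[2L]; bins <- d[3L] %/% 4L
    nc <- dim(cls)[3L]
    prob <- 1 / (1 + exp(-cls[, , , sample, drop = FALSE]))
    for (gx in seq_len(w)) for (gy in seq_len(h)) {
      p <- prob[gy, gx, , 1L]
      ci <- which.max(p)
      if (p[ci] < conf_thresh) next
      z <- matrix(reg[gy, gx, , sample], nrow = 4L, byrow = TRUE)  # (4, bins)
      z <- exp(z - apply(z, 1L, max)); z <- z / rowSums(z)
      dd <- as.numeric(z %*% (seq_len(bins) - 1))
      anc <- anchor_point(gx - 0.5, gy - 0.5, strides[i])
      box <- dist2bbox(pmax(dd, 0), anc)
      rows[[length(rows) + 1L]] <- data.frame(class_id = ci - 1L, confidence = p[ci],
                                              x1 = box[1L], y1 = box[2L],
                                              x2 = box[3L], y2 = box[4L])
    }
  }
  det <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class_id = integer(), confidence = numeric(),
               x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric())
  nms_greedy(det, iou_thresh)
}

#' Write detections as normalised YOLO-style text
#'
#' One line per detection: `class confidence cx cy w h`, coordinates
#' normalised by the image size.
#' @param det detections data.frame from [postprocess()].
#' @param path output file.
#' @param img_size image side length in pixels (assumes square input).
#' @export
detections_to_txt <- function(det, path, img_size) {
  lines <- vapply(seq_len(nrow(det)), function(i) {
    cx <- (det$x1[i] + det$x2[i]) / 2 / img_size
    cy <- (det$y1[i] + det$y2[i]) / 2 / img_size
    w <- (det$x2[i] - det$x1[i]) / img_size
    h <- (det$y2[i] - det$y1[i]) / img_size
    sprintf("%d %.6f %.6f %.6f %.6f %.6f", det$class_id[i], det$confidence[i], cx, cy, w, h)
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @describeIn detections_to_txt JSON detection report.
#' @export
detections_to_json <- function(det, path) {
  jsonlite::write_json(det, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
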