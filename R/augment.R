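## Joint image / label augmentation.
##
## Images are (h, w, 3) arrays in [0, 1]; labels are data.frames in
## normalised centre format (class_id, cx, cy, w, h).  Every operation maps
## labels consistently with the pixels and keeps them inside the unit square.

check_labels <- function(labels) {
  if (nrow(labels) == 0L) return(invisible(TRUE))
  with(labels, {
    if (any(w <= 0 | h <= 0)) stop("labels: box width/height must be positive")
    if (any(cx - w / 2 < -1e-9 | cx + w / 2 > 1 + 1e-9 |
            cy - h / 2 < -1e-9 | cy + h / 2 > 1 + 1e-9))
      stop("labels: boxes must lie inside the unit square")
  })
  invisible(TRUE)
}

#' Mirror an image and its labels
#'
#' @param image `(h, w, 3)` array in `[0, 1]`.
#' @param labels normalised-centre label data.frame.
#' @param axis `"horizontal"` (cx -> 1 - cx) or `"vertical"` (cy -> 1 - cy).
#' @return list with `image` and `labels`.
#' @export
aug_flip <- function(image, labels, axis = c("horizontal", "vertical")) {
  axis <- tryCatch(match.arg(axis), error = function(e) stop("aug_flip: invalid axis"))
  check_labels(labels)
  if (axis == "horizontal") {
    image <- image[, rev(seq_len(dim(image)[2L])), , drop = FALSE]
    labels$cx <- 1 - labels$cx
  } else {
    image <- image[rev(seq_len(dim(image)[1L])), , , drop = FALSE]
    labels$cy <- 1 - labels$cy
  }
  list(image = image, labels = labels)
}

## normalised line kernel for motion blur
motion_kernel <- function(length, angle) {
  k <- matrix(0, length, length)
  c0 <- (length + 1) / 2
  t <- seq(-(length - 1) / 2, (length - 1) / 2, length.out = max(length * 4L, 8L))
  ij <- unique(cbind(round(c0 - t * sin(angle)), round(c0 + t * cos(angle))))
  ij <- ij[ij[, 1L] >= 1 & ij[, 1L] <= length & ij[, 2L] >= 1 & ij[, 2L] <= length, , drop = FALSE]
  k[ij] <- 1
  k / sum(k)
}

#' Motion blur
#'
#' Convolves each channel with a normalised line kernel, emulating camera or
#' subject movement.  The border wraps around (toroidal), so with a kernel
#' summing to 1 the mean intensity is preserved exactly.
#'
#' @param image `(h, w, 3)` array.
#' @param length odd kernel side (streak length in pixels); 1 is identity.
#' @param angle streak angle in radians.
#' @export
aug_motion_blur <- function(image, length = 7L, angle = 0) {
  d <- dim(image)
  if (length < 1L) stop("aug_motion_blur: length must be >= 1")
  if (length > min(d[1L], d[2L])) stop("aug_motion_blur: kernel exceeds image side")
  if (length == 1L) return(image)
  k <- motion_kernel(length, angle)
  p <- (length - 1L) %/% 2L
  ## wrap-around pad
  wrap <- function(idx, n) ((idx - 1L) %% n) + 1L
  ri <- wrap(seq_len(d[1L] + 2L * p) - p, d[1L])
  rj <- wrap(seq_len(d[2L] + 2L * p) - p, d[2L])
  xp <- image[ri, rj, , drop = FALSE]
  out <- array(0, dim = d)
  for (ki in seq_len(length)) for (kj in seq_len(length)) {
    if (k[ki, kj] == 0) next
    out <- out + k[ki, kj] * xp[ki + seq_len(d[1L]) - 1L, kj + seq_len(d[2L]) - 1L, , drop = FALSE]
  }
  out
}

#' Temporal illumination ramp
#'
#' Emulates gradual lighting change: a linear per-column gain from
#' `gain_start` (left edge) to `gain_end` (right edge), clipped to `[0, 1]`.
#' For a frame sequence (list of images) the gain instead interpolates over
#' frames, one constant gain per frame.
#'
#' @param image `(h, w, 3)` array, or a list of such frames.
#' @param gain_start,gain_end positive multiplicative gains.
#' @export
aug_illumination_ramp <- function(image, gain_start = 0.6, gain_end = 1.4) {
  if (gain_start <= 0 || gain_end <= 0) stop("aug_illumination_ramp: gains must be positive")
  if (is.list(image)) {
    gains <- seq(gain_start, gain_end, length.out = length(image))
    return(lapply(seq_along(image), function(i) pmin(pmax(image[[i]] * gains[i], 0), 1)))
  }
  d <- dim(image)
  g <- seq(gain_start, gain_end, length.out = d[2L])
  out <- image * rep(g, each = d[1L])
  pmin(pmax(out, 0), 1)
}

#' Bounded colour perturbation
#'
#' Adds an independent uniform offset in `[-amplitude, amplitude]` to each
#' channel (clipped), so channel means shift by at most the amplitude.
#'
#' @param image `(h, w, 3)` array.
#' @param amplitude maximum per-channel shift.
#' @export
aug_color_perturb <- function(image, amplitude = 0.1) {
  off <- stats::runif(dim(image)[3L], -amplitude, amplitude)
  pmin(pmax(image + rep(off, each = prod(dim(image)[1:2])), 0), 1)
}

#' Multi-scale fusion (scale-jittered mosaic compositing)
#'
#' Rescales each source image by a factor drawn from `scale_set` and
#' composites them onto one canvas (2x2 mosaic for 4 sources, side-by-side
#' otherwise); labels are remapped to canvas coordinates, clipped to their
#' visible part, and dropped when less than `min_visible_frac` of the box's
#' own area remains visible (default 1%%, avoiding degenerate slivers).
#'
#' @param images list of `(h, w, 3)` arrays.
#' @param labels list of label data.frames, parallel to `images`.
#' @param target_size canvas side in pixels.
#' @param scale_set numeric vector of candidate scale factors.
#' @param min_visible_frac drop threshold as a fraction of the box's area.
#' @return list with `image` and `labels`.
#' @export
aug_multiscale_fuse <- function(images, labels, target_size = 128L,
                                scale_set = c(0.5, 0.75, 1.0),
                                min_visible_frac = 0.01) {
  if (length(images) < 1L) stop("aug_multiscale_fuse: need at least one source image")
  if (length(scale_set) == 0L) stop("aug_multiscale_fuse: empty scale_set")
  n <- length(images)
  canvas <- array(0, dim = c(target_size, target_size, 3L))
  out_labels <- list()
  if (n == 1L) {
    anchors <- list(c(0, 0)); cell <- target_size
  } else if (n <= 4L) {
    half <- target_size %/% 2L
    anchors <- list(c(0, 0), c(0, half), c(half, 0), c(half, half))[seq_len(n)]
    cell <- half
  } else stop("aug_multiscale_fuse: at most 4 source images")
  for (i in seq_len(n)) {
    sc <- if (length(scale_set) == 1L) scale_set else sample(scale_set, 1L)
    side <- max(8L, as.integer(round(cell * sc)))
    img <- resize_nn(images[[i]], side, side)
    oy <- anchors[[i]][1L]; ox <- anchors[[i]][2L]
    h_fit <- min(side, target_size - oy); w_fit <- min(side, target_size - ox)
    canvas[oy + seq_len(h_fit), ox + seq_len(w_fit), ] <- img[seq_len(h_fit), seq_len(w_fit), ]
    lb <- labels[[i]]
    if (nrow(lb) == 0L) next
    ## source-normalised -> canvas pixels
    x1 <- (lb$cx - lb$w / 2) * side + ox; x2 <- (lb$cx + lb$w / 2) * side + ox
    y1 <- (lb$cy - lb$h / 2) * side + oy; y2 <- (lb$cy + lb$h / 2) * side + oy
    x1c <- pmax(x1, ox); x2c <- pmin(x2, ox + w_fit)
    y1c <- pmax(y1, oy); y2c <- pmin(y2, oy + h_fit)
    vis <- pmax(x2c - x1c, 0) * pmax(y2c - y1c, 0) / ((x2 - x1) * (y2 - y1))
    keep <- vis >= min_visible_frac
    if (!any(keep)) next
    out_labels[[length(out_labels) + 1L]] <- data.frame(
      class_id = lb$class_id[keep],
      cx = ((x1c + x2c) / 2 / target_size)[keep],
      cy = ((y1c + y2c) / 2 / target_size)[keep],
      w = ((x2c - x1c) / target_size)[keep],
      h = ((y2c - y1c) / target_size)[keep])
  }
  lbs <- if (length(out_labels)) do.call(rbind, out_labels) else
    data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
               w = numeric(), h = numeric())
  list(image = canvas, labels = lbs)
}

## nearest-neighbour resize
resize_nn <- function(image, h, w) {
  d <- dim(image)
  ri <- pmin(pmax(round(seq(0.5, d[1L] - 0.5, length.out = h) + 0.5), 1L), d[1L])
  rj <- pmin(pmax(round(seq(0.5, d[2L] - 0.5, length.out = w) + 0.5), 1L), d[2L])
  image[ri, rj, , drop = FALSE]
}

#' Apply a named augmentation pipeline to an image/label pair
#'
#' @param image `(h, w, 3)` array.
#' @param labels label data.frame.
#' @param spec list of steps, each `list(op = <name>, ...params)`; ops:
#'   `flip`, `motion_blur`, `illumination`, `color`.
#' @param seed integer seed (fixed seed, bit-identical output).
#' @export
apply_augspec <- function(image, labels, spec, seed = 0L) {
  local_seed(seed, {
    for (st in spec) {
      res <- switch(st$op,
        flip = aug_flip(image, labels, st$axis),
        motion_blur = list(image = aug_motion_blur(image, st$length, st$angle), labels = labels),
        illumination = list(image = aug_illumination_ramp(image, st$gain_start, st$gain_end),
                            labels = labels),
        color = list(image = aug_color_perturb(image, st$amplitude), labels = labels),
        stop(sprintf("apply_augspec: unknown op '%s'", st$op)))
      image <- res$image; labels <- res$labels
    }
    list(image = image, labels = labels)
  })
}
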