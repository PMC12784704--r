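## Synthetic deer-pen scene generator.
##
## Scenes emulate fixed-camera pen footage at desk scale: a textured
## ground/background, 1-6 animals with posture-coded geometry for the four
## behaviour classes (0 stand, 1 lie, 2 eat, 3 drink), optional partial
## occlusion by fence posts, and illumination / motion-blur variation.  Class
## frequencies default to the published label distribution
## (2369 / 812 / 1600 / 281 labels, i.e. 46.8 / 16.0 / 31.6 / 5.6 %).

#' Scene generator specification
#'
#' @param image_size square image side in pixels.
#' @param n_animals integer range `c(min, max)` of animals per scene.
#' @param class_freq length-4 frequency vector (stand, lie, eat, drink),
#'   summing to 1.
#' @param occlusion_prob probability that an animal is partially occluded.
#' @param illum_range gain range for the illumination ramp.
#' @param blur_range motion-blur streak length range (pixels; 1 = none).
#' @param seed master seed; each scene derives its own substream.
#' @export
scene_spec <- function(image_size = 128L, n_animals = c(1L, 6L),
                       class_freq = c(2369, 812, 1600, 281) / 5062,
                       occlusion_prob = 0.3, illum_range = c(0.7, 1.3),
                       blur_range = c(1L, 5L), seed = 0L) {
  if (abs(sum(class_freq) - 1) > 1e-6) stop("scene_spec: class frequencies must sum to 1")
  if (any(n_animals < 0L)) stop("scene_spec: animal counts must be >= 0")
  structure(list(image_size = as.integer(image_size), n_animals = as.integer(n_animals),
                 class_freq = class_freq, occlusion_prob = occlusion_prob,
                 illum_range = illum_range, blur_range = as.integer(blur_range),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

scene_substream <- function(spec, scene_id)
  (spec$seed + 131071L * (scene_id %% 16384L)) %% .Machine$integer.max

fill_ellipse <- function(img, cy, cx, ry, rx, col) {
  d <- dim(img)
  ys <- max(1L, floor(cy - ry)):min(d[1L], ceiling(cy + ry))
  xs <- max(1L, floor(cx - rx)):min(d[2L], ceiling(cx + rx))
  if (length(ys) == 0L || length(xs) == 0L) return(img)
  m <- outer(((ys - cy) / ry)^2, ((xs - cx) / rx)^2, `+`) <= 1
  for (ch in 1:3) {
    sl <- img[ys, xs, ch]
    sl[m] <- col[ch]
    img[ys, xs, ch] <- sl
  }
  img
}

fill_rect <- function(img, y1, x1, y2, x2, col) {
  d <- dim(img)
  ys <- max(1L, round(y1)):min(d[1L], round(y2))
  xs <- max(1L, round(x1)):min(d[2L], round(x2))
  for (ch in 1:3) img[ys, xs, ch] <- col[ch]
  img
}

textured_background <- function(s) {
  base <- c(0.35, 0.32, 0.24)                      # dirt/straw pen floor
  v1 <- stats::filter(stats::rnorm(s), rep(1 / 8, 8), circular = TRUE)
  v2 <- stats::filter(stats::rnorm(s), rep(1 / 8, 8), circular = TRUE)
  tex <- outer(as.numeric(v1), as.numeric(v2)) * 0.15
  img <- array(0, dim = c(s, s, 3L))
  for (ch in 1:3) img[, , ch] <- pmin(pmax(base[ch] + tex + stats::rnorm(s * s, 0, 0.02), 0), 1)
  img
}

## draw one animal; returns list(image, bbox = c(y1,x1,y2,x2) in pixels)
draw_animal <- function(img, class_id, cy, cx, size) {
  coat <- c(0.45, 0.30, 0.18) + stats::runif(1, -0.06, 0.06)
  dark <- coat * 0.6
  bw <- size; bh <- size * 0.55
  if (class_id == 0L) {            # stand: raised body, legs, neutral head
    body_cy <- cy - size * 0.1
    img <- fill_ellipse(img, body_cy, cx, bh / 2, bw / 2, coat)
    for (lx in c(-0.35, -0.15, 0.15, 0.35))
      img <- fill_rect(img, body_cy, cx + lx * bw - 1, cy + size * 0.35, cx + lx * bw + 1, dark)
    img <- fill_ellipse(img, body_cy - bh * 0.45, cx + bw * 0.45, size * 0.14, size * 0.12, coat)
    bbox <- c(body_cy - bh / 2 - size * 0.14, cx - bw / 2, cy + size * 0.35, cx + bw * 0.57)
  } else if (class_id == 1L) {     # lie: low, wide, no legs
    img <- fill_ellipse(img, cy, cx, bh * 0.35, bw * 0.55, coat)
    img <- fill_ellipse(img, cy - bh * 0.15, cx + bw * 0.45, size * 0.12, size * 0.11, coat)
    bbox <- c(cy - bh * 0.35 - size * 0.1, cx - bw * 0.55, cy + bh * 0.35, cx + bw * 0.56)
  } else if (class_id == 2L) {     # eat: head down at a trough
    img <- fill_rect(img, cy + size * 0.28, cx - bw * 0.65, cy + size * 0.42, cx + bw * 0.2, c(0.5, 0.5, 0.52))
    img <- fill_ellipse(img, cy - size * 0.05, cx, bh / 2, bw / 2, coat)
    img <- fill_rect(img, cy - size * 0.05, cx - bw * 0.5 - 1, cy + size * 0.3, cx - bw * 0.5 + 2, coat)
    img <- fill_ellipse(img, cy + size * 0.3, cx - bw * 0.5, size * 0.1, size * 0.1, coat)
    bbox <- c(cy - size * 0.05 - bh / 2, cx - bw * 0.65, cy + size * 0.42, cx + bw * 0.5)
  } else {                          # drink: head down at a basin
    img <- fill_ellipse(img, cy + size * 0.35, cx - bw * 0.5, size * 0.12, size * 0.22, c(0.2, 0.3, 0.55))
    img <- fill_ellipse(img, cy - size * 0.05, cx, bh / 2, bw / 2, coat)
    img <- fill_rect(img, cy - size * 0.05, cx - bw * 0.45 - 1, cy + size * 0.28, cx - bw * 0.45 + 2, coat)
    img <- fill_ellipse(img, cy + size * 0.28, cx - bw * 0.45, size * 0.1, size * 0.09, coat)
    bbox <- c(cy - size * 0.05 - bh / 2, cx - bw * 0.72, cy + size * 0.42, cx + bw * 0.5)
  }
  list(image = img, bbox = bbox)
}

#' Generate one synthetic pen scene
#'
#' @param spec a [scene_spec()].
#' @param scene_id integer id selecting the per-scene random substream.
#' @return list with `image` (`(h, w, 3)` array in `[0, 1]`) and `labels`
#'   (data.frame `class_id`, `cx`, `cy`, `w`, `h`, normalised).
#' @export
generate_scene <- function(spec, scene_id = 0L) {
  for (attempt in 0:4) {
    res <- local_seed(scene_substream(spec, scene_id) + attempt,
                      try_generate_scene(spec))
    if (!is.null(res)) return(res)
  }
  stop("generate_scene: could not place animals after bounded retries")
}

try_generate_scene <- function(spec) {
  s <- spec$image_size
  img <- textured_background(s)
  n <- if (spec$n_animals[1L] == spec$n_animals[2L]) spec$n_animals[1L] else
    sample(spec$n_animals[1L]:spec$n_animals[2L], 1L)
  placed <- list()
  labels <- list()
  for (i in seq_len(n)) {
    cls <- sample(0:3, 1L, prob = spec$class_freq)
    ok <- FALSE
    for (try in 1:25) {
      size <- stats::runif(1, 0.14, 0.30) * s
      cx <- stats::runif(1, 0.18 * s, 0.82 * s)
      cy <- stats::runif(1, 0.22 * s, 0.78 * s)
      box <- c(cy - size * 0.6, cx - size * 0.75, cy + size * 0.55, cx + size * 0.6)
      clash <- FALSE
      for (p in placed) {
        iw <- max(0, min(box[4L], p[4L]) - max(box[2L], p[2L]))
        ih <- max(0, min(box[3L], p[3L]) - max(box[1L], p[1L]))
        if (iw * ih > 0.3 * (box[4L] - box[2L]) * (box[3L] - box[1L])) { clash <- TRUE; break }
      }
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) return(NULL)                          # regenerate with a new substream
    dr <- draw_animal(img, cls, cy, cx, size)
    img <- dr$image
    bb <- dr$bbox
    if (stats::runif(1) < spec$occlusion_prob) {   # fence post over the animal
      px <- stats::runif(1, bb[2L], bb[4L])
      img <- fill_rect(img, max(1, bb[1L]), px - 1.5, min(s, bb[3L]), px + 1.5, c(0.55, 0.53, 0.5))
    }
    placed[[length(placed) + 1L]] <- bb
    y1 <- max(bb[1L], 1); x1 <- max(bb[2L], 1); y2 <- min(bb[3L], s); x2 <- min(bb[4L], s)
    labels[[length(labels) + 1L]] <- data.frame(
      class_id = cls, cx = (x1 + x2) / 2 / s, cy = (y1 + y2) / 2 / s,
      w = (x2 - x1) / s, h = (y2 - y1) / s)
  }
  gains <- sort(stats::runif(2, spec$illum_range[1L], spec$illum_range[2L]))
  img <- aug_illumination_ramp(img, gains[1L], gains[2L])
  blur <- sample(spec$blur_range[1L]:spec$blur_range[2L], 1L)
  if (blur > 1L) img <- aug_motion_blur(img, blur + (blur + 1L) %% 2L, stats::runif(1, 0, pi))
  lbs <- if (length(labels)) do.call(rbind, labels) else
    data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
               w = numeric(), h = numeric())
  list(image = img, labels = lbs)
}

#' Generate a list of scenes
#' @param spec a [scene_spec()].
#' @param n number of scenes.
#' @export
generate_scenes <- function(spec, n)
  lapply(seq_len(n), function(i) generate_scene(spec, i - 1L))

#' Write scenes to disk as a YOLO-format dataset
#'
#' Writes `images/<stem>.png` and `labels/<stem>.txt`, plus a JSON split
#' manifest with disjoint, exhaustive train/val/test lists.
#'
#' @param scenes list from [generate_scenes()].
#' @param dir output directory (created).
#' @param fractions train/val/test fractions summing to 1.
#' @return the manifest (invisibly also written to `manifest.json`).
#' @export
write_dataset <- function(scenes, dir, fractions = c(0.6, 0.2, 0.2)) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("write_dataset: fractions must sum to 1")
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  stems <- sprintf("scene_%04d", seq_along(scenes) - 1L)
  for (i in seq_along(scenes)) {
    png::writePNG(scenes[[i]]$image, file.path(dir, "images", paste0(stems[i], ".png")))
    lb <- scenes[[i]]$labels
    writeLines(sprintf("%d %.6f %.6f %.6f %.6f", lb$class_id, lb$cx, lb$cy, lb$w, lb$h),
               file.path(dir, "labels", paste0(stems[i], ".txt")))
  }
  n <- length(scenes)
  n_tr <- round(n * fractions[1L]); n_va <- round(n * fractions[2L])
  manifest <- list(train = stems[seq_len(n_tr)],
                   val = stems[n_tr + seq_len(n_va)],
                   test = stems[setdiff(seq_len(n), seq_len(n_tr + n_va))],
                   fractions = fractions)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"), auto_unbox = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#' @param dir dataset directory.
#' @param split one of `"train"`, `"val"`, `"test"`, or `"all"`.
#' @export
read_dataset <- function(dir, split = "all") {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  stems <- if (split == "all") unlist(manifest[c("train", "val", "test")]) else manifest[[split]]
  lapply(stems, function(st) {
    img <- png::readPNG(file.path(dir, "images", paste0(st, ".png")))
    lb <- read_yolo_labels(file.path(dir, "labels", paste0(st, ".txt")))
    list(image = img, labels = lb, stem = st)
  })
}

#' Read normalised-centre YOLO labels
#'
#' One `class cx cy w h` line per box; missing or empty files give zero rows.
#' @param path label file.
#' @return data.frame with `class_id`, `cx`, `cy`, `w`, `h`.
#' @export
read_yolo_labels <- function(path) {
  if (!file.exists(path) || file.size(path) == 0L)
    return(data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric()))
  m <- as.matrix(utils::read.table(path))
  data.frame(class_id = as.integer(m[, 1L]), cx = m[, 2L], cy = m[, 3L],
             w = m[, 4L], h = m[, 5L])
}
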