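## Model assembly from declarative layer graphs.
##
## A model configuration is a list with `nc`, the three scaling fields and a
## `layers` list of layer specs `list(from, repeats, block, args)`.  YAML
## files keep backbone and head sections for readability; they are
## concatenated on load.  Widths written in the YAML are nominal (large-scale)
## widths: the effective width is
## `make_divisible(min(w, max_channels) * width_multiple, 8)`, and repeat
## counts scale by `depth_multiple` — the usual nano-scale convention.

make_divisible <- function(x, divisor = 8L) as.integer(ceiling(x / divisor) * divisor)

#' Read a model configuration
#'
#' @param path YAML file path, or a preset name (see [preset_config()]).
#' @return a `model_config` list.
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  layers <- c(y$backbone, y$head)
  specs <- lapply(seq_along(layers), function(i) {
    l <- layers[[i]]
    list(index = i - 1L, from = unlist(l[[1L]]), repeats = as.integer(l[[2L]]),
         block = as.character(l[[3L]]),
         args = if (length(l) >= 4L) l[[4L]] else list())
  })
  structure(list(nc = as.integer(y$nc),
                 depth_multiple = as.numeric(y$depth_multiple),
                 width_multiple = as.numeric(y$width_multiple),
                 max_channels = as.integer(y$max_channels),
                 input_size = 640L,
                 layers = specs),
            class = "model_config")
}

#' Named preset configurations
#'
#' `"yolov11n-4cls"` is the stock nano baseline at 4 classes;
#' `"sdb-yolo"` the full lightweight variant (FPSC + C3_GDConv + CBAM +
#' EfficientHead); `"sdb-yolo-pico"` a reduced-width variant for the toy
#' training harness.
#'
#' @param name preset name.
#' @return a `model_config`.
#' @export
preset_config <- function(name = c("yolov11n-4cls", "sdb-yolo", "sdb-yolo-pico")) {
  name <- match.arg(name)
  file <- switch(name,
                 "yolov11n-4cls" = "yolov11n.yaml",
                 "sdb-yolo" = "sdb-yolo.yaml",
                 "sdb-yolo-pico" = "sdb-yolo-pico.yaml")
  cfg <- read_model_config(system.file("configs", file, package = "sdbyolo", mustWork = TRUE))
  cfg$preset <- name
  cfg
}

## ---- ablation toggles -------------------------------------------------------

insert_layer_after <- function(cfg, after, block, args) {
  shift <- function(f) ifelse(f >= 0L & f > after, f + 1L, f)
  out <- list()
  for (l in cfg$layers) {
    l$from <- shift(l$from)
    l$index <- if (l$index > after) l$index + 1L else l$index
    out[[length(out) + 1L]] <- l
    if (l$index == after)
      out[[length(out) + 1L]] <- list(index = after + 1L, from = -1L, repeats = 1L,
                                      block = block, args = args)
  }
  cfg$layers <- out
  cfg
}

#' Apply module substitutions to a baseline configuration
#'
#' @param cfg a baseline `model_config`.
#' @param efficient_head replace the stock head with EfficientHead.
#' @param fpsc replace the pooling pyramid (SPPF) with FPSC.
#' @param c3gdconv replace every C3k2 with C3_GDConv (backbone and neck).
#' @param cbam insert CBAM after the P4 neck block; `cbam_hidden` is its
#'   channel-gate width.
#' @param cbam_hidden CBAM gate width (default the calibrated 269).
#' @return the modified `model_config`.
#' @export
apply_ablation <- function(cfg, efficient_head = FALSE, fpsc = FALSE,
                           c3gdconv = FALSE, cbam = FALSE, cbam_hidden = 269L) {
  for (i in seq_along(cfg$layers)) {
    l <- cfg$layers[[i]]
    if (c3gdconv && l$block == "C3k2") cfg$layers[[i]]$block <- "C3_GDConv"
    if (fpsc && l$block == "SPPF") {
      cfg$layers[[i]]$block <- "FPSC"
      cfg$layers[[i]]$args <- l$args[1L]
    }
    if (efficient_head && l$block == "Detect") cfg$layers[[i]]$block <- "EfficientHead"
  }
  if (cbam) {
    ## after the P4 neck block: the layer feeding the final stride-2 conv,
    ## i.e. the second-to-last C3-type block
    c3_like <- which(vapply(cfg$layers, function(l) l$block %in% c("C3k2", "C3_GDConv"),
                            logical(1L)))
    p4 <- cfg$layers[[c3_like[length(c3_like) - 1L]]]$index
    cfg <- insert_layer_after(cfg, p4, "CBAM", list(cbam_hidden, 7L))
  }
  cfg
}

#' The published ablation grid
#'
#' All nine combinations of the four substitutions, in the row order of the
#' published ablation table: baseline; each module alone; the pairwise and
#' three-way combinations; the full model.
#'
#' @return named list of `model_config` objects (length 9).
#' @export
ablation_grid <- function() {
  base <- preset_config("yolov11n-4cls")
  flags <- list(
    baseline = c(FALSE, FALSE, FALSE, FALSE),
    efficient_head = c(TRUE, FALSE, FALSE, FALSE),
    c3gdconv = c(FALSE, FALSE, TRUE, FALSE),
    fpsc = c(FALSE, TRUE, FALSE, FALSE),
    efficient_head_fpsc = c(TRUE, TRUE, FALSE, FALSE),
    fpsc_c3gdconv = c(FALSE, TRUE, TRUE, FALSE),
    efficient_head_c3gdconv = c(TRUE, FALSE, TRUE, FALSE),
    efficient_head_fpsc_c3gdconv = c(TRUE, TRUE, TRUE, FALSE),
    sdb_yolo = c(TRUE, TRUE, TRUE, TRUE))
  lapply(flags, function(f)
    apply_ablation(base, efficient_head = f[1L], fpsc = f[2L],
                   c3gdconv = f[3L], cbam = f[4L]))
}

## ---- block registry ---------------------------------------------------------

## each builder: function(cin, args, cfg) -> list(module, cout)
## `cin` is a vector for multi-input blocks (Concat, heads)
block_registry <- function() {
  list(
    Conv = function(cin, a, cfg, n) {
      cout <- scale_w(a[[1L]], cfg)
      list(module = conv_block(cin, cout, k = a[[2L]], s = a[[3L]]), cout = cout)
    },
    C3k2 = function(cin, a, cfg, n) {
      cout <- scale_w(a[[1L]], cfg)
      c3k <- if (length(a) >= 2L) isTRUE(a[[2L]]) else FALSE
      e <- if (length(a) >= 3L) as.numeric(a[[3L]]) else 0.5
      list(module = c3k2_block(cin, cout, n = n, c3k = c3k, e = e), cout = cout)
    },
    C3_GDConv = function(cin, a, cfg, n) {
      cout <- scale_w(a[[1L]], cfg)
      c3k <- if (length(a) >= 2L) isTRUE(a[[2L]]) else FALSE
      e <- if (length(a) >= 3L) as.numeric(a[[3L]]) else 0.5
      list(module = c3k2_block(cin, cout, n = n, c3k = c3k, e = e, inner = "gd"),
           cout = cout)
    },
    SPPF = function(cin, a, cfg, n) {
      cout <- scale_w(a[[1L]], cfg)
      list(module = sppf_block(cin, cout, k = if (length(a) >= 2L) a[[2L]] else 5L),
           cout = cout)
    },
    FPSC = function(cin, a, cfg, n) {
      cout <- scale_w(a[[1L]], cfg)
      list(module = fpsc_block(cin, cout), cout = cout)
    },
    C2PSA = function(cin, a, cfg, n) {
      cout <- scale_w(a[[1L]], cfg)
      list(module = c2psa_block(cin, cout, n = n), cout = cout)
    },
    CBAM = function(cin, a, cfg, n) {
      hid <- if (length(a) >= 1L) as.integer(a[[1L]]) else max(1L, cin %/% 16L)
      spk <- if (length(a) >= 2L) as.integer(a[[2L]]) else 7L
      list(module = cbam_block(cin, hid, spk), cout = cin)
    },
    Upsample = function(cin, a, cfg, n) list(module = upsample_block(), cout = cin),
    Concat = function(cin, a, cfg, n) list(module = concat_block(), cout = sum(cin)),
    Detect = function(cin, a, cfg, n)
      list(module = detect_v11_head(cfg$nc, cin), cout = NA_integer_),
    EfficientHead = function(cin, a, cfg, n)
      list(module = efficient_head(cfg$nc, cin), cout = NA_integer_)
  )
}

scale_w <- function(w, cfg)
  make_divisible(min(w, cfg$max_channels) * cfg$width_multiple, 8L)

scale_n <- function(n, cfg) max(1L, as.integer(round(n * cfg$depth_multiple)))

## ---- assembly ---------------------------------------------------------------

#' Assemble an executable model from a configuration
#'
#' Builds every layer of the graph with seeded weight initialisation and
#' validates the wiring (block names, from-indices, channel agreement).
#'
#' @param cfg a `model_config` (from [preset_config()], [read_model_config()]
#'   or [apply_ablation()]).
#' @param seed integer seed for weight initialisation (same seed, same
#'   weights).
#' @return an `sdb_model`.
#' @export
assemble <- function(cfg, seed = 0L) {
  stopifnot(inherits(cfg, "model_config"))
  reg <- block_registry()
  local_seed(seed, {
    layers <- list()
    couts <- integer(0L)
    in_ch <- 3L
    for (l in cfg$layers) {
      if (is.null(reg[[l$block]]))
        stop(sprintf("assemble: unknown block '%s' at layer index %d", l$block, l$index))
      from <- ifelse(l$from < 0L, l$index + l$from, l$from)
      if (l$index > 0L && (any(from < 0L) || any(from >= l$index)))
        stop(sprintf("assemble: dangling from-index at layer %d", l$index))
      cin <- if (l$index == 0L) in_ch else couts[from + 1L]
      if (length(cin) > 1L && !(l$block %in% c("Concat", "Detect", "EfficientHead")))
        stop(sprintf("assemble: block '%s' at layer %d takes one input", l$block, l$index))
      built <- reg[[l$block]](if (l$block == "Concat") cin else cin,
                              l$args, cfg, scale_n(l$repeats, cfg))
      layers[[length(layers) + 1L]] <- list(index = l$index, from = from,
                                            block = l$block, module = built$module)
      couts[l$index + 1L] <- built$cout
    }
    structure(list(layers = layers, nc = cfg$nc, cfg = cfg, couts = couts),
              class = "sdb_model")
  })
}

#' @export
print.sdb_model <- function(x, ...) {
  cat(sprintf("<sdb_model: %d layers, nc=%d%s>\n", length(x$layers), x$nc,
              if (!is.null(x$cfg$preset)) paste0(", preset=", x$cfg$preset) else ""))
  invisible(x)
}

#' Run a model forward pass
#'
#' @param model an `sdb_model`.
#' @param x input: a [feature_map()] or `(n, 3, h, w)` array with `h == w`
#'   divisible by 32.
#' @return list of per-scale raw head outputs (`list(reg=, cls=)`), with
#'   attribute `strides`.
#' @export
forward_model <- function(model, x) {
  if (!inherits(x, "feature_map")) x <- feature_map(x)
  xi <- ag(fm_internal(x))
  h_in <- dim(xi$v)[1L]
  outs <- vector("list", length(model$layers))
  result <- NULL
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    inputs <- if (l$index == 0L) xi else {
      got <- lapply(l$from, function(f) outs[[f + 1L]])
      if (length(got) == 1L) got[[1L]] else got
    }
    if (l$block %in% c("Detect", "EfficientHead")) {
      if (!is.list(inputs) || is_ag(inputs)) inputs <- list(inputs)
      result <- mod_forward(l$module, inputs)
      attr(result, "strides") <- vapply(inputs, function(t) h_in / dim(t$v)[1L], numeric(1L))
    } else {
      outs[[l$index + 1L]] <- mod_forward(l$module, inputs)
    }
  }
  if (is.null(result)) stop("forward_model: model has no detection head")
  result
}

#' Detect objects in an image with an assembled model
#'
#' Convenience wrapper: forward pass plus [postprocess()].
#' @inheritParams forward_model
#' @inheritParams postprocess
#' @export
predict_model <- function(model, x, conf_thresh = 0.25, iou_thresh = 0.45) {
  raw <- forward_model(model, x)
  postprocess(raw, attr(raw, "strides"), conf_thresh, iou_thresh)
}

## ---- weight (de)serialisation ----------------------------------------------

#' Save / load model weights
#'
#' Weights are stored as a plain named list of numeric arrays (RDS), keyed by
#' the parameter paths of [mod_params()]; configs themselves are text YAML.
#' @param model an `sdb_model`.
#' @param path file path.
#' @export
save_weights <- function(model, path) {
  ps <- mod_params(model)
  saveRDS(lapply(ps, function(p) p$v), path)
  invisible(path)
}

#' @describeIn save_weights load weights saved by `save_weights` into a
#'   structurally identical model.
#' @export
load_weights <- function(model, path) {
  vs <- readRDS(path)
  ps <- mod_params(model)
  if (!setequal(names(vs), names(ps))) stop("load_weights: parameter names do not match")
  for (nm in names(ps)) {
    if (!identical(dim(ps[[nm]]$v), dim(vs[[nm]])) &&
        !identical(length(ps[[nm]]$v), length(vs[[nm]])))
      stop(sprintf("load_weights: shape mismatch for %s", nm))
    ps[[nm]]$v <- vs[[nm]]
  }
  invisible(model)
}
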