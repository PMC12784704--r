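## Analytic parameter and FLOP accounting.
##
## Parameters follow the deployed-network convention of the published
## tables: batch-norm folds into the preceding convolution (one bias per
## fused conv), group-norm and true biases count as-is, and the fixed
## bin buffer of the distribution-focal decoder is included.  A train-time
## total (norm scale+shift unfolded) is reported alongside.
##
## FLOPs count one multiply-accumulate per conv weight per output position
## (`K^2 * C_in/g * C_out * H * W`), summed over parameter tensors: a kernel
## shared across dilation sweeps, or aggregated from dynamic-convolution
## experts, is counted at its effective single application.  Headline GFLOPs
## are 2 x MACs / 1e9 (multiply and add counted separately), the reporting
## convention of the detector family.  Pooling, activations, upsampling and
## attention matrix products are excluded.

#' Parameter and FLOP count of a single convolution
#'
#' `params = K^2 * C_in/g * C_out` (weights only; norm/bias terms are
#' itemized separately by the model profiler) and
#' `flops = params * H * W` multiply-accumulates.
#'
#' @param K kernel size.
#' @param c_in,c_out channel widths.
#' @param H,W output spatial size (for `flops`).
#' @param groups convolution groups; `groups = c_in` is depthwise.
#' @return list with `params` and `flops`.
#' @examples
#' count_conv(3, 16, 32)$params            # 4608
#' count_conv(3, 16, 32, 20, 20)$flops     # 1843200
#' count_conv(3, 32, 32, groups = 32)$params  # 288
#' @export
count_conv <- function(K, c_in, c_out, H = 1L, W = 1L, groups = 1L) {
  if (any(c(K, c_in, c_out, H, W, groups) < 1L))
    stop("count_conv: all arguments must be >= 1")
  if (c_in %% groups != 0L) stop("count_conv: c_in not divisible by groups")
  p <- K * K * (c_in %/% groups) * c_out
  list(params = p, flops = p * H * W)
}

#' Profile an assembled model
#'
#' Walks the layer graph analytically at the given input resolution and
#' returns a per-parameter-tensor ledger plus totals.  The trainable total is
#' cross-checked against an exhaustive enumeration of the model's parameter
#' arrays; a mismatch is an error.
#'
#' @param model an `sdb_model`.
#' @param input_size square input side, divisible by 32.
#' @return a `profile_report`: list with `entries` (data.frame), `total_params`
#'   (deployed convention, as published), `total_params_train`,
#'   `total_params_conv` (weights-only), `total_macs`, `gflops`, and
#'   `meta` notes.
#' @export
profile_model <- function(model, input_size = 640L) {
  stopifnot(inherits(model, "sdb_model"))
  if (input_size %% 32L != 0L) stop("profile_model: input_size must be divisible by 32")
  shapes <- vector("list", length(model$layers))
  entries <- list()
  lay_ids <- integer(0L)
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    shp_in <- if (l$index == 0L) c(input_size, input_size, 3L) else {
      got <- lapply(l$from, function(f) shapes[[f + 1L]])
      if (length(got) == 1L && !(l$block %in% c("Detect", "EfficientHead"))) got[[1L]] else got
    }
    pr <- mod_profile(l$module, shp_in)
    if (length(pr$entries)) {
      entries <- c(entries, pr$entries)
      lay_ids <- c(lay_ids, rep(l$index, length(pr$entries)))
    }
    shapes[[l$index + 1L]] <- pr$out
  }
  df <- do.call(rbind, lapply(entries, function(e) as.data.frame(e, stringsAsFactors = FALSE)))
  df <- cbind(layer = lay_ids, df)
  total_train <- sum(df$params_train)
  enum <- n_params(model)
  if (total_train != enum)
    stop(sprintf("profile_model: ledger (%d) disagrees with parameter enumeration (%d)",
                 total_train, enum))
  macs <- sum(df$macs)
  structure(list(entries = df,
                 total_params = sum(df$params_deploy),
                 total_params_train = total_train,
                 total_params_conv = sum(df$params_w),
                 total_macs = macs,
                 gflops = 2 * macs / 1e9,
                 input_size = input_size,
                 meta = c("params: deployed convention (batch-norm folded); train-time total alongside",
                          "flops: one MAC per conv weight per output position, x2 for multiply+add",
                          "shared/dynamic kernels counted at one effective application",
                          "pooling, activations, upsampling, attention matmuls excluded")),
            class = "profile_report")
}

#' @export
print.profile_report <- function(x, ...) {
  cat(sprintf("<profile_report @%d: %s params (%s train-time), %.2f GFLOPs>\n",
              x$input_size, format(x$total_params, big.mark = ","),
              format(x$total_params_train, big.mark = ","), x$gflops))
  invisible(x)
}

#' Per-layer difference of two profiles
#'
#' @param a,b `profile_report`s from the same input size.
#' @return list with a per-layer `delta` data.frame (signed, b relative to a)
#'   and total deltas.
#' @export
diff_profiles <- function(a, b) {
  stopifnot(inherits(a, "profile_report"), inherits(b, "profile_report"))
  if (a$input_size != b$input_size) stop("diff_profiles: input sizes differ")
  agg <- function(r) {
    s <- stats::aggregate(cbind(params_deploy, macs) ~ layer, data = r$entries, FUN = sum)
    s
  }
  sa <- agg(a); sb <- agg(b)
  layers <- sort(union(sa$layer, sb$layer))
  da <- sa$params_deploy[match(layers, sa$layer)]; da[is.na(da)] <- 0
  db <- sb$params_deploy[match(layers, sb$layer)]; db[is.na(db)] <- 0
  ma <- sa$macs[match(layers, sa$layer)]; ma[is.na(ma)] <- 0
  mb <- sb$macs[match(layers, sb$layer)]; mb[is.na(mb)] <- 0
  list(delta = data.frame(layer = layers, d_params = db - da, d_macs = mb - ma),
       d_total_params = b$total_params - a$total_params,
       d_total_macs = b$total_macs - a$total_macs,
       d_gflops = b$gflops - a$gflops)
}

#' Write a profile report as JSON
#' @param report a `profile_report`.
#' @param path output file.
#' @export
profile_to_json <- function(report, path) {
  jsonlite::write_json(list(entries = report$entries,
                            total_params = report$total_params,
                            total_params_train = report$total_params_train,
                            total_params_conv = report$total_params_conv,
                            total_macs = report$total_macs,
                            gflops = report$gflops,
                            input_size = report$input_size,
                            meta = report$meta),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
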