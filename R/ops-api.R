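## Public functional interface to the bespoke blocks: configuration objects
## plus one-shot forward functions operating on feature maps.  Each forward
## builds a seeded module (or adopts the weights supplied in the config) and
## runs it; the module constructors themselves are what the model assembler
## uses.

check_channels <- function(x, expected, what) {
  s <- fm_shape(x)
  if (s[2L] != expected)
    stop(sprintf("%s: configuration error, input has %d channels but config expects %d",
                 what, s[2L], expected))
}

run_module <- function(m, x) {
  y <- mod_forward(m, ag(fm_internal(x)))
  fm_wrap(y$v)
}

#' Configuration for the shared-convolution pyramid (FPSC)
#'
#' @param in_channels,out_channels block input/output widths.
#' @param hidden_channels width after the 1x1 reduction; defaults to half the
#'   input width (the same convention as the pooling block it replaces).
#' @param dilation_rates ordered distinct positive dilation rates for the
#'   shared 3x3 kernel.
#' @param gate_logits optional fixed gate logits `g_d` (one per rate).  When
#'   `NULL` (default) gates are input-conditioned: the logit of a branch is
#'   its global mean response, so fusion weights adapt to content and the
#'   block carries no gate parameters.
#' @param seed integer seed for weight initialisation.
#' @export
fpsc_config <- function(in_channels, out_channels,
                        hidden_channels = in_channels %/% 2L,
                        dilation_rates = c(1L, 3L, 5L),
                        gate_logits = NULL, seed = 0L) {
  if (hidden_channels < 1L) stop("fpsc_config: hidden_channels must be >= 1")
  if (any(dilation_rates < 1L)) stop("fpsc_config: dilation rates must be positive")
  if (anyDuplicated(dilation_rates)) stop("fpsc_config: configuration error, dilation rates must be distinct")
  if (!is.null(gate_logits) && length(gate_logits) != length(dilation_rates))
    stop("fpsc_config: number of gates must equal number of rates")
  structure(list(in_channels = in_channels, out_channels = out_channels,
                 hidden_channels = hidden_channels, dilation_rates = dilation_rates,
                 gate_logits = gate_logits, seed = seed), class = "fpsc_config")
}

#' Shared-convolution pyramid forward pass
#'
#' Reduces channels 1x1, applies ONE shared 3x3 kernel at each dilation rate
#' (padding = dilation, spatial size preserved), softmax-gates the branches,
#' concatenates them with the reduced input and fuses 1x1.
#'
#' @param x a [feature_map()].
#' @param cfg an [fpsc_config()].
#' @return a [feature_map()] with `out_channels` channels and the input's
#'   spatial size.
#' @export
fpsc_forward <- function(x, cfg) {
  stopifnot(inherits(cfg, "fpsc_config"))
  check_channels(x, cfg$in_channels, "fpsc_forward")
  m <- local_seed(cfg$seed, fpsc_block(cfg$in_channels, cfg$out_channels,
                                       cfg$hidden_channels, cfg$dilation_rates,
                                       cfg$gate_logits))
  run_module(m, x)
}

#' Configuration for the ghost feature module
#'
#' @param in_channels,out_channels widths.
#' @param ratio integer; the primary convolution produces
#'   `ceiling(out_channels / ratio)` channels, the cheap depthwise op the rest.
#' @param cheap_kernel depthwise kernel size of the cheap op.
#' @param primary_kernel kernel size of the primary convolution.
#' @param seed integer seed.
#' @export
ghost_config <- function(in_channels, out_channels, ratio = 2L,
                         cheap_kernel = 5L, primary_kernel = 1L, seed = 0L) {
  if (ratio < 1L) stop("ghost_config: ratio must be >= 1")
  if (out_channels < ratio) stop("ghost_config: configuration error, out_channels < ratio")
  structure(list(in_channels = in_channels, out_channels = out_channels,
                 ratio = ratio, cheap_kernel = cheap_kernel,
                 primary_kernel = primary_kernel, seed = seed), class = "ghost_config")
}

#' Ghost module forward pass
#' @param x a [feature_map()].
#' @param cfg a [ghost_config()].
#' @export
ghost_forward <- function(x, cfg) {
  stopifnot(inherits(cfg, "ghost_config"))
  check_channels(x, cfg$in_channels, "ghost_forward")
  m <- local_seed(cfg$seed, ghost_block(cfg$in_channels, cfg$out_channels,
                                        cfg$ratio, cfg$primary_kernel, cfg$cheap_kernel))
  run_module(m, x)
}

#' Configuration for dynamic convolution
#'
#' @param in_channels,out_channels widths.
#' @param K number of expert kernels (>= 1).
#' @param kernel_size expert kernel size.
#' @param expert_kernels optional list of K arrays `(k, k, c_in, c_out)`
#'   fixing the expert weights.
#' @param masks `FALSE` (no masks, exactly the plain expert aggregation),
#'   `TRUE` (learnable all-ones-initialised elementwise masks), or a list of K
#'   arrays fixing the masks.
#' @param alpha_override optional fixed attention weights (length K, summing
#'   to 1) bypassing the gate — used to test the aggregation identities.
#' @param bias logical, add an output-channel bias (default off).
#' @param gate_reduce bottleneck divisor of the attention MLP.
#' @param attn_spatial,attn_in,attn_out reserved flags for the additional
#'   attention dimensions of the omni-dimensional formulation; only the
#'   kernel-number dimension is modelled, so these must remain `FALSE`.
#' @param seed integer seed.
#' @export
dynamic_conv_config <- function(in_channels, out_channels = in_channels, K = 2L,
                                kernel_size = 1L, expert_kernels = NULL,
                                masks = FALSE, alpha_override = NULL, bias = FALSE,
                                gate_reduce = 2L, attn_spatial = FALSE,
                                attn_in = FALSE, attn_out = FALSE, seed = 0L) {
  if (K < 1L) stop("dynamic_conv_config: configuration error, K must be >= 1")
  if (isTRUE(attn_spatial) || isTRUE(attn_in) || isTRUE(attn_out))
    stop("dynamic_conv_config: only kernel-number attention is modelled; extra attention dims must stay FALSE")
  if (!is.null(expert_kernels)) {
    if (length(expert_kernels) != K) stop("dynamic_conv_config: need K expert kernels")
    dims <- lapply(expert_kernels, dim)
    if (length(unique(vapply(dims, paste, character(1L), collapse = "x"))) != 1L)
      stop("dynamic_conv_config: expert kernels must all have the same shape")
  }
  if (!is.null(alpha_override)) {
    if (length(alpha_override) != K) stop("dynamic_conv_config: internal error, attention length != K")
    if (abs(sum(alpha_override) - 1) > 1e-6) stop("dynamic_conv_config: alpha must sum to 1")
  }
  structure(list(in_channels = in_channels, out_channels = out_channels, K = K,
                 kernel_size = kernel_size, expert_kernels = expert_kernels,
                 masks = masks, alpha_override = alpha_override, bias = bias,
                 gate_reduce = gate_reduce, seed = seed), class = "dynamic_conv_config")
}

build_dynconv <- function(cfg) {
  m <- local_seed(cfg$seed, dynamic_conv_block(cfg$in_channels, cfg$out_channels,
                                               cfg$kernel_size, cfg$K, cfg$gate_reduce,
                                               masks = !identical(cfg$masks, FALSE)))
  if (!is.null(cfg$expert_kernels))
    for (i in seq_len(cfg$K)) m$params[[paste0("w", i)]]$v <- cfg$expert_kernels[[i]]
  if (is.list(cfg$masks))
    for (i in seq_len(cfg$K)) m$params[[paste0("mask", i)]]$v <- cfg$masks[[i]]
  if (cfg$bias) m$params$b <- ag(numeric(cfg$out_channels), req = TRUE)
  m
}

#' Dynamic convolution forward pass
#'
#' Per-sample attention over K expert kernels; the output equals the
#' convolution with the attention-weighted (and optionally masked) kernel
#' aggregate.  With `K = 1` this is exactly a static convolution; with
#' all-ones masks the masked form collapses to the plain aggregation.
#'
#' @param x a [feature_map()].
#' @param cfg a [dynamic_conv_config()].
#' @return a [feature_map()]; attach attribute `alpha` with the per-sample
#'   attention weights.
#' @export
dynamic_conv_forward <- function(x, cfg) {
  stopifnot(inherits(cfg, "dynamic_conv_config"))
  check_channels(x, cfg$in_channels, "dynamic_conv_forward")
  m <- build_dynconv(cfg)
  xin <- ag(fm_internal(x))
  n <- dim(xin$v)[4L]
  alpha <- if (!is.null(cfg$alpha_override))
    matrix(rep(cfg$alpha_override, n), cfg$K, n)
  else if (cfg$K == 1L) matrix(1, 1L, n)
  else dynconv_alpha(m, xin)$v
  acc <- NULL
  for (i in seq_len(cfg$K)) {
    w <- m$params[[paste0("w", i)]]
    if (!identical(cfg$masks, FALSE)) w <- op_mul(w, m$params[[paste0("mask", i)]])
    z <- op_conv2d(xin, w, NULL, stride = 1L, pad = autopad(cfg$kernel_size))
    z <- op_scale_channels(z, ag(matrix(rep(alpha[i, ], each = cfg$out_channels),
                                        cfg$out_channels, n)))
    acc <- if (is.null(acc)) z else op_add(acc, z)
  }
  if (cfg$bias) acc <- op_add(acc, ag(array(rep(m$params[["b"]]$v,
                                                each = prod(dim(acc$v)[1:2])),
                                            dim = dim(acc$v))))
  out <- fm_wrap(acc$v)
  attr(out, "alpha") <- alpha
  out
}

#' Cross-stage ghost/dynamic block forward pass
#'
#' The C3k2-shaped shell whose inner sub-blocks are ghost modules
#' (`c3k = FALSE`) or ghost-ghost-dynamic stacks (`c3k = TRUE`).
#'
#' @param x a [feature_map()].
#' @param n number of stacked inner sub-blocks (>= 1).
#' @param c3k logical, use the ghost-ghost-dynamic sub-block.
#' @param out_channels output width (default: input width).
#' @param e hidden-width expansion of the shell.
#' @param seed integer seed.
#' @export
c3_gdconv_forward <- function(x, n = 1L, c3k = FALSE, out_channels = NULL,
                              e = 0.5, seed = 0L) {
  if (n < 1L) stop("c3_gdconv_forward: configuration error, n must be >= 1")
  s <- fm_shape(x)
  cout <- if (is.null(out_channels)) s[2L] else out_channels
  m <- local_seed(seed, c3k2_block(s[2L], cout, n = n, c3k = c3k, e = e, inner = "gd"))
  run_module(m, x)
}

#' Configuration for convolutional block attention
#'
#' @param channels input width.
#' @param mlp_reduction channel-gate bottleneck divisor (hidden width =
#'   `channels / mlp_reduction`); mutually exclusive with `mlp_hidden`.
#' @param mlp_hidden explicit gate hidden width.
#' @param spatial_kernel odd spatial-attention kernel size (default 7).
#' @param seed integer seed.
#' @export
cbam_config <- function(channels, mlp_reduction = 16L, mlp_hidden = NULL,
                        spatial_kernel = 7L, seed = 0L) {
  if (is.null(mlp_hidden)) {
    if (channels < mlp_reduction)
      stop("cbam_config: configuration error, channels < mlp_reduction")
    mlp_hidden <- channels %/% mlp_reduction
  }
  if (spatial_kernel %% 2L == 0L) stop("cbam_config: spatial kernel must be odd")
  structure(list(channels = channels, mlp_hidden = mlp_hidden,
                 spatial_kernel = spatial_kernel, seed = seed), class = "cbam_config")
}

#' Convolutional block attention forward pass
#'
#' Channel attention (dual-pool shared MLP, logistic) rescales channels, then
#' spatial attention (channel mean/max maps, k x k conv, logistic) rescales
#' positions; output shape equals input shape.
#'
#' @param x a [feature_map()].
#' @param cfg a [cbam_config()].
#' @export
cbam_forward <- function(x, cfg) {
  stopifnot(inherits(cfg, "cbam_config"))
  check_channels(x, cfg$channels, "cbam_forward")
  m <- local_seed(cfg$seed, cbam_block(cfg$channels, cfg$mlp_hidden, cfg$spatial_kernel))
  run_module(m, x)
}
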