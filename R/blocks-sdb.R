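## The bespoke lightweight blocks: FPSC, GhostModule, DynamicConv,
## Ghost-Ghost-DynamicConv sub-block (the c3k=TRUE inner of C3_GDConv), and
## CBAM.  Internal widths follow the published parameter budgets; see the
## methods vignette for the calibration.

## ---- FPSC: feature pyramid shared convolution ------------------------------

## One 3x3 kernel, shared across all dilation rates; branch features are
## softmax-gated and concatenated with the reduced input (4-way concat, the
## same fusion width as the SPPF block it replaces).  Gates are
## input-conditioned and parameter-free by default: the logit of branch d is
## the global mean response of F_d.  `gate_logits` switches to fixed logits
## (useful for testing the softmax fusion in isolation).
fpsc_block <- function(c1, c2, hidden = c1 %/% 2L, dilations = c(1L, 3L, 5L),
                       gate_logits = NULL) {
  if (hidden < 1L) stop("fpsc: hidden_channels must be >= 1")
  if (any(dilations < 1L) || anyDuplicated(dilations))
    stop("fpsc: dilation rates must be positive and distinct")
  new_module("fpsc",
             params = list(w_shared = ag(kaiming_w(3L, hidden, hidden), req = TRUE)),
             children = list(cv1 = conv_block(c1, hidden, 1L),
                             cv2 = conv_block(hidden * (1L + length(dilations)), c2, 1L)),
             cin = c1, cout = c2, hidden = hidden, dilations = as.integer(dilations),
             gate_logits = gate_logits)
}

#' Softmax gate weights of the shared-convolution pyramid
#'
#' Maps per-branch gate logits `g_d` to fusion weights
#' `beta_d = exp(g_d) / sum_k exp(g_k)`.
#'
#' @param g numeric vector of gate logits, one per dilation rate.
#' @return numeric vector of weights summing to 1.
#' @examples
#' fpsc_gate_weights(c(0, 0, 0))       # uniform 1/3
#' fpsc_gate_weights(c(log(2), 0, 0))  # (0.5, 0.25, 0.25)
#' @export
fpsc_gate_weights <- function(g) {
  e <- exp(g - max(g))
  e / sum(e)
}

#' @export
mod_forward.fpsc <- function(m, x, ...) {
  x1 <- mod_forward(m$children$cv1, x)
  nd <- length(m$dilations)
  branches <- lapply(m$dilations, function(d)
    op_conv2d(x1, m$params$w_shared, NULL, stride = 1L, pad = d, dilation = d))
  n <- dim(as_ag(x1)$v)[4L]
  cc <- m$hidden
  if (is.null(m$gate_logits)) {
    ones_c <- matrix(1 / cc, 1L, cc)
    logits <- op_rbind(lapply(branches, function(b) op_matmul(ag(ones_c), op_gap(b))))
    beta <- op_t(op_softmax_rows(op_t(logits)))       # (nd, n), columns sum to 1
  } else {
    b <- fpsc_gate_weights(m$gate_logits)
    beta <- ag(matrix(rep(b, n), nd, n))
  }
  scaled <- lapply(seq_len(nd), function(i) {
    s <- op_matmul(ag(matrix(1, cc, 1L)), op_rows(beta, i))  # (c, n)
    op_scale_channels(branches[[i]], s)
  })
  mod_forward(m$children$cv2, op_concat_c(c(list(x1), scaled)))
}

#' @export
mod_profile.fpsc <- function(m, shp, ...) {
  e1 <- mod_profile(m$children$cv1, shp)
  s <- e1$out
  pw <- 9L * m$hidden * m$hidden
  shared <- profile_row("fpsc_shared", 3L, m$hidden, m$hidden, s[1L], s[2L],
                        pw, pw, pw, pw * s[1L] * s[2L],
                        note = sprintf("shared kernel, %d dilation sweeps", length(m$dilations)))
  e2 <- mod_profile(m$children$cv2, c(s[1L], s[2L], m$hidden * (1L + length(m$dilations))))
  list(entries = c(e1$entries, list(shared), e2$entries), out = e2$out)
}

## ---- GhostModule ------------------------------------------------------------

## Primary 1x1 convolution produces ceil(cout/ratio) intrinsic channels; a
## cheap depthwise convolution derives the remaining "ghost" channels.
ghost_block <- function(c1, c2, ratio = 2L, primary_k = 1L, cheap_k = 5L) {
  if (ratio < 1L) stop("ghost: ratio must be >= 1")
  if (c2 < ratio) stop("ghost: out_channels must be >= ratio")
  init <- as.integer(ceiling(c2 / ratio))
  cheap <- c2 - init
  ch <- list(primary = conv_block(c1, init, primary_k))
  if (cheap > 0L) ch$cheap <- conv_block(init, init, cheap_k, g = init)
  new_module("ghost", children = ch,
             cin = c1, cout = c2, init = init, n_cheap = cheap, ratio = ratio)
}

#' @export
mod_forward.ghost <- function(m, x, ...) {
  y1 <- mod_forward(m$children$primary, x)
  if (m$n_cheap == 0L) return(y1)
  y2 <- mod_forward(m$children$cheap, y1)
  if (m$n_cheap < m$init) y2 <- op_channels(y2, seq_len(m$n_cheap))
  op_concat_c(list(y1, y2))
}

#' @export
mod_profile.ghost <- function(m, shp, ...) {
  e1 <- mod_profile(m$children$primary, shp)
  if (m$n_cheap == 0L) return(e1)
  e2 <- mod_profile(m$children$cheap, e1$out)
  list(entries = c(e1$entries, e2$entries),
       out = c(e1$out[1L], e1$out[2L], m$cout))
}

## ---- DynamicConv ------------------------------------------------------------

## K expert kernels aggregated by input-conditioned attention.  Convolution is
## linear in the kernel, so y = sum_i alpha_i(x) conv(x, M_i * W_i) equals the
## convolution with the aggregated kernel; the batched implementation runs one
## convolution per expert and mixes outputs per sample.  The gate is
## GAP -> fc(c -> c/gate_reduce) -> ReLU -> fc(-> K) -> softmax, bias-free.
dynamic_conv_block <- function(cin, cout = cin, k = 1L, K = 2L,
                               gate_reduce = 2L, masks = FALSE) {
  if (K < 1L) stop("dynamic_conv: K must be >= 1")
  gh <- max(1L, cin %/% gate_reduce)
  params <- list()
  for (i in seq_len(K)) params[[paste0("w", i)]] <- ag(kaiming_w(k, cin, cout), req = TRUE)
  if (masks) for (i in seq_len(K))
    params[[paste0("mask", i)]] <- ag(array(1, dim = c(k, k, cin, cout)), req = TRUE)
  params$att1 <- ag(matrix(stats::rnorm(gh * cin, 0, sqrt(2 / cin)), gh, cin), req = TRUE)
  params$att2 <- ag(matrix(stats::rnorm(K * gh, 0, sqrt(2 / gh)), K, gh), req = TRUE)
  new_module("dynamic_conv", params = params,
             cin = cin, cout = cout, k = k, K = K, gh = gh, masks = masks,
             p = autopad(k))
}

dynconv_alpha <- function(m, x) {
  z <- op_linear(op_relu(op_linear(op_gap(x), m$params$att1)), m$params$att2)  # (K, n)
  op_t(op_softmax_rows(op_t(z)))                                              # columns sum to 1
}

#' @export
mod_forward.dynamic_conv <- function(m, x, ...) {
  alpha <- if (m$K == 1L) NULL else dynconv_alpha(m, x)
  n <- dim(as_ag(x)$v)[4L]
  terms <- vector("list", m$K)
  for (i in seq_len(m$K)) {
    w <- m$params[[paste0("w", i)]]
    if (m$masks) w <- op_mul(w, m$params[[paste0("mask", i)]])
    z <- op_conv2d(x, w, NULL, stride = 1L, pad = m$p)
    if (m$K > 1L) {
      s <- op_matmul(ag(matrix(1, m$cout, 1L)), op_rows(alpha, i))
      z <- op_scale_channels(z, s)
    }
    terms[[i]] <- z
  }
  y <- terms[[1L]]
  if (m$K > 1L) for (i in 2:m$K) y <- op_add(y, terms[[i]])
  y
}

#' @export
mod_profile.dynamic_conv <- function(m, shp, ...) {
  ho <- shp[1L]; wo <- shp[2L]
  pw1 <- m$k * m$k * m$cin * m$cout
  entries <- list(
    ## K expert tensors count fully; the conv is applied at its effective
    ## single-kernel cost (the experts are aggregated before application)
    profile_row("dynconv_experts", m$k, m$cin, m$cout, ho, wo,
                m$K * pw1, m$K * pw1, m$K * pw1, pw1 * ho * wo,
                note = sprintf("K=%d experts, effective single-kernel FLOPs", m$K)))
  if (m$masks) {
    mp <- m$K * pw1
    entries <- c(entries, list(profile_row("dynconv_masks", m$k, m$cin, m$cout, ho, wo,
                                           0L, mp, mp, 0L, note = "elementwise masks")))
  }
  entries <- c(entries, list(
    profile_row("dynconv_gate", 1L, m$cin, m$gh, 1L, 1L,
                m$gh * m$cin, m$gh * m$cin, m$gh * m$cin, m$gh * m$cin),
    profile_row("dynconv_gate", 1L, m$gh, m$K, 1L, 1L,
                m$K * m$gh, m$K * m$gh, m$K * m$gh, m$K * m$gh)))
  list(entries = entries, out = c(ho, wo, m$cout))
}

## ---- Ghost-Ghost-DynamicConv sub-block (C3k_GDConv) -------------------------

ggd_block <- function(c) {
  new_module("ggd",
             children = list(g1 = ghost_block(c, c),
                             g2 = ghost_block(c, c),
                             dyn = dynamic_conv_block(c, c, k = 1L, K = 2L)))
}

#' @export
mod_forward.ggd <- function(m, x, ...)
  mod_forward(m$children$dyn, mod_forward(m$children$g2, mod_forward(m$children$g1, x)))

#' @export
mod_profile.ggd <- function(m, shp, ...) profile_seq(m$children, shp, c("g1", "g2", "dyn"))

## ---- CBAM -------------------------------------------------------------------

## Channel attention: shared bias-free two-layer MLP applied to both the
## average- and max-pooled descriptors, summed, sigmoid.  Spatial attention:
## channel-wise mean and max maps, concatenated, bias-free k x k convolution
## over edge-replicated padding, sigmoid.  `mlp_hidden` is the gate bottleneck width (default c/16; the
## sdb-yolo preset uses a calibrated width, see the vignette).
cbam_block <- function(c, mlp_hidden = max(1L, c %/% 16L), spatial_k = 7L) {
  if (spatial_k %% 2L == 0L) stop("cbam: spatial kernel must be odd")
  if (c < 1L || mlp_hidden < 1L) stop("cbam: invalid channels")
  new_module("cbam",
             params = list(fc1 = ag(matrix(stats::rnorm(mlp_hidden * c, 0, sqrt(2 / c)),
                                           mlp_hidden, c), req = TRUE),
                           fc2 = ag(matrix(stats::rnorm(c * mlp_hidden, 0, sqrt(2 / mlp_hidden)),
                                           c, mlp_hidden), req = TRUE),
                           wsp = ag(kaiming_w(spatial_k, 2L, 1L), req = TRUE)),
             c = c, hidden = mlp_hidden, spk = spatial_k)
}

#' @export
mod_forward.cbam <- function(m, x, ...) {
  mlp <- function(v) op_linear(op_relu(op_linear(v, m$params$fc1)), m$params$fc2)
  ca <- op_sigmoid(op_add(mlp(op_gap(x)), mlp(op_gmp(x))))
  x1 <- op_scale_channels(x, ca)
  sp <- op_concat_c(list(op_channel_mean(x1), op_channel_max(x1)))
  ## edge-replicated padding keeps the attention map constant on constant input
  sp <- op_pad_replicate(sp, (m$spk - 1L) %/% 2L)
  sa <- op_sigmoid(op_conv2d(sp, m$params$wsp, NULL, stride = 1L, pad = 0L))
  op_scale_spatial(x1, sa)
}

#' @export
mod_profile.cbam <- function(m, shp, ...) {
  list(entries = list(
    profile_row("cbam_mlp", 1L, m$c, m$hidden, 1L, 1L,
                m$hidden * m$c, m$hidden * m$c, m$hidden * m$c, 2L * m$hidden * m$c),
    profile_row("cbam_mlp", 1L, m$hidden, m$c, 1L, 1L,
                m$c * m$hidden, m$c * m$hidden, m$c * m$hidden, 2L * m$c * m$hidden),
    profile_row("cbam_spatial", m$spk, 2L, 1L, shp[1L], shp[2L],
                2L * m$spk^2, 2L * m$spk^2, 2L * m$spk^2, 2L * m$spk^2 * shp[1L] * shp[2L])),
    out = shp)
}
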