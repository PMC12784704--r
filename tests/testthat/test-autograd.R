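## Gradient correctness of the numerical core, checked against central
## finite differences, and the convolution forward against a naive oracle.

num_grad <- function(fn, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

grad_ok <- function(build, shapes, tol = 1e-5) {
  vals <- lapply(shapes, function(s) array(rnorm(prod(s)), dim = s))
  ags <- lapply(vals, function(a) ag(a, req = TRUE))
  with_grad({
    out <- build(ags)
    ag_backward(out)
  })
  for (k in seq_along(vals)) {
    fk <- function(v) {
      vs <- vals; vs[[k]] <- v
      a2 <- lapply(vs, function(a) ag(a, req = TRUE))
      with_grad(build(a2)$v)
    }
    ng <- num_grad(fk, vals[[k]])
    agr <- ags[[k]]$grad
    if (is.null(agr)) agr <- ng * 0
    rel <- max(abs(ng - agr)) / max(1e-8, max(abs(ng)))
    expect_lt(rel, tol)
  }
}

test_that("convolution variants match finite-difference gradients", {
  set.seed(11)
  grad_ok(function(a) op_mean_all(op_conv2d(a[[1]], a[[2]], a[[3]], stride = 1L, pad = 1L)),
          list(c(5, 5, 3, 2), c(3, 3, 3, 4), 4))
  grad_ok(function(a) op_mean_all(op_conv2d(a[[1]], a[[2]], NULL, stride = 2L, pad = 2L,
                                            dilation = 2L, groups = 2L)),
          list(c(8, 8, 4, 2), c(3, 3, 2, 6)))
  grad_ok(function(a) op_mean_all(op_conv2d(a[[1]], a[[2]], a[[3]], stride = 1L,
                                            pad = 2L, groups = 4L)),
          list(c(6, 6, 4, 2), c(5, 5, 1, 4), 4))
})

test_that("normalisation, pooling and attention primitives match finite differences", {
  set.seed(12)
  grad_ok(function(a) op_mean_all(op_mul(op_batchnorm(a[[1]], a[[2]], a[[3]]), a[[1]])),
          list(c(4, 4, 3, 2), 3, 3), tol = 1e-4)
  grad_ok(function(a) op_mean_all(op_mul(op_groupnorm(a[[1]], a[[2]], a[[3]], 2L), a[[1]])),
          list(c(4, 4, 4, 2), 4, 4), tol = 1e-4)
  grad_ok(function(a) op_mean_all(op_maxpool(a[[1]], 5L, 1L, 2L)), list(c(6, 6, 2, 2)))
  grad_ok(function(a) op_mean_all(op_add(op_gap(a[[1]]), op_gmp(a[[1]]))), list(c(4, 4, 3, 2)))
  grad_ok(function(a) op_mean_all(op_scale_channels(a[[1]], a[[2]])),
          list(c(3, 3, 4, 2), c(4, 2)))
  grad_ok(function(a) op_mean_all(op_scale_spatial(a[[1]], a[[2]])),
          list(c(3, 3, 4, 2), c(3, 3, 1, 2)))
  grad_ok(function(a) op_mean_all(op_add(op_channel_mean(a[[1]]), op_channel_max(a[[1]]))),
          list(c(3, 3, 4, 2)))
  grad_ok(function(a) op_mean_all(op_mul(op_softmax_rows(a[[1]]), a[[2]])),
          list(c(4, 5), c(4, 5)))
})

test_that("whole blocks are differentiable end to end", {
  set.seed(13)
  blocks <- list(
    function() fpsc_block(8L, 8L, hidden = 4L),
    function() ghost_block(8L, 8L),
    function() dynamic_conv_block(6L, 6L, K = 2L),
    function() cbam_block(8L, 4L),
    function() c3k2_block(8L, 8L, 1L, TRUE, inner = "gd"))
  for (mk in blocks) {
    m <- mk()
    x0 <- array(rnorm(6 * 6 * 8 * 2), dim = c(6, 6, 8, 2))
    cin <- if (inherits(m, "dynamic_conv")) 6L else 8L
    x0 <- array(rnorm(6 * 6 * cin * 2), dim = c(6, 6, cin, 2))
    ps <- mod_params(m, trainable_only = TRUE)
    with_grad({
      l <- op_mean_all(op_mul(mod_forward(m, ag(x0)), ag(x0 * 0 + 1)))
      l2 <- op_mean_all(op_mul(mod_forward(m, ag(x0)), ag(array(rnorm(length(x0)), dim = dim(x0)))))
      ag_backward(l2)
    })
    ## every trainable tensor receives a gradient
    got <- vapply(ps, function(p) !is.null(p$grad), logical(1))
    expect_true(all(got))
    ## spot-check one parameter against finite differences
    p <- ps[[1]]
    w0 <- p$v
    seedmask <- array(rnorm(length(x0)), dim = dim(x0))
    fn <- function(v) { p$v <- v; r <- mean(mod_forward(m, ag(x0))$v * seedmask); p$v <- w0; r }
    with_grad({
      l3 <- op_mean_all(op_mul(mod_forward(m, ag(x0)), ag(seedmask)))
      ag_backward(l3)
    })
    idx <- seq_len(min(10L, length(w0)))
    ng <- vapply(idx, function(i) {
      e <- 1e-5; vp <- w0; vp[i] <- vp[i] + e; vm <- w0; vm[i] <- vm[i] - e
      (fn(vp) - fn(vm)) / (2 * e)
    }, numeric(1))
    expect_lt(max(abs(ng - p$grad[idx])), 1e-4)
  }
})

test_that("conv2d agrees with a naive direct-convolution oracle", {
  set.seed(14)
  x <- array(rnorm(2 * 3 * 7 * 7), dim = c(2, 3, 7, 7))
  w <- array(rnorm(3 * 3 * 3 * 4), dim = c(3, 3, 3, 4))
  for (cfg in list(c(pad = 1, dil = 1), c(pad = 2, dil = 2))) {
    ours <- op_conv2d(ag(fm_internal(feature_map(x))), ag(w), NULL,
                      stride = 1L, pad = cfg[["pad"]], dilation = cfg[["dil"]])
    ours_nchw <- aperm(ours$v, c(4, 3, 1, 2))
    expect_equal(ours_nchw, oracle_conv2d(x, w, cfg[["pad"]], cfg[["dil"]]), tolerance = 1e-10)
  }
})
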