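## Contracts of the bespoke convolutional blocks.

test_that("pyramid gate softmax reproduces hand-computed fusion weights", {
  expect_equal(fpsc_gate_weights(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(fpsc_gate_weights(c(log(2), 0, 0)), c(0.5, 0.25, 0.25))
  expect_equal(sum(fpsc_gate_weights(rnorm(5))), 1)
})

test_that("shared-kernel pyramid preserves shape and shares one 3x3 kernel", {
  cfg <- fpsc_config(16L, 24L, seed = 5L)
  x <- rand_fm(1, 16, 32, 32, seed = 2)
  y <- fpsc_forward(x, cfg)
  expect_equal(fm_shape(y), c(1L, 24L, 32L, 32L))

  ## trainable weights of all dilated branches together = ONE 3x3 conv
  m <- fpsc_block(64L, 64L, hidden = 64L)
  expect_identical(length(m$params$w_shared$v), 3L * 3L * 64L * 64L)
  expect_identical(length(m$params$w_shared$v), 36864L)
  ## and the number of branch weight tensors does not grow with the rates
  m5 <- fpsc_block(64L, 64L, hidden = 64L, dilations = c(1L, 2L, 3L, 4L, 5L))
  expect_identical(length(m5$params$w_shared$v), 36864L)

  ## dynamic gates: per-sample weights sum to 1
  m2 <- fpsc_block(8L, 8L, hidden = 4L)
  xi <- ag(fm_internal(rand_fm(3, 8, 10, 10, seed = 3)))
  x1 <- mod_forward(m2$children$cv1, xi)
  br <- lapply(m2$dilations, function(d)
    op_conv2d(x1, m2$params$w_shared, NULL, stride = 1L, pad = d, dilation = d))
  ones_c <- matrix(1 / 4, 1L, 4L)
  logits <- op_rbind(lapply(br, function(b) op_matmul(ag(ones_c), op_gap(b))))
  beta <- op_t(op_softmax_rows(op_t(logits)))
  expect_equal(colSums(beta$v), rep(1, 3), tolerance = 1e-6)
})

test_that("pyramid config validation rejects bad inputs", {
  expect_error(fpsc_config(16L, 16L, dilation_rates = c(1L, 3L, 3L)), "distinct")
  expect_error(fpsc_forward(rand_fm(1, 8, 8, 8), fpsc_config(16L, 16L)), "configuration error")
})

test_that("ghost module channel arithmetic and ratio-1 degeneracy", {
  ## out=64, ratio=2 -> 32 primary + 32 cheap
  m <- ghost_block(32L, 64L, ratio = 2L)
  expect_identical(m$init, 32L)
  expect_identical(m$n_cheap, 32L)
  x <- rand_fm(2, 32, 12, 12, seed = 4)
  expect_equal(fm_shape(ghost_forward(x, ghost_config(32L, 64L, seed = 1L))),
               c(2L, 64L, 12L, 12L))

  ## ratio = 1: cheap branch empty, exactly a plain convolution
  cfg1 <- ghost_config(8L, 8L, ratio = 1L, primary_kernel = 1L, seed = 7L)
  m1 <- local_seed(7L, ghost_block(8L, 8L, 1L, 1L, 5L))
  expect_null(m1$children$cheap)
  y1 <- ghost_forward(x8 <- rand_fm(1, 8, 6, 6, seed = 5), cfg1)
  plain <- local_seed(7L, conv_block(8L, 8L, 1L))
  y2 <- mod_forward(plain, ag(fm_internal(x8)))
  expect_equal(fm_array(y1), aperm(y2$v, c(4, 3, 1, 2)), tolerance = 1e-12)

  ## fewer parameters than the standard convolution it replaces (ratio >= 2)
  for (c in c(16L, 32L, 64L)) {
    g <- sum(vapply(mod_params(ghost_block(c, c)), function(p) length(p$v), numeric(1)))
    std <- count_conv(3L, c, c)$params + 2L * c
    expect_lt(g, std)
  }
  expect_error(ghost_config(8L, 1L, ratio = 2L), "configuration error")
})

test_that("dynamic convolution reduces to a static conv at K = 1", {
  set.seed(21)
  w <- array(rnorm(3 * 3 * 4 * 4), dim = c(3, 3, 4, 4))
  x <- rand_fm(2, 4, 9, 9, seed = 6)
  y <- dynamic_conv_forward(x, dynamic_conv_config(4L, 4L, K = 1L, kernel_size = 3L,
                                                   expert_kernels = list(w)))
  expect_equal(attr(y, "alpha"), matrix(1, 1, 2))
  ystatic <- op_conv2d(ag(fm_internal(x)), ag(w), NULL, stride = 1L, pad = 1L)
  expect_identical(fm_array(y), aperm(ystatic$v, c(4, 3, 1, 2)))
})

test_that("dynamic convolution attention is a proper distribution over experts", {
  x <- rand_fm(3, 8, 7, 7, seed = 7)
  y <- dynamic_conv_forward(x, dynamic_conv_config(8L, 8L, K = 4L, seed = 2L))
  a <- attr(y, "alpha")
  expect_equal(dim(a), c(4L, 3L))
  expect_true(all(a >= 0))
  expect_equal(colSums(a), rep(1, 3), tolerance = 1e-6)
})

test_that("uniform attention with all-ones masks equals the mean-kernel convolution", {
  set.seed(22)
  ws <- lapply(1:3, function(i) array(rnorm(3 * 3 * 4 * 4), dim = c(3, 3, 4, 4)))
  x <- rand_fm(1, 4, 8, 8, seed = 8)
  ones <- lapply(ws, function(w) array(1, dim = dim(w)))
  y <- dynamic_conv_forward(x, dynamic_conv_config(4L, 4L, K = 3L, kernel_size = 3L,
                                                   expert_kernels = ws, masks = ones,
                                                   alpha_override = rep(1 / 3, 3)))
  wbar <- (ws[[1]] + ws[[2]] + ws[[3]]) / 3
  ymean <- op_conv2d(ag(fm_internal(x)), ag(wbar), NULL, stride = 1L, pad = 1L)
  expect_equal(fm_array(y), aperm(ymean$v, c(4, 3, 1, 2)), tolerance = 1e-12)

  ## all-zero masks annihilate the output (bias-free block -> zero map)
  zeros <- lapply(ws, function(w) array(0, dim = dim(w)))
  y0 <- dynamic_conv_forward(x, dynamic_conv_config(4L, 4L, K = 3L, kernel_size = 3L,
                                                    expert_kernels = ws, masks = zeros,
                                                    alpha_override = rep(1 / 3, 3)))
  expect_true(all(fm_array(y0) == 0))
  expect_error(dynamic_conv_config(4L, K = 0L), "configuration error")
})

test_that("cross-stage ghost/dynamic block preserves shape and composes its parts", {
  x <- rand_fm(1, 64, 16, 16, seed = 9)
  y <- c3_gdconv_forward(x, n = 1L, c3k = FALSE, seed = 11L)
  expect_equal(fm_shape(y), c(1L, 64L, 16L, 16L))

  ## the c3k sub-block is exactly Ghost -> Ghost -> DynamicConv
  m <- local_seed(3L, ggd_block(16L))
  xi <- ag(fm_internal(rand_fm(1, 16, 10, 10, seed = 10)))
  composed <- mod_forward(m$children$dyn,
                          mod_forward(m$children$g2, mod_forward(m$children$g1, xi)))
  whole <- mod_forward(m, xi)
  expect_identical(whole$v, composed$v)

  ## fewer parameters than the stock block at identical width/depth
  for (cfg in list(c(64L, 64L, 0L), c(128L, 128L, 1L))) {
    gd <- n_params(c3k2_block(cfg[1], cfg[2], 1L, cfg[3] == 1L, inner = "gd"))
    base <- n_params(c3k2_block(cfg[1], cfg[2], 1L, cfg[3] == 1L))
    expect_lt(gd, base)
  }
  expect_error(c3_gdconv_forward(x, n = 0L), "configuration error")
})

test_that("block attention rescales without changing shape, factors in (0,1)", {
  x <- rand_fm(2, 16, 8, 8, seed = 12)
  y <- cbam_forward(x, cbam_config(16L, mlp_reduction = 4L, seed = 3L))
  expect_equal(fm_shape(y), fm_shape(x))

  m <- local_seed(4L, cbam_block(16L, 4L))
  xi <- ag(fm_internal(x))
  mlp <- function(v) op_linear(op_relu(op_linear(v, m$params$fc1)), m$params$fc2)
  ca <- op_sigmoid(op_add(mlp(op_gap(xi)), mlp(op_gmp(xi))))$v
  expect_true(all(ca > 0 & ca < 1))

  ## spatially constant input: channel max-pool equals avg-pool, and the
  ## output is the input scaled by one factor per channel times one constant
  xc <- feature_map(aperm(array(rep(c(0.5, 2.0), each = 16), dim = c(4, 4, 2, 1)), c(4, 3, 1, 2)))
  mc <- local_seed(5L, cbam_block(2L, 1L))
  xi2 <- ag(fm_internal(xc))
  expect_equal(op_gap(xi2)$v, op_gmp(xi2)$v)
  yc <- fm_array(run_module(mc, xc))
  ratio <- yc / fm_array(xc)
  ## one factor per channel (constant over positions), times nothing else
  for (ch in 1:2)
    expect_lt(max(abs(ratio[1, ch, , ] - ratio[1, ch, 1, 1])), 1e-9)
  expect_error(cbam_config(8L, mlp_reduction = 16L), "configuration error")
})

test_that("every block maps shapes as declared over a randomized grid", {
  set.seed(30)
  for (i in 1:6) {
    h <- sample(c(8L, 12L, 16L), 1L)
    cc <- sample(c(8L, 16L), 1L)
    n <- sample(1:2, 1L)
    x <- ag(fm_internal(rand_fm(n, cc, h, h, seed = i)))
    checks <- list(
      list(conv_block(cc, 2L * cc, 3L, s = 2L), c(h %/% 2L, h %/% 2L, 2L * cc)),
      list(c3k2_block(cc, cc, 1L, FALSE), c(h, h, cc)),
      list(c3k2_block(cc, cc, 1L, TRUE, inner = "gd"), c(h, h, cc)),
      list(sppf_block(cc, cc), c(h, h, cc)),
      list(fpsc_block(cc, cc), c(h, h, cc)),
      list(ghost_block(cc, cc), c(h, h, cc)),
      list(cbam_block(cc, cc %/% 4L), c(h, h, cc)))
    for (ch in checks) {
      y <- mod_forward(ch[[1]], x)
      expect_identical(dim(y$v)[1:3], as.integer(ch[[2]]))
    }
  }
})

test_that("fixed seed and fixed weights give bit-identical outputs", {
  x <- rand_fm(1, 8, 10, 10, seed = 40)
  y1 <- fpsc_forward(x, fpsc_config(8L, 8L, seed = 9L))
  y2 <- fpsc_forward(x, fpsc_config(8L, 8L, seed = 9L))
  expect_identical(fm_array(y1), fm_array(y2))
  z1 <- c3_gdconv_forward(x, 1L, TRUE, seed = 9L)
  z2 <- c3_gdconv_forward(x, 1L, TRUE, seed = 9L)
  expect_identical(fm_array(z1), fm_array(z2))
})
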