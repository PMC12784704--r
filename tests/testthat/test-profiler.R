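## Analytic cost accounting.

test_that("single-convolution counts follow the weight-times-area rule", {
  expect_identical(count_conv(3L, 16L, 32L)$params, 4608L)
  expect_identical(count_conv(3L, 16L, 32L, 20L, 20L)$flops, 1843200L)
  expect_identical(count_conv(3L, 32L, 32L, groups = 32L)$params, 288L)
  expect_error(count_conv(0L, 1L, 1L), ">= 1")
  expect_error(count_conv(3L, 10L, 4L, groups = 4L), "divisible")
})

test_that("ledger subtotals equal the exhaustive parameter enumeration per block", {
  blocks <- list(conv_block(16L, 32L, 3L),
                 conv_block(32L, 32L, 3L, g = 2L, norm = "gn"),
                 bottleneck_block(32L, 32L),
                 c3k2_block(64L, 64L, 1L, TRUE),
                 c3k2_block(64L, 64L, 1L, TRUE, inner = "gd"),
                 sppf_block(64L, 64L),
                 c2psa_block(128L, 128L),
                 fpsc_block(64L, 64L),
                 ghost_block(32L, 32L),
                 dynamic_conv_block(32L, 32L, K = 3L, masks = TRUE),
                 cbam_block(128L, 269L))
  for (m in blocks) {
    pr <- mod_profile(m, c(20L, 20L, 64L))  # width component is informational here
    led <- sum(vapply(pr$entries, function(e) e$params_train, numeric(1)))
    expect_equal(led, n_params(m))
    ## Eq-style conv-weight subtotal + itemized extras = everything
    ws <- sum(vapply(pr$entries, function(e) e$params_w, numeric(1)))
    expect_lte(ws, led)
  }
})

test_that("model profile totals are consistent, batch-free and resolution-scaled", {
  m <- assemble(preset_config("sdb-yolo-pico"), seed = 1L)
  p64 <- profile_model(m, 64L)
  expect_identical(p64$total_params_train, n_params(m))
  expect_identical(sum(p64$entries$params_deploy), p64$total_params)
  ## doubling the side multiplies conv FLOPs by 4 (parameters unchanged);
  ## pooled-gate entries (1x1 ledger rows) are resolution-free
  p128 <- profile_model(m, 128L)
  expect_identical(p128$total_params, p64$total_params)
  conv_macs <- function(p) sum(p$entries$macs[p$entries$h > 1])
  expect_equal(conv_macs(p128) / conv_macs(p64), 4, tolerance = 1e-6)
})

test_that("dynamic convolution profiles at linear parameters but flat conv flops in K", {
  p2 <- mod_profile(dynamic_conv_block(32L, 32L, K = 2L), c(20L, 20L, 32L))
  p4 <- mod_profile(dynamic_conv_block(32L, 32L, K = 4L), c(20L, 20L, 32L))
  pw2 <- sum(vapply(p2$entries, function(e) e$params_w, numeric(1)))
  pw4 <- sum(vapply(p4$entries, function(e) e$params_w, numeric(1)))
  ## expert weights grow linearly in K
  e2 <- p2$entries[[1]]; e4 <- p4$entries[[1]]
  expect_equal(e4$params_w, 2 * e2$params_w)
  ## conv flops do not grow; only the gate head differs
  expect_equal(e4$macs, e2$macs)
  gate2 <- sum(vapply(p2$entries[-1], function(e) e$macs, numeric(1)))
  gate4 <- sum(vapply(p4$entries[-1], function(e) e$macs, numeric(1)))
  expect_gt(gate4, gate2)
})

test_that("profile differences are per-layer, signed, and sum to the total delta", {
  a <- profile_model(assemble(preset_config("yolov11n-4cls"), seed = 1L), 640L)
  d0 <- diff_profiles(a, a)
  expect_true(all(d0$delta$d_params == 0))
  expect_equal(d0$d_total_params, 0)
  b <- profile_model(assemble(preset_config("sdb-yolo"), seed = 1L), 640L)
  d <- diff_profiles(a, b)
  expect_equal(sum(d$delta$d_params), d$d_total_params)
  ## the published lightweighting: about 4.09e5 parameters removed
  expect_equal(-d$d_total_params, 408542)
  expect_error(diff_profiles(a, profile_model(assemble(preset_config("sdb-yolo"), seed = 1L), 320L)),
               "input sizes")
})

test_that("json round trip preserves the headline totals", {
  m <- assemble(preset_config("sdb-yolo-pico"), seed = 1L)
  rep <- profile_model(m, 64L)
  f <- tempfile(fileext = ".json")
  profile_to_json(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$total_params, rep$total_params)
  expect_equal(back$gflops, rep$gflops, tolerance = 1e-9)
})
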