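## Joint image/label augmentation.

demo_img <- function(seed = 1) {
  set.seed(seed)
  array(runif(32 * 32 * 3), dim = c(32, 32, 3))
}
demo_labels <- function() data.frame(class_id = c(0L, 2L), cx = c(0.3, 0.5),
                                     cy = c(0.4, 0.5), w = c(0.2, 0.3), h = c(0.2, 0.4))

test_that("flips are involutions and map labels as mirrors", {
  img <- demo_img(); lb <- demo_labels()
  h1 <- aug_flip(img, lb, "horizontal")
  expect_equal(h1$labels$cx, c(0.7, 0.5))
  expect_equal(h1$labels$cy, lb$cy)
  expect_equal(h1$labels$w, lb$w)
  back <- aug_flip(h1$image, h1$labels, "horizontal")
  expect_identical(back$image, img)
  expect_equal(back$labels, lb)
  v1 <- aug_flip(img, lb, "vertical")
  expect_equal(v1$labels$cy, c(0.6, 0.5))
  ## centred box is a fixed point
  expect_equal(h1$labels$cx[2], 0.5)
  expect_error(aug_flip(img, lb, "diagonal"), "invalid axis")
})

test_that("motion blur preserves mean intensity and fixes constants", {
  img <- demo_img(2)
  expect_identical(aug_motion_blur(img, 1L), img)
  for (ang in c(0, 0.7, pi / 2)) {
    b <- aug_motion_blur(img, 7L, ang)
    expect_equal(mean(b), mean(img), tolerance = 1e-6)
  }
  const <- array(0.4, dim = c(16, 16, 3))
  expect_equal(aug_motion_blur(const, 5L, 0.3), const, tolerance = 1e-12)
  expect_error(aug_motion_blur(img, 99L), "exceeds")
})

test_that("illumination ramp scales as configured and orders column means", {
  img <- demo_img(3)
  expect_identical(aug_illumination_ramp(img, 1, 1), img)
  half <- aug_illumination_ramp(array(0.5, dim = c(8, 8, 3)), 0.5, 0.5)
  expect_equal(half, array(0.25, dim = c(8, 8, 3)))
  up <- aug_illumination_ramp(array(0.5, dim = c(8, 16, 3)), 0.6, 1.4)
  cm <- apply(up, 2, mean)
  expect_true(all(diff(cm) >= -1e-12))
  expect_error(aug_illumination_ramp(img, 0, 1), "positive")
  ## frame-sequence mode: one gain per frame
  frames <- aug_illumination_ramp(list(img, img), 0.5, 1.0)
  expect_equal(mean(frames[[1]]) * 2, mean(img) * 1, tolerance = 1e-6)
})

test_that("colour perturbation shifts channel means by at most the amplitude", {
  img <- demo_img(4)
  set.seed(9)
  out <- aug_color_perturb(img, amplitude = 0.05)
  for (ch in 1:3)
    expect_lte(abs(mean(out[, , ch]) - mean(img[, , ch])), 0.05 + 1e-9)
})

test_that("mosaic compositing remaps, clips and drops labels correctly", {
  img <- demo_img(5); lb <- demo_labels()
  ## single source at scale 1: identity composite, labels unchanged
  one <- aug_multiscale_fuse(list(img), list(lb), target_size = 32L, scale_set = 1.0)
  expect_equal(one$image, img)
  expect_equal(one$labels$cx, lb$cx, tolerance = 1e-6)
  ## 4-tile mosaic: every surviving box inside the unit square
  set.seed(10)
  four <- aug_multiscale_fuse(rep(list(img), 4), rep(list(lb), 4), target_size = 64L,
                              scale_set = c(0.75, 1.0))
  expect_true(all(four$labels$cx - four$labels$w / 2 >= -1e-9))
  expect_true(all(four$labels$cx + four$labels$w / 2 <= 1 + 1e-9))
  expect_true(all(four$labels$class_id %in% c(0L, 2L)))
  ## a box whose visible fraction falls below the threshold is dropped
  edge <- data.frame(class_id = 1L, cx = 0.995, cy = 0.5, w = 0.4, h = 0.02)
  res <- aug_multiscale_fuse(list(img), list(rbind(lb, edge)), target_size = 32L,
                             scale_set = 2.0, min_visible_frac = 0.01)
  expect_false(1L %in% res$labels$class_id)
  expect_true(all(c(0L, 2L) %in% res$labels$class_id))
  expect_error(aug_multiscale_fuse(list(img), list(lb), scale_set = numeric(0)), "empty")
  expect_error(aug_multiscale_fuse(list(), list(), scale_set = 1), "at least one")
})

test_that("an augmentation pipeline is bit-reproducible under a fixed seed", {
  img <- demo_img(6); lb <- demo_labels()
  spec <- list(list(op = "flip", axis = "horizontal"),
               list(op = "motion_blur", length = 5L, angle = 0.4),
               list(op = "illumination", gain_start = 0.8, gain_end = 1.2),
               list(op = "color", amplitude = 0.1))
  a <- apply_augspec(img, lb, spec, seed = 123L)
  b <- apply_augspec(img, lb, spec, seed = 123L)
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
  ## labels stay valid and classes unchanged
  expect_silent(sdbyolo:::check_labels(a$labels))
  expect_identical(a$labels$class_id, lb$class_id)
})
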