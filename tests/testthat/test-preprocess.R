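test_that("gaussian blur preserves constants, identity at radius 0, and mass", {
  const <- matrix(7, 32, 32)
  expect_equal(gaussian_blur(const, 2), const)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(gaussian_blur(img, 0), img)
  point <- matrix(0, 33, 33); point[17, 17] <- 100
  expect_equal(sum(gaussian_blur(point, 1)), 100, tolerance = 1e-6)
})

test_that("background subtraction matches a brute-force morphological oracle", {
  set.seed(21)
  # flat image: zero residual
  expect_equal(subtract_background(matrix(50, 24, 24), 5),
               matrix(0, 24, 24))
  # flat image with a small dark disk, dark object polarity
  img <- matrix(200, 24, 24)
  dm <- disk_mask(3, pad = 9)[1:24, 1:24]
  img[dm] <- 80
  res <- subtract_background(img, 5, "dark_on_light")
  expect_equal(res, brute_subtract_background(img, 5, "dark_on_light"))
  expect_true(all(res[dm] > 0))
  expect_true(all(res[!dm] == 0))
  # bright object polarity against the oracle, with noise
  img2 <- matrix(30 + runif(24 * 24, 0, 5), 24, 24)
  img2[10:14, 8:12] <- img2[10:14, 8:12] + 90
  expect_equal(subtract_background(img2, 4, "light_on_dark"),
               brute_subtract_background(img2, 4, "light_on_dark"))
})

test_that("an illumination ramp without an object leaves only a bounded edge residual", {
  ramp <- matrix(rep(seq(100, 160, length.out = 48), each = 48), 48, 48)
  slope <- 60 / 47
  res10 <- subtract_background(ramp, 10, "dark_on_light")
  expect_equal(res10, brute_subtract_background(ramp, 10, "dark_on_light"))
  # away from the border band the ramp is removed completely ...
  expect_equal(res10[11:38, 11:38], matrix(0, 28, 28))
  # ... and the border band residual is bounded by ball_radius x slope
  expect_lte(max(res10), 10 * slope + 1e-9)
})

test_that("background subtraction honours bounds and dynamic range", {
  img <- matrix(runif(40 * 40, 10, 250), 40, 40)
  res <- subtract_background(img, 6)
  expect_true(all(res >= 0))
  expect_lte(max(res), diff(range(img)))
  expect_error(subtract_background(img, 30), "does not fit")
})

test_that("otsu separates a perfectly bimodal image and rejects constants", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  t <- otsu_threshold(img)
  expect_gte(t, 10); expect_lt(t, 200)
  mask <- binarize(img, t, "dark_on_light")
  expect_identical(mask, img == 10)
  expect_error(otsu_threshold(matrix(5, 4, 4)), "constant")
})

test_that("otsu equals exhaustive between-class-variance search", {
  set.seed(33)
  # a 16-gray-level toy histogram
  v <- sample(seq(0, 240, by = 16), 400, replace = TRUE,
              prob = c(rep(4, 8), rep(1, 8)))
  img <- matrix(v, 20, 20)
  expect_equal(otsu_threshold(img), brute_otsu(v))
  # randomized small-image suite
  for (i in 1:50) {
    v <- sample(0:255, sample(4:64, 1), replace = TRUE)
    if (length(unique(v)) < 2) next
    expect_equal(otsu_threshold(matrix(v, nrow = 1)), brute_otsu(v))
  }
})

test_that("otsu of an image and of its photometric inverse give complementary classes", {
  set.seed(9)
  v <- sample(0:255, 100, replace = TRUE)
  img <- matrix(v, 10, 10)
  inv <- 255 - img
  dark <- binarize(img, otsu_threshold(img), "dark_on_light")
  light <- binarize(inv, otsu_threshold(inv), "light_on_dark")
  expect_identical(dark, light)
})

test_that("binarize obeys its polarity conventions", {
  img <- matrix(1:9, 3, 3)
  expect_true(all(binarize(img, 9, "dark_on_light")))
  expect_identical(binarize(img, 5, "light_on_dark"),
                   !binarize(img, 5, "dark_on_light"))
})

test_that("segmentation recovers the phantom body area within 5%", {
  spec <- small_phantom_spec(contraction_fraction = 0)
  ph <- render_phantom(spec)
  mask <- segment_frame(ph$frames[[1]], small_seg_params())
  # exclude the indicator dot region from the area check
  ind <- roi_mask(roi_disk(spec$indicator_center, spec$indicator_radius + 2),
                  spec$image_size)
  mask[ind] <- FALSE
  true_area <- pi * spec$body_axes[1] * spec$body_axes[2]
  expect_lt(abs(sum(mask) / true_area - 1), 0.05)
  # determinism
  expect_identical(mask_rerun <- segment_frame(ph$frames[[1]], small_seg_params()),
                   segment_frame(ph$frames[[1]], small_seg_params()))
})

test_that("a frame with nothing left after background subtraction yields an empty mask", {
  flat <- matrix(128, 64, 64)
  mask <- segment_frame(flat, small_seg_params())
  expect_identical(mask, matrix(FALSE, 64, 64))
})

test_that("mask area shrinks when the phantom contracts", {
  spec <- small_phantom_spec(contraction_fraction = 0.3, response_tau = 0.01,
                             protocol = stimulus_protocol(2, 2, 1, 8))
  ph <- render_phantom(spec)
  areas <- vapply(ph$frames, function(f) {
    m <- segment_frame(f, small_seg_params())
    ind <- roi_mask(roi_disk(spec$indicator_center, spec$indicator_radius + 2),
                    spec$image_size)
    sum(m & !ind)
  }, numeric(1))
  rest <- mean(areas[!ph$truth$led_state_true])
  contracted <- mean(areas[ph$truth$led_state_true & ph$truth$time_s >=
                             (spec$protocol$delay_s + 0.5)])
  expect_lt(contracted, rest)
})
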