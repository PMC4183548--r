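test_that("RGB to 8-bit HSB matches hand-evaluated conversions", {
  cases <- list(
    list(rgb = c(255, 0, 0), hsb = c(0, 255, 255)),     # pure red, hue 0
    list(rgb = c(128, 128, 128), hsb = c(0, 0, 128)),   # achromatic
    list(rgb = c(0, 0, 255), hsb = c(170, 255, 255)),   # 240 deg * 255/360
    list(rgb = c(0, 255, 0), hsb = c(85, 255, 255)),    # 120 deg * 255/360
    list(rgb = c(0, 0, 0), hsb = c(0, 0, 0))
  )
  for (cs in cases) {
    got <- rgb_to_hsb(matrix(cs$rgb, ncol = 3))
    expect_equal(as.vector(got), cs$hsb, info = paste(cs$rgb, collapse = ","))
  }
})

test_that("conversion agrees with grDevices::rgb2hsv on random pixels", {
  withr::with_seed(7, {
    px <- matrix(sample(0:255, 3000, replace = TRUE), ncol = 3)
    got <- rgb_to_hsb(px)
    ref <- t(grDevices::rgb2hsv(t(px), maxColorValue = 255))
    # same quantization applied to the reference; the two code paths may
    # disagree by one unit where float noise straddles a rounding boundary
    expect_true(all(abs(got[, 1] - floor(ref[, 1] * 255 + 1e-9)) <= 1))
    expect_true(mean(got[, 1] == floor(ref[, 1] * 255 + 1e-9)) > 0.99)
    expect_true(all(abs(got[, 2] - round(ref[, 2] * 255)) <= 1))
    expect_equal(got[, 3], round(ref[, 3] * 255))
  })
})

test_that("conversion is shape-invariant and rejects malformed input", {
  withr::with_seed(1, img <- random_rgb_image(9, 7))
  flat <- rgb_to_hsb(matrix(img, ncol = 3))
  expect_equal(as.vector(rgb_to_hsb(img)), as.vector(flat))
  expect_error(rgb_to_hsb(array(0, c(4, 4, 2))), "3 channels")
  expect_error(rgb_to_hsb(1:10), "array")
})

test_that("hue survives an HSB round trip within one unit when saturated", {
  h <- 0:255
  rgb <- hsb_to_rgb(h, 255, 255)
  back <- rgb_to_hsb(rgb)
  # hue 255 sits at the wheel's wrap point (360 degrees = 0), so compare
  # circularly
  d <- (back[, 1] - h) %% 256
  expect_true(all(pmin(d, 256 - d) <= 1))
  expect_true(all(back[, 3] == 255))
})

test_that("range membership is inclusive on every axis", {
  blue <- mtc_blue_range()
  expect_true(in_hsb_range(125, 100, 100, range = blue))
  expect_true(in_hsb_range(121, 20, 10, range = blue))   # all lower bounds
  expect_true(in_hsb_range(179, 255, 255, range = blue)) # all upper bounds
  expect_false(in_hsb_range(120, 100, 100, range = blue))
  expect_false(in_hsb_range(180, 100, 100, range = blue))
  expect_false(in_hsb_range(125, 19, 100, range = blue))
})

test_that("hsb_range validates its bounds", {
  expect_error(hsb_range(10, 5), "lo <= hi")
  expect_error(hsb_range(-1, 10), "\\[0, 255\\]")
  expect_error(hsb_range(1, 300), "\\[0, 255\\]")
})

test_that("hue classification follows the printed bins, boundaries inclusive", {
  expect_equal(classify_hue(5, 100, 100), "red")
  expect_equal(classify_hue(53, 10, 20), "green")  # lower bounds inclusive
  expect_equal(classify_hue(13, 10, 20), "red")
  expect_equal(classify_hue(14, 10, 20), "orange")
  expect_equal(classify_hue(110, 255, 255), "green")
  # outside any bin: hue 0, hue > 110, or failing S/B floors
  expect_equal(classify_hue(0, 255, 255), "unclassified")
  expect_equal(classify_hue(111, 255, 255), "unclassified")
  expect_equal(classify_hue(230, 255, 255), "unclassified") # no red wraparound
  expect_equal(classify_hue(5, 5, 100), "unclassified")     # S below floor
  expect_equal(classify_hue(5, 100, 19), "unclassified")    # B below floor
})

test_that("overlapping hue bins are rejected at construction", {
  expect_error(psr_bins(red = hsb_range(1, 14, 10, 255, 20, 255)),
               "disjoint")
})

test_that("threshold_mask matches the nested-loop oracle", {
  blue <- mtc_blue_range()
  withr::with_seed(42, {
    for (k in 1:10) {
      img <- random_rgb_image(16, 16)
      expect_identical(sum(threshold_mask(img, blue)),
                       oracle_threshold_count(img, blue))
    }
  })
  # 2x2 image with one pure-blue pixel: blue maps to hue 170, inside 121-179
  img <- array(0L, c(2, 2, 3)); img[1, 1, 3] <- 255L
  expect_equal(sum(threshold_mask(img, blue)), 1)
  # all-black image, any range requiring brightness
  expect_equal(sum(threshold_mask(array(0L, c(3, 3, 3)),
                                  hsb_range(0, 255, 0, 255, 1, 255))), 0)
  # full range accepts everything
  withr::with_seed(5, img <- random_rgb_image(4, 4))
  expect_true(all(threshold_mask(img, hsb_range(0, 255, 0, 255, 0, 255))))
})

test_that("the four default bin masks are pairwise disjoint", {
  withr::with_seed(9, {
    for (k in 1:5) {
      img <- random_rgb_image(20, 20)
      masks <- hue_bin_masks(img)
      overlap <- Reduce(`+`, lapply(masks, as.integer))
      expect_true(all(overlap <= 1))
    }
  })
})
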