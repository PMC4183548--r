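test_that("generators are pure functions of their seed", {
  a <- gen_psr_pair(seed = 99, size = 48)
  b <- gen_psr_pair(seed = 99, size = 48)
  expect_identical(a$polarized, b$polarized)
  expect_identical(a$brightfield, b$brightfield)
  expect_identical(a$truth$bin_counts, b$truth$bin_counts)
  expect_false(identical(a$polarized, gen_psr_pair(seed = 100, size = 48)$polarized))

  expect_identical(gen_mtc_image(seed = 3)$image, gen_mtc_image(seed = 3)$image)
  expect_identical(gen_shg_stack(seed = 3)$stack, gen_shg_stack(seed = 3)$stack)
  expect_identical(gen_cohort(seed = 3)$records, gen_cohort(seed = 3)$records)
})

test_that("painted-pixel bookkeeping matches a recount on the emitted image", {
  sim <- gen_psr_pair(seed = 12, size = 48)
  bg <- sim$truth$params$bg
  corrected <- correct_background(sim$polarized, bg)
  hsb <- matrix(rgb_to_hsb(corrected), ncol = 3)
  lab <- classify_hue(hsb[, 1], hsb[, 2], hsb[, 3])
  for (nm in bin_names()) {
    expect_identical(which(lab == nm), sort(sim$truth$bin_pixels[[nm]]),
                     label = nm)
  }
  # painted bins are disjoint
  all_px <- unlist(sim$truth$bin_pixels)
  expect_equal(anyDuplicated(all_px), 0)
  expect_equal(sum(sim$truth$bin_counts), sim$truth$total_positive)
  # fibres never invade lumens
  expect_length(intersect(all_px, sim$truth$lumen_pixels), 0)
})

test_that("PSR generator honours requested fractions and rejects bad ones", {
  frac <- c(red = 0.1, orange = 0, yellow = 0, green = 0.1)
  sim <- gen_psr_pair(seed = 42, size = 64, fractions = frac)
  expect_identical(unname(sim$truth$bin_counts[c("orange", "yellow")]),
                   c(0L, 0L))
  expect_identical(sim$truth$bin_counts[["red"]],
                   as.integer(round(0.1 * sim$truth$roi_size)))
  q <- quantify_birefringence(correct_background(sim$polarized,
                                                 sim$truth$params$bg),
                              build_roi(sim$polarized,
                                        brightfield = sim$brightfield))
  expect_identical(c(q$n_red, q$n_orange, q$n_yellow, q$n_green),
                   unname(sim$truth$bin_counts))

  blank <- gen_psr_pair(seed = 1, size = 32,
                        fractions = c(red = 0, orange = 0, yellow = 0, green = 0))
  expect_equal(blank$truth$total_fraction, 0)
  expect_error(gen_psr_pair(fractions = c(red = 0.5, orange = 0.4,
                                          yellow = 0.2, green = 0.1)),
               "sum to at most 1")
})

test_that("trichrome generator paints the exact expected mean blue intensity", {
  sim <- gen_mtc_image(seed = 8, size = 64, ecm_fraction = 0.1,
                       blue_brightness = 200)
  e <- quantify_ecm(sim$image)
  expect_equal(e$mean_blue_intensity,
               round(0.1 * 64^2) * 200 / 64^2)  # ~ 0.1 * 200
  expect_identical(e$blue_pixel_count, sim$truth$ecm_count)
  zero <- gen_mtc_image(seed = 8, ecm_fraction = 0)
  expect_equal(quantify_ecm(zero$image)$mean_blue_intensity, 0)
})

test_that("SHG generator respects slice limits and analytic projection", {
  sim <- gen_shg_stack(seed = 15, n_slices = 12)
  expect_equal(dim(sim$stack)[1], 12)
  expect_equal(mean(max_project(sim$stack)), sim$truth$mip_mean)
  expect_error(gen_shg_stack(n_slices = 40), "\\[1, 32\\]")
  expect_error(gen_shg_stack(n_slices = 0), "\\[1, 32\\]")
})

test_that("cohort generator plants slopes and missingness as configured", {
  full <- gen_cohort(seed = 5, n = 200, missing_rates = NULL)
  expect_equal(nrow(full$records), 200)
  expect_false(anyNA(full$records))
  # default missingness mirrors the reported availability (~32% for size)
  dflt <- gen_cohort(seed = 5, n = 470)
  expect_gt(mean(is.na(dflt$records$prostate_size)), 0.5)
  expect_lt(mean(is.na(dflt$records$psa)), 0.5)

  planted <- gen_cohort(seed = 6, n = 400, slopes = c(age = 0.5),
                        noise_sd = 2, missing_rates = NULL)
  fit <- linreg(planted$records$age, planted$records$total_fraction)
  expect_lt(abs(fit$slope - 0.5), 3 * fit$slope_sem)
  expect_lt(fit$p, 1e-6)
  expect_error(gen_cohort(n = 1), "at least 2")
  expect_error(gen_cohort(slopes = c(shoe_size = 1)), "Unknown covariate")
})
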