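# constructs a polarized-style image with known painted pixels
painted_image <- function(size, spots) {
  img <- array(0L, c(size, size, 3))
  for (sp in spots) {
    rgb <- hsb_to_rgb(sp$h, sp$s, sp$b)
    for (idx in sp$px) {
      i <- ((idx - 1) %% size) + 1; j <- ((idx - 1) %/% size) + 1
      img[i, j, ] <- rgb
    }
  }
  img
}

test_that("birefringence counts and both denominators are as constructed", {
  # 10x10, ROI = all 100 px, 20 red px
  img <- painted_image(10, list(list(h = 6, s = 150, b = 150, px = 1:20)))
  q <- quantify_birefringence(img)
  expect_equal(q$n_red, 20L)
  expect_equal(q$total_positive, 20L)
  expect_equal(q$total_fraction, 0.20)
  expect_equal(q$prop_red, 1.0)
  expect_equal(q$roi_size, 100L)

  # 10 red + 10 green -> proportions 0.5 / 0.5
  img2 <- painted_image(10, list(
    list(h = 6, s = 150, b = 150, px = 1:10),
    list(h = 80, s = 150, b = 150, px = 11:20)
  ))
  q2 <- quantify_birefringence(img2)
  expect_equal(q2$prop_red, 0.5)
  expect_equal(q2$prop_green, 0.5)
  expect_equal(q2$total_fraction, 0.2)
})

test_that("invariants hold and empty ROI / blank images are handled", {
  withr::with_seed(13, img <- random_rgb_image(16, 16))
  q <- quantify_birefringence(img)
  expect_equal(q$total_positive, q$n_red + q$n_orange + q$n_yellow + q$n_green)
  expect_equal(q$total_fraction, q$total_positive / q$roi_size)
  expect_equal(q$prop_red + q$prop_orange + q$prop_yellow + q$prop_green, 1)

  blank <- array(0L, c(8, 8, 3))
  qb <- quantify_birefringence(blank)
  expect_equal(qb$total_fraction, 0)
  expect_true(is.na(qb$prop_red))  # undefined, not 0/0

  expect_error(
    suppressWarnings(quantify_birefringence(blank, matrix(FALSE, 8, 8))),
    "unquantifiable")
})

test_that("counts are invariant to pixel permutation and scale under replication", {
  sim <- gen_psr_pair(seed = 31, size = 48)
  img <- sim$polarized
  q <- quantify_birefringence(img)

  withr::with_seed(1, perm <- sample.int(48 * 48))
  shuffled <- array(0L, dim(img))
  hw <- 48 * 48
  for (ch in 0:2) shuffled[perm + ch * hw] <- img[seq_len(hw) + ch * hw]
  qs <- quantify_birefringence(shuffled)
  expect_equal(qs[paste0("n_", bin_names())], q[paste0("n_", bin_names())])

  # 2x2 pixel replication: counts x4, fractions unchanged
  big <- img[rep(1:48, each = 2), rep(1:48, each = 2), ]
  qbig <- quantify_birefringence(big)
  expect_equal(qbig$total_positive, 4L * q$total_positive)
  expect_equal(qbig$total_fraction, q$total_fraction)
  expect_equal(qbig$prop_orange, q$prop_orange)
})

test_that("bin counting inside an ROI matches the nested-loop oracle", {
  bins <- psr_bins()
  withr::with_seed(77, {
    for (k in 1:8) {
      img <- random_rgb_image(12, 12)
      mask <- matrix(sample(c(TRUE, FALSE), 144, replace = TRUE,
                            prob = c(0.8, 0.2)), 12, 12)
      if (!any(mask)) next
      q <- quantify_birefringence(img, mask)
      ora <- oracle_bin_counts(img, bins, mask)
      expect_identical(c(q$n_red, q$n_orange, q$n_yellow, q$n_green),
                       unname(as.integer(ora)))
    }
  })
})

test_that("replicate averaging is the unweighted mean", {
  reps <- dplyr::bind_rows(
    tibble::tibble(patient_id = "a", total_fraction = c(0.4, 0.5, 0.6),
                   prop_red = c(0.2, 0.4, 0.3), prop_green = c(0.8, 0.6, 0.7)),
    tibble::tibble(patient_id = "b", total_fraction = 0.3,
                   prop_red = 0.5, prop_green = 0.5)
  )
  avg <- average_replicates(reps)
  expect_equal(avg$total_fraction[avg$patient_id == "a"], 0.5)
  expect_equal(avg$prop_red[avg$patient_id == "a"], 0.3)
  expect_equal(avg$n_replicates, c(3L, 1L))
  # single replicate is the identity
  expect_equal(avg$total_fraction[avg$patient_id == "b"], 0.3)
  expect_error(average_replicates(reps[0, ]), "No replicate")
})

test_that("normalization pins the reference-group mean at exactly 1", {
  samples <- tibble::tibble(
    group = c("ref", "ref", "other", "other"),
    prop_red = c(0.2, 0.4, 0.5, 0.1),
    prop_orange = c(0.1, 0.3, 0.2, 0.2),
    prop_yellow = c(0.4, 0.2, 0.2, 0.5),
    prop_green = c(0.3, 0.1, 0.1, 0.2)
  )
  norm <- normalize_to_reference(samples, reference = "ref")
  expect_equal(norm$norm_prop_red[1:2], c(0.2, 0.4) / 0.3)
  for (nm in paste0("norm_prop_", bin_names())) {
    expect_equal(mean(norm[[nm]][norm$group == "ref"]), 1, tolerance = 1e-12)
  }
  # single-sample reference normalizes itself to exactly 1
  one <- normalize_to_reference(samples[c(1, 3), ], reference = "ref")
  expect_equal(one$norm_prop_red[1], 1)
  # zero reference mean names the offending bin
  bad <- samples; bad$prop_red[1:2] <- 0
  expect_error(normalize_to_reference(bad, reference = "ref"), "prop_red")
  expect_error(normalize_to_reference(samples, reference = "missing"),
               "empty")
})
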