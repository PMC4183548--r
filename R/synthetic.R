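# Seeded synthetic histology generators. Every generator is a pure function
# of its seed and parameters, and records exact painted ground truth so the
# measurement code can be tested against zero-tolerance expectations.
#
# Painted colours are constructed >= 2 units inside their HSB bin boundaries
# so that RGB <-> HSB quantization cannot move a pixel across a bin edge,
# and the polarized background is a uniform offset so background estimation
# and correction recover the painted colours bit-exactly. The fixtures test
# the measurement code, not microscopy: there is no polarization physics or
# PSF model.

# ---- low-level raster helpers ------------------------------------------

disc_offsets <- function(width) {
  r <- max(0, (width - 1) / 2)
  g <- expand.grid(di = -ceiling(r):ceiling(r), dj = -ceiling(r):ceiling(r))
  g <- g[g$di^2 + g$dj^2 <= r^2 + 1e-9, , drop = FALSE]
  g
}

# pixel indices (column-major) of a thick line segment, clipped to the frame
stroke_pixels <- function(i0, j0, theta, len, width, h, w) {
  t <- seq(0, len, by = 0.5)
  ii <- round(i0 + t * sin(theta))
  jj <- round(j0 + t * cos(theta))
  off <- disc_offsets(width)
  ii <- rep(ii, each = nrow(off)) + off$di
  jj <- rep(jj, each = nrow(off)) + off$dj
  keep <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
  unique(as.integer(ii[keep] + (jj[keep] - 1) * h))
}

ellipse_pixels <- function(ci, cj, ri, rj, h, w) {
  ii <- matrix(seq_len(h), h, w)
  jj <- matrix(seq_len(w), h, w, byrow = TRUE)
  which(((ii - ci) / ri)^2 + ((jj - cj) / rj)^2 <= 1)
}

# deterministic palette of RGB colours strictly interior to an HSB bin
bin_palette <- function(range, margin = 2L) {
  hs <- unique(pmax(range$h_lo + margin,
                    pmin(range$h_hi - margin,
                         floor(seq(range$h_lo + margin, range$h_hi - margin,
                                   length.out = 4)))))
  grid <- expand.grid(h = hs, s = c(80L, 140L, 200L), b = c(60L, 120L, 180L))
  rgb <- hsb_to_rgb(grid$h, grid$s, grid$b)
  back <- rgb_to_hsb(rgb)
  ok <- in_hsb_range(back[, 1], back[, 2], back[, 3], range)
  rgb[ok, , drop = FALSE]
}

paint_channels <- function(img, idx, rgb) {
  hw <- dim(img)[1] * dim(img)[2]
  img[idx] <- rgb[1]
  img[idx + hw] <- rgb[2]
  img[idx + 2L * hw] <- rgb[3]
  img
}

flat_rgb <- function(h, w, rgb) {
  array(rep(as.integer(rgb), each = h * w), dim = c(h, w, 3))
}

# paint strokes into `avail` pixels until exactly `target` are covered;
# returns list(indices, image). Falls back to single random pixels if stroke
# placement stalls, so counts are always exact.
paint_fibres <- function(img, avail, target, palette, len_range, width_range,
                         h, w) {
  painted <- integer(0)
  remaining <- target
  guard <- 0L
  while (remaining > 0L) {
    guard <- guard + 1L
    open <- which(avail)
    if (length(open) == 0L) abort("Ran out of paintable pixels.")
    if (guard <= 2000L) {
      start <- open[sample.int(length(open), 1L)]
      i0 <- ((start - 1L) %% h) + 1L
      j0 <- ((start - 1L) %/% h) + 1L
      px <- stroke_pixels(i0, j0, stats::runif(1, 0, pi),
                          stats::runif(1, len_range[1], len_range[2]),
                          sample(seq(width_range[1], width_range[2]), 1L),
                          h, w)
      px <- px[avail[px]]
    } else {
      px <- open[sample.int(length(open), min(remaining, length(open)))]
    }
    if (length(px) == 0L) next
    if (length(px) > remaining) px <- px[seq_len(remaining)]
    colour <- palette[sample.int(nrow(palette), 1L), ]
    img <- paint_channels(img, px, colour)
    avail[px] <- FALSE
    painted <- c(painted, px)
    remaining <- remaining - length(px)
  }
  list(img = img, idx = painted, avail = avail)
}

# ---- Picrosirius red brightfield/polarized pair ------------------------

#' Default birefringence bin fractions for synthetic fields
#'
#' Per-bin target fractions of the region of interest. The defaults give a
#' total birefringent fraction of 0.53 split 10/15/40/35 percent across
#' red/orange/yellow/green, matching the magnitude of the reported group
#' means (total birefringence near 53 percent, thin green/yellow fibrils
#' dominating the birefringent area).
#'
#' @return Named numeric vector over the four bins.
#' @export
default_bin_fractions <- function() {
  0.53 * c(red = 0.10, orange = 0.15, yellow = 0.40, green = 0.35)
}

#' Generate a synthetic Picrosirius red image pair
#'
#' Produces a pixel-aligned brightfield/polarized pair plus exact ground
#' truth. The polarized frame is a uniform near-black background (`bg`
#' offset) with fibre strokes painted in HSB colours strictly interior to
#' their target bins, shifted by the background offset so that background
#' estimation and subtraction restore them exactly. The brightfield frame is
#' a pink tissue field with near-white lumen ellipses at the same
#' coordinates; lumens carry no fibres.
#'
#' @param seed Integer seed; fully determines the output.
#' @param size Image side in pixels (square frames). Default 96.
#' @param fractions Named per-bin target fractions of the ROI
#'   (red/orange/yellow/green), summing to at most 1.
#' @param bg Length-3 background offset of the polarized frame.
#' @param lumen_n Number of glandular lumen ellipses. Default 2.
#' @param lumen_radius Lumen radii as fractions of `size` (min, max).
#' @param fiber_len,fiber_width Stroke length (px) and width (px) ranges.
#' @param tissue_rgb,lumen_rgb Brightfield colours for tissue and lumen.
#' @param brightfield_noise Max absolute uniform integer noise added to the
#'   brightfield (kept small enough not to cross the near-white thresholds).
#' @return List (classed `psr_sim`): `brightfield`, `polarized` (RGB
#'   arrays), and `truth` with per-bin painted pixel indices and counts,
#'   the lumen pixel set, `roi_size`, realized `total_fraction` and
#'   per-bin proportions, and the generating parameters.
#' @export
gen_psr_pair <- function(seed = 1L, size = 96L,
                         fractions = default_bin_fractions(),
                         bg = c(10L, 5L, 12L),
                         lumen_n = 2L, lumen_radius = c(0.06, 0.15),
                         fiber_len = c(8, 25), fiber_width = c(1, 3),
                         tissue_rgb = c(222L, 170L, 185L),
                         lumen_rgb = c(247L, 247L, 245L),
                         brightfield_noise = 3L) {
  fractions <- fractions[bin_names()]
  if (anyNA(fractions)) abort("`fractions` must name all four bins.")
  if (any(fractions < 0) || sum(fractions) > 1) {
    abort("Bin fractions must be nonnegative and sum to at most 1.")
  }
  if (any(bg < 0) || any(bg > 15)) abort("`bg` offsets must lie in [0, 15].")

  withr::with_seed(seed, {
    h <- w <- as.integer(size)
    n_px <- h * w

    lumen_idx <- integer(0)
    for (k in seq_len(lumen_n)) {
      ri <- stats::runif(1, lumen_radius[1], lumen_radius[2]) * size
      rj <- stats::runif(1, lumen_radius[1], lumen_radius[2]) * size
      ci <- stats::runif(1, ri + 1, h - ri)
      cj <- stats::runif(1, rj + 1, w - rj)
      lumen_idx <- union(lumen_idx, ellipse_pixels(ci, cj, ri, rj, h, w))
    }
    tissue_idx <- setdiff(seq_len(n_px), lumen_idx)
    roi_size <- length(tissue_idx)

    # brightfield: pink tissue, near-white lumens, small uniform noise
    bf <- flat_rgb(h, w, tissue_rgb)
    bf <- paint_channels(bf, lumen_idx, lumen_rgb)
    if (brightfield_noise > 0) {
      bf <- bf + array(sample(-brightfield_noise:brightfield_noise,
                              n_px * 3L, replace = TRUE), dim = dim(bf))
      bf[bf < 0L] <- 0L; bf[bf > 255L] <- 255L
    }
    storage.mode(bf) <- "integer"

    # polarized: uniform background offset, fibres painted colour + offset
    pol <- flat_rgb(h, w, bg)
    avail <- logical(n_px)
    avail[tissue_idx] <- TRUE
    bins <- psr_bins()
    bin_idx <- list()
    for (nm in bin_names()) {
      target <- as.integer(round(fractions[[nm]] * roi_size))
      if (target == 0L) { bin_idx[[nm]] <- integer(0); next }
      pal <- sweep(bin_palette(bins[[nm]]), 2, as.integer(bg), `+`)
      res <- paint_fibres(pol, avail, target, pal, fiber_len, fiber_width,
                          h, w)
      pol <- res$img; avail <- res$avail; bin_idx[[nm]] <- res$idx
    }
    storage.mode(pol) <- "integer"

    counts <- vapply(bin_idx, length, integer(1))
    total_pos <- sum(counts)
    truth <- list(
      bin_pixels = bin_idx,
      bin_counts = counts,
      total_positive = total_pos,
      lumen_pixels = lumen_idx,
      roi_size = roi_size,
      total_fraction = total_pos / roi_size,
      proportions = if (total_pos > 0) counts / total_pos else
        stats::setNames(rep(NA_real_, 4), bin_names()),
      params = list(seed = seed, size = size, fractions = fractions, bg = bg,
                    lumen_n = lumen_n)
    )
    structure(list(brightfield = bf, polarized = pol, truth = truth),
              class = "psr_sim")
  })
}

# ---- Masson's trichrome image ------------------------------------------

#' Generate a synthetic Masson's trichrome image
#'
#' Blue ECM strokes painted strictly inside the blue threshold box over a
#' red/pink cellular field. The painted brightness is fixed so the expected
#' mean blue intensity per tissue area is exactly
#' `ecm_fraction * blue_brightness`.
#'
#' @param seed Integer seed.
#' @param size Image side in pixels. Default 96.
#' @param ecm_fraction Target ECM (blue) fraction of the frame; default 0.03,
#'   giving mean blue intensities near the reported magnitude of 5-6.
#' @param blue_brightness Painted HSB brightness of ECM pixels (exactly
#'   preserved through quantization). Default 200.
#' @param cyto_rgb Cytoplasm colour, outside the blue box.
#' @param fiber_len,fiber_width Stroke geometry ranges.
#' @return List (classed `mtc_sim`): `image`, `truth` (ECM pixel indices
#'   and count, tissue area, expected `mean_blue_intensity` and
#'   `blue_area_fraction`, params).
#' @export
gen_mtc_image <- function(seed = 1L, size = 96L, ecm_fraction = 0.03,
                          blue_brightness = 200L,
                          cyto_rgb = c(230L, 170L, 180L),
                          fiber_len = c(8, 25), fiber_width = c(1, 3)) {
  if (ecm_fraction < 0 || ecm_fraction > 1) {
    abort("`ecm_fraction` must lie in [0, 1].")
  }
  withr::with_seed(seed, {
    h <- w <- as.integer(size)
    n_px <- h * w
    img <- flat_rgb(h, w, cyto_rgb)

    blue <- mtc_blue_range()
    hs <- floor(seq(blue$h_lo + 2L, blue$h_hi - 2L, length.out = 5))
    grid <- expand.grid(h = hs, s = c(80L, 140L, 200L))
    pal <- hsb_to_rgb(grid$h, grid$s, as.integer(blue_brightness))
    back <- rgb_to_hsb(pal)
    pal <- pal[in_hsb_range(back[, 1], back[, 2], back[, 3], blue) &
                 back[, 3] == as.integer(blue_brightness), , drop = FALSE]

    target <- as.integer(round(ecm_fraction * n_px))
    ecm_idx <- integer(0)
    if (target > 0L) {
      avail <- rep(TRUE, n_px)
      res <- paint_fibres(img, avail, target, pal, fiber_len, fiber_width,
                          h, w)
      img <- res$img; ecm_idx <- res$idx
    }
    storage.mode(img) <- "integer"
    truth <- list(
      ecm_pixels = ecm_idx,
      ecm_count = length(ecm_idx),
      tissue_area = n_px,
      mean_blue_intensity = length(ecm_idx) * blue_brightness / n_px,
      blue_area_fraction = length(ecm_idx) / n_px,
      params = list(seed = seed, size = size, ecm_fraction = ecm_fraction,
                    blue_brightness = blue_brightness)
    )
    structure(list(image = img, truth = truth), class = "mtc_sim")
  })
}

# ---- SHG stack ----------------------------------------------------------

#' Generate a synthetic second harmonic generation stack
#'
#' Fibres are spread across optical sections with a Gaussian intensity
#' falloff around each fibre's focal slice, emulating 12-15 sections per
#' core. Ground truth includes the exact elementwise-maximum projection
#' (built from the paint records) and its mean.
#'
#' @param seed Integer seed.
#' @param size Frame side in pixels. Default 64.
#' @param n_slices Number of optical sections; default sampled in 12-15.
#'   Must lie in \[1, `max_slices`\].
#' @param max_slices Upper bound on stack depth. Default 32.
#' @param n_fibers Number of fibres. Default 8.
#' @param peak_range Peak fibre intensity range (8-bit). Default 120-220.
#' @param sigma_z Gaussian falloff (in slices) around the focal slice.
#' @param fiber_len,fiber_width Stroke geometry ranges.
#' @return List (classed `shg_sim`): `stack` (Z x H x W integer array),
#'   `truth` (`projection` matrix, `mip_mean`, `n_slices`, params).
#' @export
gen_shg_stack <- function(seed = 1L, size = 64L, n_slices = NULL,
                          max_slices = 32L, n_fibers = 8L,
                          peak_range = c(120, 220), sigma_z = 1.5,
                          fiber_len = c(10, 30), fiber_width = c(1, 3)) {
  withr::with_seed(seed, {
    if (is.null(n_slices)) n_slices <- sample(12:15, 1L)
    if (n_slices < 1L || n_slices > max_slices) {
      abort(sprintf("`n_slices` must lie in [1, %d].", max_slices))
    }
    h <- w <- as.integer(size)
    stack <- array(0L, dim = c(n_slices, h, w))
    proj <- matrix(0L, h, w)
    for (f in seq_len(n_fibers)) {
      start <- sample.int(h * w, 1L)
      px <- stroke_pixels(((start - 1L) %% h) + 1L, ((start - 1L) %/% h) + 1L,
                          stats::runif(1, 0, pi),
                          stats::runif(1, fiber_len[1], fiber_len[2]),
                          sample(seq(fiber_width[1], fiber_width[2]), 1L),
                          h, w)
      peak <- stats::runif(1, peak_range[1], peak_range[2])
      z0 <- sample.int(n_slices, 1L)
      for (z in seq_len(n_slices)) {
        val <- as.integer(round(peak * exp(-(z - z0)^2 / (2 * sigma_z^2))))
        if (val <= 0L) next
        flat <- (z - 1L) + (px - 1L) * n_slices + 1L  # index into Z x H x W
        stack[flat] <- pmax(stack[flat], val)
      }
      peak_i <- as.integer(round(peak))  # z = z0 term: exp(0) = 1
      proj[px] <- pmax(proj[px], peak_i)
    }
    truth <- list(
      projection = proj,
      mip_mean = mean(proj),
      n_slices = n_slices,
      params = list(seed = seed, size = size, n_fibers = n_fibers,
                    sigma_z = sigma_z)
    )
    structure(list(stack = stack, truth = truth), class = "shg_sim")
  })
}

# ---- clinical cohort ----------------------------------------------------

#' Generate a synthetic clinical cohort
#'
#' Emulates a retrospective surgical cohort: covariates drawn to match the
#' reported medians and interquartile ranges (log-normal PSA, post-void
#' residuals and prostate size; near-normal age and symptom index), two
#' treatment flags, and a collagen metric generated as a linear function of
#' chosen covariates plus Gaussian noise. All slopes and flag effects
#' default to 0 (the null). Missingness is applied per covariate after
#' metric generation, at the availability rates of the reported table;
#' missing values are `NA`, never imputed.
#'
#' @param seed Integer seed.
#' @param n Number of patients. Default 47.
#' @param slopes Named list/vector of true slopes on (median-centred)
#'   covariates, e.g. `c(age = 0.5)`. Default none.
#' @param flag_effects Named additive effects of `alpha_blocker` and
#'   `finasteride`. Default 0.
#' @param baseline Metric mean at covariate medians. Default 52.9.
#' @param noise_sd Residual SD of the metric. Default 11 (the between-
#'   patient spread implied by a group SEM of 2.3 at n = 24).
#' @param missing_rates Named missingness probabilities; `NULL` for
#'   complete data. Defaults mirror the reported availability.
#' @return List (classed `cohort_sim`): `records` (tibble, one row per
#'   patient) and `truth` (generating parameters).
#' @export
gen_cohort <- function(seed = 1L, n = 47L, slopes = NULL, flag_effects = NULL,
                       baseline = 52.9, noise_sd = 11,
                       missing_rates = c(prostate_size = 1 - 15 / 47,
                                         auasi = 1 - 15 / 47,
                                         pvr_pre = 1 - 19 / 47,
                                         pvr_post = 1 - 24 / 47,
                                         psa = 1 - 34 / 47)) {
  if (n < 2L) abort("Cohort needs at least 2 patients.")
  slopes <- unlist(slopes %||% numeric(0))
  flag_effects <- unlist(flag_effects %||% numeric(0))

  withr::with_seed(seed, {
    centres <- c(age = 70, psa = 4.05, prostate_size = 35, auasi = 21,
                 pvr_pre = 164, pvr_post = 80)
    records <- tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      age = round(pmin(90, pmax(45, stats::rnorm(n, 70, 8)))),
      psa = round(stats::rlnorm(n, log(4.05), 0.895), 2),
      prostate_size = round(stats::rlnorm(n, log(35), 0.243), 1),
      auasi = round(pmin(35, pmax(0, stats::rnorm(n, 21, 5.6)))),
      pvr_pre = round(stats::rlnorm(n, log(164), 1.042), 1),
      pvr_post = round(stats::rlnorm(n, log(80), 1.743), 1),
      alpha_blocker = stats::runif(n) < 37 / 47,
      finasteride = stats::runif(n) < 22 / 47
    )

    metric <- rep(baseline, n)
    for (nm in names(slopes)) {
      if (!nm %in% names(records)) abort(sprintf("Unknown covariate `%s`.", nm))
      centre <- if (nm %in% names(centres)) centres[[nm]] else 0
      metric <- metric + slopes[[nm]] * (records[[nm]] - centre)
    }
    for (nm in names(flag_effects)) {
      if (!nm %in% names(records)) abort(sprintf("Unknown flag `%s`.", nm))
      metric <- metric + flag_effects[[nm]] * as.numeric(records[[nm]])
    }
    records$total_fraction <- metric + stats::rnorm(n, 0, noise_sd)

    if (!is.null(missing_rates)) {
      for (nm in names(missing_rates)) {
        drop <- stats::runif(n) < missing_rates[[nm]]
        records[[nm]][drop] <- NA
      }
    }

    truth <- list(slopes = slopes, flag_effects = flag_effects,
                  baseline = baseline, noise_sd = noise_sd,
                  params = list(seed = seed, n = n))
    structure(list(records = records, truth = truth), class = "cohort_sim")
  })
}

# ---- study-level simulation ---------------------------------------------

#' Simulate a two-group Picrosirius red study on disk
#'
#' Draws per-patient birefringence parameters (total fraction and per-bin
#' proportions, log-normal between-patient variation), renders each
#' patient's image pair(s) with [gen_psr_pair()], writes PNGs into `dir`,
#' and returns the manifest [run_tma_comparison()] consumes.
#'
#' Default dispersions are the coefficients of variation implied by the
#' reported normalized SEMs at n = 24 (red 0.47, orange 0.31, yellow 0.16,
#' green 0.23); total fraction CV 0.21.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param groups Named integer vector of patients per group,
#'   e.g. `c(normal = 48, bph = 24)`.
#' @param prop_shift Named list: per group, multiplicative shifts on mean
#'   proportions, e.g. `list(bph = c(orange = 1.25))`. Shifted bins get
#'   exactly the stated multiplier; the remaining bins are scaled down
#'   together so the proportions still sum to 1.
#' @param mean_props Baseline mean proportions over bins (sum 1).
#' @param prop_cv Per-bin CVs of the proportions.
#' @param total_fraction_mean,total_fraction_cv Between-patient distribution
#'   of the total birefringent fraction.
#' @param replicates Images per patient (1-3). Default 1.
#' @param size Image side in pixels. Default 64.
#' @return Tibble manifest: `patient_id`, `group`, `replicate`,
#'   `polarized`, `brightfield` (file paths), plus the per-patient true
#'   fractions used.
#' @export
simulate_psr_study <- function(dir, seed = 1L,
                               groups = c(normal = 48L, bph = 24L),
                               prop_shift = list(),
                               mean_props = c(red = 0.10, orange = 0.15,
                                              yellow = 0.40, green = 0.35),
                               prop_cv = c(red = 0.47, orange = 0.31,
                                           yellow = 0.16, green = 0.23),
                               total_fraction_mean = 0.53,
                               total_fraction_cv = 0.21,
                               replicates = 1L, size = 64L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stopifnot(replicates >= 1L, replicates <= 3L)
  withr::with_seed(seed, {
    rows <- list()
    pat <- 0L
    for (g in names(groups)) {
      props_g <- mean_props / sum(mean_props)
      shift <- prop_shift[[g]]
      if (!is.null(shift)) {
        if (!all(names(shift) %in% names(props_g))) {
          abort("`prop_shift` names must be bins.")
        }
        shifted <- props_g[names(shift)] * shift
        if (sum(shifted) >= 1) abort("Shifted proportions exceed 1.")
        others <- setdiff(names(props_g), names(shift))
        props_g[others] <- props_g[others] *
          (1 - sum(shifted)) / sum(props_g[others])
        props_g[names(shift)] <- shifted
      }
      for (k in seq_len(groups[[g]])) {
        pat <- pat + 1L
        id <- sprintf("%s_%03d", g, k)
        tf <- stats::rlnorm(1, log(total_fraction_mean) -
                              log(1 + total_fraction_cv^2) / 2,
                            sqrt(log(1 + total_fraction_cv^2)))
        tf <- min(0.85, max(0.05, tf))
        pp <- stats::rlnorm(4, log(props_g[bin_names()]) -
                              log(1 + prop_cv[bin_names()]^2) / 2,
                            sqrt(log(1 + prop_cv[bin_names()]^2)))
        pp <- pp / sum(pp)
        frac <- stats::setNames(tf * pp, bin_names())
        for (rep_i in seq_len(replicates)) {
          sim <- gen_psr_pair(
            seed = sample.int(.Machine$integer.max, 1L),
            size = size, fractions = frac
          )
          pol_path <- file.path(dir, sprintf("%s_r%d_pol.png", id, rep_i))
          bf_path <- file.path(dir, sprintf("%s_r%d_bf.png", id, rep_i))
          write_image(sim$polarized, pol_path)
          write_image(sim$brightfield, bf_path)
          rows[[length(rows) + 1L]] <- tibble(
            patient_id = id, group = g, replicate = rep_i,
            polarized = pol_path, brightfield = bf_path,
            true_total_fraction = unname(sum(frac)),
            true_prop_red = unname(pp[1]), true_prop_orange = unname(pp[2]),
            true_prop_yellow = unname(pp[3]), true_prop_green = unname(pp[4])
          )
        }
      }
    }
    bind_rows(rows)
  })
}

#' Write a complete fixture set to a directory
#'
#' Generates Picrosirius red pairs, a trichrome image, an SHG stack and a
#' clinical cohort, writing images, a manifest, the cohort CSV and ground
#' truth as JSON.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n_pairs Number of PSR image pairs. Default 3.
#' @return Invisibly, a list of the written paths.
#' @export
simulate_fixtures <- function(dir, seed = 1L, n_pairs = 3L) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("simulate_fixtures() needs the jsonlite package.")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- simulate_psr_study(dir, seed = seed,
                                 groups = c(normal = n_pairs),
                                 replicates = 1L)
  mtc <- gen_mtc_image(seed = seed + 1L)
  mtc_path <- file.path(dir, "mtc.png")
  write_image(mtc$image, mtc_path)
  shg <- gen_shg_stack(seed = seed + 2L)
  shg_path <- file.path(dir, "shg_stack.tif")
  write_image(shg$stack, shg_path)
  cohort <- gen_cohort(seed = seed + 3L)
  cohort_path <- file.path(dir, "cohort.csv")
  utils::write.csv(cohort$records, cohort_path, row.names = FALSE)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  truth <- list(
    mtc = mtc$truth[c("ecm_count", "tissue_area", "mean_blue_intensity")],
    shg = list(mip_mean = shg$truth$mip_mean, n_slices = shg$truth$n_slices),
    cohort = cohort$truth[c("slopes", "baseline", "noise_sd")]
  )
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest_path, mtc = mtc_path, shg = shg_path,
                 cohort = cohort_path, truth = truth_path))
}
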