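# Background correction of polarized-light images and automated ROI
# construction. The original workflow removed background colour with an
# interactive plugin and measured ROI size by hand in a photo editor; here
# both are deterministic rules with a mask-file escape hatch.

#' Estimate the background colour of a polarized-light image
#'
#' Polarized-light micrographs have a dark, nominally featureless background
#' wherever no birefringent fibre lies. The estimate is the per-channel
#' median of the darkest `dark_quantile` fraction of pixels, ranked by HSB
#' brightness (max channel). Ties at the brightness cutoff are broken by
#' row-major pixel order under a stable sort, so the estimate is fully
#' deterministic.
#'
#' @param polarized RGB image array.
#' @param dark_quantile Fraction of pixels, in (0, 0.5\], used for the
#'   estimate. Default 0.25.
#' @return A list with `offset` (length-3 integer vector r, g, b) and
#'   `fraction_used`, classed `background_estimate`.
#' @export
estimate_background <- function(polarized, dark_quantile = 0.25) {
  if (!is.numeric(dark_quantile) || dark_quantile <= 0 || dark_quantile > 0.5) {
    abort("`dark_quantile` must lie in (0, 0.5].")
  }
  px <- matrix(as.numeric(polarized), ncol = 3L)
  bright <- pmax(px[, 1], px[, 2], px[, 3])
  if (max(bright) == min(bright) && stats::var(as.vector(px)) == 0) {
    warn("Degenerate image (single value); background set to that value.")
  }
  n_dark <- max(1L, as.integer(ceiling(dark_quantile * nrow(px))))
  idx <- order(bright)[seq_len(n_dark)]  # stable: ties keep row-major order
  offset <- apply(px[idx, , drop = FALSE], 2, stats::median)
  structure(
    list(offset = as.integer(round(offset)), fraction_used = dark_quantile),
    class = "background_estimate"
  )
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf("<background_estimate rgb (%d, %d, %d), darkest %.0f%% of pixels>\n",
              x$offset[1], x$offset[2], x$offset[3], 100 * x$fraction_used))
  invisible(x)
}

#' Subtract a background estimate from an image
#'
#' Per-channel subtraction clamped at zero; output stays in \[0, 255\].
#' Re-estimating on the corrected output returns offsets of zero (up to
#' quantization), so the operation is idempotent.
#'
#' @param img RGB image array.
#' @param bg A `background_estimate`, or a length-3 numeric offset vector.
#' @return Corrected RGB image array.
#' @export
correct_background <- function(img, bg) {
  offset <- if (inherits(bg, "background_estimate")) bg$offset else bg
  if (length(offset) != 3L) abort("`bg` must supply three channel offsets.")
  d <- dim(img)
  px <- matrix(as.numeric(img), ncol = 3L)
  px <- sweep(px, 2, as.numeric(offset))
  px[px < 0] <- 0
  out <- array(as.integer(px), dim = d)
  out
}

#' Tissue mask from a brightfield image
#'
#' Marks pixels as tissue unless they are near-white: empty slide background
#' and glandular lumens appear bright and unsaturated under brightfield.
#' A pixel is excluded when brightness >= `white_cut` AND saturation <=
#' `min_sat` (8-bit HSB scale).
#'
#' Raising `white_cut` (or lowering `min_sat`) can only grow the mask.
#'
#' @param brightfield RGB image array.
#' @param white_cut Brightness threshold in \[0, 255\]; default 230.
#' @param min_sat Saturation ceiling in \[0, 255\]; default 25.
#' @return H x W logical mask, `TRUE` on tissue.
#' @export
tissue_mask <- function(brightfield, white_cut = 230, min_sat = 25) {
  if (white_cut < 0 || white_cut > 255 || min_sat < 0 || min_sat > 255) {
    abort("Thresholds must lie in [0, 255].")
  }
  hsb <- rgb_to_hsb(brightfield)
  d <- dim(hsb)
  px <- matrix(hsb, ncol = 3L)
  near_white <- px[, 3] >= white_cut & px[, 2] <= min_sat
  matrix(!near_white, nrow = d[1], ncol = d[2])
}

#' Build a region of interest for a polarized image
#'
#' The ROI is the tissue region over which birefringence is scored: total
#' pixels minus empty and glandular space. Either pass a brightfield partner
#' image (same field of view, pixel-aligned; lumens are invisible under
#' polarization so the brightfield carries that information) for automatic
#' masking, or supply a mask directly.
#'
#' @param polarized RGB image array the ROI will be applied to.
#' @param brightfield Optional brightfield partner (RGB array) for
#'   automatic masking via [tissue_mask()].
#' @param mask Optional H x W logical (or 0/1) mask; `TRUE`/nonzero = inside
#'   the ROI. Overrides `brightfield`.
#' @param white_cut,min_sat Passed to [tissue_mask()] in auto mode.
#' @return A list with `mode` (`"auto"` or `"provided"`), `mask` and
#'   `roi_size`, classed `roi_spec`. `roi_size = 0` flags the image as
#'   unquantifiable.
#' @export
build_roi <- function(polarized, brightfield = NULL, mask = NULL,
                      white_cut = 230, min_sat = 25) {
  target_dim <- dim(polarized)[1:2]
  if (!is.null(mask)) {
    m <- mask
    if (is.numeric(m)) m <- m != 0
    if (!identical(as.integer(dim(m)), as.integer(target_dim))) {
      abort(sprintf(
        "Provided mask is %s but the polarized image is %s.",
        paste(dim(m), collapse = "x"), paste(target_dim, collapse = "x")
      ))
    }
    mode <- "provided"
  } else if (!is.null(brightfield)) {
    if (!identical(as.integer(dim(brightfield)[1:2]), as.integer(target_dim))) {
      abort("Brightfield partner and polarized image differ in shape.")
    }
    m <- tissue_mask(brightfield, white_cut = white_cut, min_sat = min_sat)
    mode <- "auto"
  } else {
    abort("Supply either `brightfield` or `mask`.")
  }
  roi_size <- sum(m)
  if (roi_size == 0) {
    warn("ROI is empty; image is unquantifiable.")
  }
  structure(list(mode = mode, mask = m, roi_size = as.integer(roi_size)),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec mode=%s, roi_size=%d of %d px>\n",
              x$mode, x$roi_size, length(x$mask)))
  invisible(x)
}
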