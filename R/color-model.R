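#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# ---- image container ---------------------------------------------------

#' Validate and coerce an RGB image
#'
#' Images are plain integer arrays of dimension H x W x 3, one 8-bit channel
#' per plane, values in \[0, 255\], origin top-left. [read_image()] returns
#' this representation and all quantification functions consume it.
#'
#' @param x A numeric array with `dim(x) = c(H, W, 3)`.
#' @return The validated integer array, invisibly classed `rgb_image`.
#' @export
as_rgb_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L) {
    abort("`x` must be an H x W x 3 array (one 8-bit plane per channel).")
  }
  if (anyNA(x) || min(x) < 0 || max(x) > 255) {
    abort("RGB channel values must lie in [0, 255] with no missing values.")
  }
  storage.mode(x) <- "integer"
  class(x) <- c("rgb_image", class(x))
  x
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d, 8-bit>\n", dim(x)[1], dim(x)[2]))
  invisible(x)
}

# ---- HSB colour space --------------------------------------------------

#' Convert an RGB image to 8-bit hue/saturation/brightness
#'
#' The hue wheel is mapped to 8 bits: the hue angle in degrees is scaled by
#' 255/360 and floored, so pure blue (240 degrees) lands at hue 170. This is
#' the scale on which all threshold ranges in this package are expressed
#' (blue ECM at hue 121-179, the four birefringence bins at hue 1-110).
#' Saturation is `(max - min)/max` scaled to \[0, 255\] and rounded;
#' brightness is the maximum channel. Achromatic pixels get hue 0 and
#' saturation 0 by convention.
#'
#' @param img An RGB image (H x W x 3 array, channels in \[0, 255\]), or an
#'   N x 3 matrix of pixels.
#' @return An array (or matrix) of the same shape with planes h, s, b, each
#'   an integer in \[0, 255\].
#' @examples
#' rgb_to_hsb(array(c(0, 0, 255), c(1, 1, 3)))[1, 1, ]  # blue -> 170 255 255
#' @export
rgb_to_hsb <- function(img) {
  dims <- dim(img)
  if (is.null(dims)) abort("`img` must be an array or matrix, not a vector.")
  if (length(dims) == 3L) {
    if (dims[3] != 3L) abort("`img` must have 3 channels.")
    px <- matrix(as.numeric(img), ncol = 3L)
  } else if (length(dims) == 2L && dims[2] == 3L) {
    px <- matrix(as.numeric(img), ncol = 3L)
  } else {
    abort("`img` must be H x W x 3 or N x 3.")
  }
  r <- px[, 1]; g <- px[, 2]; b <- px[, 3]
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  delta <- mx - mn

  s <- ifelse(mx == 0, 0, round(255 * delta / pmax(mx, 1e-12)))

  # hue sextant; achromatic pixels stay at 0
  h6 <- numeric(length(r))
  chrom <- delta > 0
  if (any(chrom)) {
    d <- delta[chrom]
    rr <- r[chrom]; gg <- g[chrom]; bb <- b[chrom]; m <- mx[chrom]
    h <- numeric(sum(chrom))
    i <- m == rr
    h[i] <- ((gg[i] - bb[i]) / d[i]) %% 6
    i <- m == gg & m != rr
    h[i] <- (bb[i] - rr[i]) / d[i] + 2
    i <- m == bb & m != rr & m != gg
    h[i] <- (rr[i] - gg[i]) / d[i] + 4
    h6[chrom] <- h
  }
  hdeg <- 60 * h6
  h8 <- floor(hdeg * 255 / 360)

  out <- cbind(h8, s, mx)
  storage.mode(out) <- "integer"
  if (length(dims) == 3L) {
    out <- array(out, dim = dims)
  } else {
    colnames(out) <- c("h", "s", "b")
  }
  out
}

#' Convert 8-bit HSB values back to RGB
#'
#' Inverse of [rgb_to_hsb()] up to quantization: hue survives a round trip
#' to within one unit on the 8-bit wheel, and brightness (the max channel)
#' is preserved exactly. Used by the synthetic generators to paint pixels
#' whose HSB classification is known in advance.
#'
#' @param h,s,b Integer vectors in \[0, 255\] (recycled to common length).
#' @return An N x 3 integer matrix of RGB values.
#' @export
hsb_to_rgb <- function(h, s, b) {
  n <- max(length(h), length(s), length(b))
  h <- rep_len(as.numeric(h), n)
  s <- rep_len(as.numeric(s), n) / 255
  v <- rep_len(as.numeric(b), n)
  hdeg <- h * 360 / 255
  c0 <- v * s
  hp <- hdeg / 60
  x <- c0 * (1 - abs(hp %% 2 - 1))
  m <- v - c0
  sext <- floor(hp) %% 6
  r1 <- ifelse(sext == 0 | sext == 5, c0, ifelse(sext == 1 | sext == 4, x, 0))
  g1 <- ifelse(sext == 1 | sext == 2, c0, ifelse(sext == 0 | sext == 3, x, 0))
  b1 <- ifelse(sext == 3 | sext == 4, c0, ifelse(sext == 2 | sext == 5, x, 0))
  out <- round(cbind(r = r1 + m, g = g1 + m, b = b1 + m))
  storage.mode(out) <- "integer"
  out
}

# ---- threshold ranges and hue bins -------------------------------------

#' Construct an inclusive HSB threshold box
#'
#' A threshold range is a box in 8-bit hue/saturation/brightness space with
#' all six bounds inclusive, matching how interactive threshold tools treat
#' their displayed bounds.
#'
#' @param h_lo,h_hi,s_lo,s_hi,b_lo,b_hi Integer bounds in \[0, 255\],
#'   `lo <= hi` on each axis.
#' @return An object of class `hsb_range`.
#' @examples
#' hsb_range(121, 179, 20, 255, 10, 255)  # trichrome blue
#' @export
hsb_range <- function(h_lo, h_hi, s_lo = 0L, s_hi = 255L,
                      b_lo = 0L, b_hi = 255L) {
  v <- c(h_lo = h_lo, h_hi = h_hi, s_lo = s_lo, s_hi = s_hi,
         b_lo = b_lo, b_hi = b_hi)
  if (anyNA(v) || any(v < 0) || any(v > 255)) {
    abort("All HSB bounds must be integers in [0, 255].")
  }
  if (h_lo > h_hi || s_lo > s_hi || b_lo > b_hi) {
    abort("Each HSB axis needs lo <= hi.")
  }
  structure(as.list(as.integer(v)), names = names(v), class = "hsb_range")
}

#' @export
print.hsb_range <- function(x, ...) {
  cat(sprintf("<hsb_range H %d-%d, S %d-%d, B %d-%d>\n",
              x$h_lo, x$h_hi, x$s_lo, x$s_hi, x$b_lo, x$b_hi))
  invisible(x)
}

#' Default birefringence hue bins for Picrosirius red
#'
#' Under circularly polarized light, Picrosirius red birefringence shifts
#' from green (thin fibrils) through yellow and orange to red (thick
#' bundles). The shipped bins on the 8-bit hue wheel are red H 1-13,
#' orange H 14-25, yellow H 26-52 and green H 53-110, each with
#' S 10-255 and B 20-255. Hue 0 and hues above 110 are unclassified.
#'
#' @param red,orange,yellow,green Optional [hsb_range()] overrides.
#' @return A named list of four `hsb_range` objects, classed `hue_bin_set`,
#'   validated for pairwise-disjoint hue intervals.
#' @export
psr_bins <- function(red = hsb_range(1, 13, 10, 255, 20, 255),
                     orange = hsb_range(14, 25, 10, 255, 20, 255),
                     yellow = hsb_range(26, 52, 10, 255, 20, 255),
                     green = hsb_range(53, 110, 10, 255, 20, 255)) {
  bins <- list(red = red, orange = orange, yellow = yellow, green = green)
  ok <- vapply(bins, inherits, logical(1), what = "hsb_range")
  if (!all(ok)) abort("All bins must be hsb_range objects.")
  ivals <- t(vapply(bins, function(r) c(r$h_lo, r$h_hi), numeric(2)))
  o <- order(ivals[, 1])
  if (any(ivals[o, 1][-1] <= ivals[o, 2][-nrow(ivals)])) {
    abort("Hue bins must have pairwise-disjoint hue intervals.")
  }
  structure(bins, class = "hue_bin_set")
}

#' @rdname psr_bins
#' @export
bin_names <- function() c("red", "orange", "yellow", "green")

#' Default blue-ECM threshold for Masson's trichrome
#'
#' Blue coloration (extracellular matrix) is selected at hue 121-179,
#' saturation 20-255, brightness 10-255 on the 8-bit scale.
#'
#' @return An [hsb_range()].
#' @export
mtc_blue_range <- function() hsb_range(121, 179, 20, 255, 10, 255)

# ---- membership and classification -------------------------------------

#' Test HSB pixels against a threshold range
#'
#' @param h,s,b Integer vectors of HSB components (or `h` may be an N x 3
#'   matrix with `s`, `b` missing).
#' @param range An [hsb_range()].
#' @return Logical vector, `TRUE` where all three components fall inside
#'   the (inclusive) box.
#' @export
in_hsb_range <- function(h, s = NULL, b = NULL, range) {
  if (is.matrix(h) && is.null(s)) {
    s <- h[, 2]; b <- h[, 3]; h <- h[, 1]
  }
  h >= range$h_lo & h <= range$h_hi &
    s >= range$s_lo & s <= range$s_hi &
    b >= range$b_lo & b <= range$b_hi
}

#' Classify HSB pixels into birefringence bins
#'
#' @param h,s,b HSB components (or `h` an N x 3 matrix).
#' @param bins A [psr_bins()] bin set.
#' @return A character vector with values `"red"`, `"orange"`, `"yellow"`,
#'   `"green"` or `"unclassified"`. Pixels failing a bin's saturation or
#'   brightness bounds are unclassified even when the hue falls in the bin.
#' @export
classify_hue <- function(h, s = NULL, b = NULL, bins = psr_bins()) {
  if (!inherits(bins, "hue_bin_set")) bins <- do.call(psr_bins, bins)
  if (is.matrix(h) && is.null(s)) {
    s <- h[, 2]; b <- h[, 3]; h <- h[, 1]
  }
  out <- rep("unclassified", length(h))
  for (nm in names(bins)) {
    out[in_hsb_range(h, s, b, bins[[nm]])] <- nm
  }
  out
}

#' Threshold an RGB image against an HSB box
#'
#' @param img An RGB image array.
#' @param range An [hsb_range()].
#' @return An H x W logical mask, `TRUE` where the pixel's HSB value lies
#'   inside the box.
#' @export
threshold_mask <- function(img, range) {
  hsb <- rgb_to_hsb(img)
  d <- dim(hsb)
  px <- matrix(hsb, ncol = 3L)
  matrix(in_hsb_range(px[, 1], px[, 2], px[, 3], range),
         nrow = d[1], ncol = d[2])
}

#' Per-bin masks for an image
#'
#' @param img RGB image array.
#' @param bins A [psr_bins()] bin set.
#' @return Named list of H x W logical masks, one per bin; pairwise
#'   disjoint because the bins are.
#' @export
hue_bin_masks <- function(img, bins = psr_bins()) {
  hsb <- rgb_to_hsb(img)
  d <- dim(hsb)
  px <- matrix(hsb, ncol = 3L)
  lapply(bins, function(r) {
    matrix(in_hsb_range(px[, 1], px[, 2], px[, 3], r), nrow = d[1], ncol = d[2])
  })
}
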