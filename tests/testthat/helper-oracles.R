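# Independent scalar oracles: per-pixel nested loops, no vectorization,
# written separately from the package internals.

# scalar RGB -> 8-bit HSB, one pixel at a time
scalar_hsb <- function(r, g, b) {
  mx <- max(r, g, b); mn <- min(r, g, b); delta <- mx - mn
  v <- mx
  s <- if (mx == 0) 0 else round(255 * delta / mx)
  if (delta == 0) {
    h <- 0
  } else {
    h6 <- if (mx == r) ((g - b) / delta) %% 6
          else if (mx == g) (b - r) / delta + 2
          else (r - g) / delta + 4
    h <- floor(60 * h6 * 255 / 360)
  }
  c(h = h, s = s, b = v)
}

scalar_in_range <- function(hsb, r) {
  hsb[1] >= r$h_lo && hsb[1] <= r$h_hi &&
    hsb[2] >= r$s_lo && hsb[2] <= r$s_hi &&
    hsb[3] >= r$b_lo && hsb[3] <= r$b_hi
}

# nested-loop count of pixels inside an HSB box
oracle_threshold_count <- function(img, range) {
  d <- dim(img)
  n <- 0L
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      hsb <- scalar_hsb(img[i, j, 1], img[i, j, 2], img[i, j, 3])
      if (scalar_in_range(hsb, range)) n <- n + 1L
    }
  }
  n
}

# nested-loop per-bin counts inside an optional mask
oracle_bin_counts <- function(img, bins, mask = NULL) {
  d <- dim(img)
  counts <- stats::setNames(integer(length(bins)), names(bins))
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      if (!is.null(mask) && !mask[i, j]) next
      hsb <- scalar_hsb(img[i, j, 1], img[i, j, 2], img[i, j, 3])
      for (nm in names(bins)) {
        if (scalar_in_range(hsb, bins[[nm]])) {
          counts[nm] <- counts[nm] + 1L
          break
        }
      }
    }
  }
  counts
}

random_rgb_image <- function(h, w) {
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}
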