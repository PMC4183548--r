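# Image file IO (PNG/TIFF via the png and tiff packages) and run
# configuration with the shipped threshold defaults.

#' Read an image or image stack
#'
#' PNG and TIFF are supported. Colour images come back as 8-bit RGB arrays
#' (H x W x 3, values 0-255); an alpha channel is dropped with a warning.
#' Single-page grayscale images come back as an H x W matrix, and
#' multi-page grayscale TIFFs as a Z x H x W array with the stored bit
#' depth (8- or 16-bit) preserved.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return RGB array, matrix, or Z x H x W stack array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("Image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path)
    x <- round(x * 255)
    pages <- list(x)
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    # values come back normalized to [0, 1]; restore the stored bit depth
    pages <- lapply(pages, function(p) {
      bits <- attr(p, "bits.per.sample") %||% 8L
      round(p * (2^bits - 1))
    })
  } else {
    abort(sprintf("Unsupported image format `%s`: %s", ext, path))
  }

  if (length(pages) > 1L) {
    if (any(vapply(pages, function(p) length(dim(p)) == 3L, logical(1)))) {
      abort(sprintf("Multi-page colour TIFF is not supported: %s", path))
    }
    stack <- aperm(simplify2array(pages), c(3, 1, 2))
    storage.mode(stack) <- "integer"
    return(stack)
  }

  x <- pages[[1]]
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] == 4L) {
      warn(sprintf("Dropping alpha channel: %s", path))
      x <- x[, , 1:3, drop = FALSE]
    } else if (dim(x)[3] == 2L) {
      warn(sprintf("Dropping alpha channel of grayscale image: %s", path))
      x <- x[, , 1, drop = TRUE]
    }
  }
  if (length(dim(x)) == 2L) {
    storage.mode(x) <- "integer"
    return(x)
  }
  as_rgb_image(x)
}

#' Write an image or image stack
#'
#' RGB arrays and grayscale matrices are written as 8-bit PNG or TIFF by
#' file extension; Z x H x W stacks as multi-page TIFF (16-bit when any
#' value exceeds 255). Writing is lossless for 8-bit inputs: a write/read
#' round trip returns the original values.
#'
#' @param img RGB array, H x W matrix, or Z x H x W stack.
#' @param path Output path (`.png`, `.tif`, `.tiff`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  d <- dim(img)
  if (length(d) == 3L && d[3] != 3L) {
    # Z x H x W stack -> multi-page TIFF
    if (!ext %in% c("tif", "tiff")) {
      abort("Image stacks must be written as multi-page TIFF.")
    }
    depth <- if (max(img) > 255) 16L else 8L
    scale <- if (depth == 16L) 65535 else 255
    pages <- lapply(seq_len(d[1]), function(z) img[z, , ] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = depth)
    return(invisible(path))
  }
  if (max(img) > 255 || min(img) < 0) abort("8-bit output expects [0, 255].")
  if (ext == "png") {
    png::writePNG(img / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img / 255, path, bits.per.sample = 8L)
  } else {
    abort(sprintf("Unsupported output format `%s`.", ext))
  }
  invisible(path)
}

#' Read a binary ROI mask file
#'
#' Single-channel PNG/TIFF; nonzero pixels are inside the ROI.
#'
#' @param path Mask file path.
#' @return H x W logical matrix.
#' @export
read_mask <- function(path) {
  m <- read_image(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m != 0
}

# ---- configuration -------------------------------------------------------

#' Default run configuration
#'
#' All thresholds ship with the study's printed values: the four
#' birefringence bins, the blue ECM box, near-white exclusion thresholds
#' (brightness >= 230, saturation <= 25), background dark-quantile 0.25.
#'
#' @return Named list (classed `run_config`).
#' @export
default_config <- function() {
  structure(list(
    bins = psr_bins(),
    blue_range = mtc_blue_range(),
    white_cut = 230,
    min_sat = 25,
    dark_quantile = 0.25,
    aggregation = "patient",
    reference_group = NULL,
    seed = 1L
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Unspecified fields keep the [default_config()] values. Bin and blue-range
#' entries are 6-element maps (`h_lo` ... `b_hi`) validated through
#' [hsb_range()]; bin hue intervals must be pairwise disjoint. A template
#' with the shipped defaults is installed at
#' `system.file("extdata", "default-config.yaml", package = "collagenquant")`.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return A `run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$bins)) {
    bins <- lapply(raw$bins, function(b) do.call(hsb_range, b))
    cfg$bins <- do.call(psr_bins, bins[bin_names()])
  }
  if (!is.null(raw$blue_range)) {
    cfg$blue_range <- do.call(hsb_range, raw$blue_range)
  }
  for (nm in c("white_cut", "min_sat", "dark_quantile", "aggregation",
               "reference_group", "seed")) {
    if (!is.null(raw[[nm]])) cfg[[nm]] <- raw[[nm]]
  }
  if (!cfg$aggregation %in% c("patient", "core")) {
    abort("`aggregation` must be \"patient\" or \"core\".")
  }
  cfg
}
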