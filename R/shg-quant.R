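# Second harmonic generation scoring: stacks of optical sections are
# flattened to a maximum-intensity z-projection and scored as mean gray
# intensity.

#' Maximum-intensity z-projection of an image stack
#'
#' @param stack A Z x H x W numeric array of nonnegative intensities
#'   (8- or 16-bit), or a list of H x W matrices.
#' @return An H x W matrix, the elementwise maximum across slices.
#' @export
max_project <- function(stack) {
  if (is.list(stack)) {
    if (length(stack) == 0) abort("Empty stack.")
    stack <- simplify2array(stack)        # H x W x Z
    stack <- aperm(stack, c(3, 1, 2))
  }
  d <- dim(stack)
  if (is.null(d) || length(d) != 3L || d[1] < 1L) {
    abort("`stack` must be a Z x H x W array with Z >= 1.")
  }
  apply(stack, c(2, 3), max)
}

#' Mean gray intensity of a projection
#'
#' @param projection H x W numeric matrix (typically a [max_project()]
#'   output).
#' @param region Optional H x W logical mask restricting scoring; default
#'   the whole field, matching per-core scoring without masking.
#' @return One-row tibble (classed `shg_result`): `mean_gray`, `n_pixels`,
#'   `region` (`"whole"` or `"mask"`).
#' @export
mean_gray <- function(projection, region = NULL) {
  if (!is.matrix(projection)) abort("`projection` must be an H x W matrix.")
  if (is.null(region)) {
    vals <- as.numeric(projection)
    reg <- "whole"
  } else {
    if (!identical(dim(region), dim(projection))) {
      abort("Region mask shape does not match the projection.")
    }
    if (!any(region)) abort("Region mask is empty.")
    vals <- as.numeric(projection[region])
    reg <- "mask"
  }
  out <- tibble(mean_gray = mean(vals), n_pixels = length(vals), region = reg)
  class(out) <- c("shg_result", class(out))
  out
}

#' Score an SHG stack end to end
#'
#' Convenience wrapper: [max_project()] then [mean_gray()].
#'
#' @inheritParams max_project
#' @inheritParams mean_gray
#' @return See [mean_gray()]; adds `n_slices`.
#' @export
quantify_shg <- function(stack, region = NULL) {
  proj <- max_project(stack)
  nz <- if (is.list(stack)) length(stack) else dim(stack)[1]
  mean_gray(proj, region) |> mutate(n_slices = as.integer(nz))
}
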