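# ggplot2 views of the result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_errorbar geom_point
#'   labs position_dodge
#' @export
ggplot2::autoplot

#' Plot per-colour birefringence proportions
#'
#' @param object A `birefringence_result` (one or more stacked rows).
#' @param ... Unused.
#' @return A ggplot bar chart of the four bin proportions.
#' @export
autoplot.birefringence_result <- function(object, ...) {
  long <- object |>
    mutate(.row = dplyr::row_number()) |>
    tidyr::pivot_longer(dplyr::starts_with("prop_"), names_to = "bin",
                        names_prefix = "prop_", values_to = "proportion") |>
    mutate(bin = factor(.data$bin, levels = bin_names()))
  ggplot(long, aes(x = .data$bin, y = .data$proportion)) +
    geom_col(fill = c(red = "#c0392b", orange = "#e67e22",
                      yellow = "#f1c40f", green = "#27ae60")[as.character(long$bin)]) +
    labs(x = "birefringence bin", y = "proportion of birefringent pixels",
         title = "Fibre-thickness colour proportions")
}

#' Plot a group comparison of normalized proportions
#'
#' Mean +/- SEM of the normalized per-colour proportions per group, the
#' reference group pinned at 1.
#'
#' @param object A `tma_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tma_comparison <- function(object, ...) {
  pp <- object$per_patient |>
    tidyr::pivot_longer(dplyr::starts_with("norm_prop_"), names_to = "bin",
                        names_prefix = "norm_prop_", values_to = "norm") |>
    mutate(bin = factor(.data$bin, levels = bin_names())) |>
    group_by(.data$group, .data$bin) |>
    summarise(mean = mean(.data$norm, na.rm = TRUE),
              sem = stats::sd(.data$norm, na.rm = TRUE) /
                sqrt(sum(!is.na(.data$norm))),
              .groups = "drop")
  ggplot(pp, aes(x = .data$bin, y = .data$mean, fill = .data$group)) +
    geom_col(position = position_dodge(0.8), width = 0.7) +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem),
                  position = position_dodge(0.8), width = 0.25) +
    labs(x = "birefringence bin", y = "normalized proportion (reference = 1)",
         title = "Normalized birefringent colour proportions by group")
}

#' Hue histogram of ROI pixels
#'
#' Diagnostic view: distribution of 8-bit hue over ROI pixels passing the
#' bins' saturation/brightness floors, with bin boundaries marked.
#'
#' @param img Polarized RGB image (background-corrected).
#' @param roi Optional ROI (mask or [build_roi()] result).
#' @param bins A [psr_bins()] set.
#' @return A ggplot histogram.
#' @export
plot_hue_histogram <- function(img, roi = NULL, bins = psr_bins()) {
  hsb <- matrix(rgb_to_hsb(img), ncol = 3L)
  mask <- as.vector(roi_mask(roi, dim(img)[1:2]))
  keep <- mask & hsb[, 2] >= bins$red$s_lo & hsb[, 3] >= bins$red$b_lo
  df <- tibble(hue = hsb[keep, 1])
  edges <- unlist(lapply(bins, function(b) c(b$h_lo, b$h_hi)))
  ggplot(df, aes(x = .data$hue)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey40") +
    ggplot2::geom_vline(xintercept = edges, linetype = "dotted",
                        colour = "red3") +
    labs(x = "hue (8-bit wheel)", y = "pixels",
         title = "ROI hue distribution with bin boundaries")
}
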