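# Picrosirius red quantification: per-bin pixel counts inside the ROI,
# total collagen fraction, per-colour proportions, reference-group
# normalization and triplicate averaging.

#' Quantify birefringence of a polarized-light image
#'
#' Counts ROI pixels falling in each birefringence hue bin. Two denominators
#' are reported, both taken directly from the study design: the total
#' collagen fraction divides birefringent pixels by the ROI size, while the
#' per-colour proportions divide each bin count by the total number of
#' birefringent pixels.
#'
#' @param polarized Background-corrected RGB image array.
#' @param roi A [build_roi()] result, an H x W logical mask, or `NULL` to
#'   score the whole frame.
#' @param bins A [psr_bins()] bin set.
#' @return A one-row tibble (classed `birefringence_result`) with columns
#'   `n_red`, `n_orange`, `n_yellow`, `n_green`, `total_positive`,
#'   `roi_size`, `total_fraction` and `prop_red` ... `prop_green`. When no
#'   pixel is birefringent the proportions are `NA` (flagged undefined
#'   rather than 0/0).
#' @export
quantify_birefringence <- function(polarized, roi = NULL, bins = psr_bins()) {
  if (!inherits(bins, "hue_bin_set")) bins <- do.call(psr_bins, bins)
  d <- dim(polarized)[1:2]
  mask <- roi_mask(roi, d)
  roi_size <- sum(mask)
  if (roi_size == 0) abort("ROI is empty: image is unquantifiable.")

  hsb <- matrix(rgb_to_hsb(polarized), ncol = 3L)
  inside <- as.vector(mask)
  lab <- classify_hue(hsb[inside, 1], hsb[inside, 2], hsb[inside, 3], bins)
  counts <- vapply(bin_names(), function(nm) sum(lab == nm), integer(1))
  total_pos <- sum(counts)

  props <- if (total_pos > 0) counts / total_pos else rep(NA_real_, 4)
  out <- tibble(
    n_red = counts[["red"]], n_orange = counts[["orange"]],
    n_yellow = counts[["yellow"]], n_green = counts[["green"]],
    total_positive = total_pos, roi_size = as.integer(roi_size),
    total_fraction = total_pos / roi_size,
    prop_red = props[[1]], prop_orange = props[[2]],
    prop_yellow = props[[3]], prop_green = props[[4]]
  )
  class(out) <- c("birefringence_result", class(out))
  out
}

roi_mask <- function(roi, d) {
  if (is.null(roi)) {
    matrix(TRUE, d[1], d[2])
  } else if (inherits(roi, "roi_spec")) {
    if (!identical(as.integer(dim(roi$mask)), as.integer(d))) {
      abort("ROI mask shape does not match the image.")
    }
    roi$mask
  } else {
    m <- if (is.numeric(roi)) roi != 0 else roi
    if (!identical(as.integer(dim(m)), as.integer(d))) {
      abort("ROI mask shape does not match the image.")
    }
    m
  }
}

#' Average replicate measurements per sample
#'
#' The study scored three representative fields per surgical specimen and
#' analysed the triplicate average. This takes per-image results carrying a
#' sample identifier and returns the unweighted mean of every numeric
#' metric per sample.
#'
#' @param results A tibble of per-image rows (e.g. stacked
#'   [quantify_birefringence()] results) with an identifier column.
#' @param id Name of the identifier column. Default `"patient_id"`.
#' @return A tibble with one row per identifier; numeric columns are
#'   arithmetic means over replicates (`NA` proportions dropped from their
#'   mean), plus `n_replicates`.
#' @export
average_replicates <- function(results, id = "patient_id") {
  if (nrow(results) == 0) abort("No replicate rows supplied.")
  if (!id %in% names(results)) {
    abort(sprintf("Identifier column `%s` not found.", id))
  }
  results |>
    group_by(.data[[id]]) |>
    summarise(
      n_replicates = n(),
      across(where(is.numeric), ~ mean(.x, na.rm = TRUE)),
      across(where(is.character) & !any_of(id), ~ .x[[1]]),
      .groups = "drop"
    ) |>
    mutate(across(where(is.numeric), ~ replace(.x, is.nan(.x), NA_real_)))
}

#' Normalize per-colour proportions to a reference group
#'
#' Each sample's per-bin proportion is divided by the reference group's mean
#' proportion for that bin, so the reference group's normalized mean is
#' exactly 1 per bin (the "1.000 +/- SEM" convention). The reference label
#' is always explicit, never inferred.
#'
#' @param samples Tibble of per-sample results with `prop_*` columns and a
#'   grouping column.
#' @param reference Label of the reference group.
#' @param group Name of the grouping column. Default `"group"`.
#' @param cols Proportion columns to normalize; default the four bins.
#' @return `samples` with added `norm_<col>` columns.
#' @export
normalize_to_reference <- function(samples, reference, group = "group",
                                   cols = paste0("prop_", bin_names())) {
  if (!group %in% names(samples)) {
    abort(sprintf("Grouping column `%s` not found.", group))
  }
  ref_rows <- samples[samples[[group]] == reference, , drop = FALSE]
  if (nrow(ref_rows) == 0) {
    abort(sprintf("Reference group \"%s\" is empty.", reference))
  }
  cols <- intersect(cols, names(samples))
  for (cl in cols) {
    ref_mean <- mean(ref_rows[[cl]], na.rm = TRUE)
    if (!is.finite(ref_mean) || ref_mean == 0) {
      abort(sprintf("Reference mean for `%s` is zero or undefined.", cl))
    }
    samples[[paste0("norm_", cl)]] <- samples[[cl]] / ref_mean
  }
  samples
}
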