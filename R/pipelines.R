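# End-to-end runs: the tissue-microarray group comparison and the clinical
# association table.

#' Run the two-group tissue comparison
#'
#' For every manifest row: read the polarized image (and its brightfield
#' partner or mask file), estimate and subtract the background, build the
#' ROI, quantify birefringence; then average replicates per patient,
#' normalize proportions to the reference group, and compare every metric
#' between the two groups with pooled t-tests.
#'
#' @param manifest Data frame or CSV path with columns `patient_id`,
#'   `group`, `replicate`, `polarized` (file path), and one of
#'   `brightfield` or `mask` (file paths; `mask` wins). A `modality` column,
#'   if present, restricts rows to `"psr"`.
#' @param config A [default_config()]-style list; `reference_group` names
#'   the group whose normalized mean is fixed at 1 (defaults to the first
#'   group in the manifest).
#' @param out_dir Optional directory for tidy CSVs (`per_image.csv`,
#'   `per_patient.csv`, `comparison.csv`) and a `params.yaml` log of every
#'   threshold used.
#' @return List (classed `tma_comparison`): `per_image`, `per_patient`,
#'   `comparison` tibbles, `reference_group`, `errors` (per-file failures;
#'   the run continues past unreadable files).
#' @export
run_tma_comparison <- function(manifest, config = default_config(),
                               out_dir = NULL) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  manifest <- as_tibble(manifest)
  if ("modality" %in% names(manifest)) {
    manifest <- filter(manifest, .data$modality == "psr")
  }
  needed <- c("patient_id", "group", "polarized")
  if (nrow(manifest) == 0 || !all(needed %in% names(manifest))) {
    abort("Manifest must be non-empty with columns patient_id, group, polarized.")
  }
  if (!"replicate" %in% names(manifest)) manifest$replicate <- 1L

  rows <- list(); errors <- list()
  for (k in seq_len(nrow(manifest))) {
    r <- manifest[k, ]
    res <- tryCatch({
      pol <- read_image(r$polarized)
      mask <- NULL; bf <- NULL
      if ("mask" %in% names(manifest) && !is.na(r$mask) && nzchar(r$mask)) {
        mask <- read_mask(r$mask)
      } else if ("brightfield" %in% names(manifest) &&
                 !is.na(r$brightfield) && nzchar(r$brightfield)) {
        bf <- read_image(r$brightfield)
      }
      bg <- estimate_background(pol, dark_quantile = config$dark_quantile)
      pol <- correct_background(pol, bg)
      roi <- build_roi(pol, brightfield = bf, mask = mask,
                       white_cut = config$white_cut, min_sat = config$min_sat)
      q <- quantify_birefringence(pol, roi, bins = config$bins)
      bind_cols(tibble(patient_id = r$patient_id, group = r$group,
                       replicate = r$replicate, file = r$polarized), q)
    }, error = function(e) {
      errors[[length(errors) + 1L]] <<- tibble(file = r$polarized,
                                               error = conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  per_image <- bind_rows(rows)
  if (nrow(per_image) == 0) abort("No manifest row could be quantified.")

  per_patient <- per_image |>
    select(-"file", -"replicate") |>
    average_replicates(id = "patient_id")

  reference <- config$reference_group %||% per_patient$group[[1]]
  per_patient <- normalize_to_reference(per_patient, reference = reference)

  groups <- unique(per_patient$group)
  comparison <- NULL
  if (length(groups) == 2L) {
    other <- setdiff(groups, reference)
    metrics <- c("total_fraction", paste0("norm_prop_", bin_names()))
    comparison <- purrr::map_dfr(metrics, function(m) {
      x <- per_patient[[m]][per_patient$group == other]
      y <- per_patient[[m]][per_patient$group == reference]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      tt <- ttest_pooled(x, y)
      tibble(metric = m,
             mean_ref = mean(y), sem_ref = stats::sd(y) / sqrt(length(y)),
             mean_other = mean(x), sem_other = stats::sd(x) / sqrt(length(x)),
             n_ref = length(y), n_other = length(x),
             t = tt$statistic, df = tt$df, p = tt$p.value)
    })
  }

  out <- structure(
    list(per_image = per_image, per_patient = per_patient,
         comparison = comparison, reference_group = reference,
         errors = bind_rows(errors)),
    class = "tma_comparison"
  )
  if (!is.null(out_dir)) write_comparison(out, out_dir, config)
  out
}

write_comparison <- function(x, out_dir, config) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(x$per_image, file.path(out_dir, "per_image.csv"),
                   row.names = FALSE)
  utils::write.csv(x$per_patient, file.path(out_dir, "per_patient.csv"),
                   row.names = FALSE)
  if (!is.null(x$comparison)) {
    utils::write.csv(x$comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
  }
  log <- list(
    package_version = as.character(utils::packageVersion("collagenquant")),
    reference_group = x$reference_group,
    white_cut = config$white_cut, min_sat = config$min_sat,
    dark_quantile = config$dark_quantile, seed = config$seed,
    bins = lapply(config$bins, function(b) unclass(b)),
    blue_range = unclass(config$blue_range)
  )
  yaml::write_yaml(log, file.path(out_dir, "params.yaml"))
  invisible(out_dir)
}

#' @export
print.tma_comparison <- function(x, ...) {
  cat(sprintf("<tma_comparison: %d images, %d patients, reference \"%s\">\n",
              nrow(x$per_image), nrow(x$per_patient), x$reference_group))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' Run the clinical association table
#'
#' Joins per-patient quantification to a clinical covariate table and runs
#' the univariate battery: one regression per continuous covariate, one
#' pooled t-test per treatment flag, listwise missing-data handling per
#' covariate, no multiplicity adjustment by default.
#'
#' @param quant Data frame or CSV path of per-patient quantification
#'   results (must carry `by` and `metric`).
#' @param clinical Data frame or CSV path of clinical covariates.
#' @param metric Metric column to associate. Default `"total_fraction"`.
#' @param covariates Continuous covariate columns. Defaults to the
#'   standard clinical set present in `clinical`.
#' @param flags Binary flag columns; defaults to the treatment flags
#'   present in `clinical`.
#' @param by Join key. Default `"patient_id"`.
#' @param adjust Passed to [run_association_battery()].
#' @param out_csv Optional path for the results CSV.
#' @return Tibble, one row per covariate/flag (see
#'   [run_association_battery()]).
#' @export
run_clinical_association <- function(quant, clinical,
                                     metric = "total_fraction",
                                     covariates = NULL, flags = NULL,
                                     by = "patient_id",
                                     adjust = c("none", "BH"),
                                     out_csv = NULL) {
  if (is.character(quant)) quant <- utils::read.csv(quant)
  if (is.character(clinical)) clinical <- utils::read.csv(clinical)
  for (nm in c("quant", "clinical")) {
    tab <- get(nm)
    if (!by %in% names(tab)) {
      abort(sprintf("Join key `%s` missing from `%s`.", by, nm))
    }
  }
  joined <- inner_join(as_tibble(quant), as_tibble(clinical), by = by)
  if (nrow(joined) == 0) abort("Join produced zero rows.")
  if (!metric %in% names(joined)) {
    abort(sprintf("Metric column `%s` not found after join.", metric))
  }
  std_cov <- c("age", "psa", "prostate_size", "auasi", "pvr_pre", "pvr_post")
  std_flag <- c("finasteride", "alpha_blocker")
  covariates <- covariates %||% intersect(std_cov, names(joined))
  flags <- flags %||% intersect(std_flag, names(joined))
  res <- run_association_battery(joined, metric = metric,
                                 covariates = covariates, flags = flags,
                                 adjust = match.arg(adjust))
  if (!is.null(out_csv)) utils::write.csv(res, out_csv, row.names = FALSE)
  res
}
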