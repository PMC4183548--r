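# broom-style tidiers for the classed results.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a pooled t-test
#'
#' @param x A `pooled_ttest` from [ttest_pooled()] or [ttest_from_summary()].
#' @param ... Unused.
#' @return One-row tibble: `estimate` (mean difference), `estimate1`,
#'   `estimate2`, `statistic`, `df`, `p.value`, `method`, `degenerate`.
#' @export
tidy.pooled_ttest <- function(x, ...) {
  tibble(
    estimate = unname(x$estimate[1] - x$estimate[2]),
    estimate1 = unname(x$estimate[1]),
    estimate2 = unname(x$estimate[2]),
    statistic = x$statistic,
    df = x$df,
    p.value = x$p.value,
    method = x$method,
    degenerate = x$degenerate
  )
}

#' @rdname tidy.pooled_ttest
#' @export
glance.pooled_ttest <- function(x, ...) tidy(x, ...)

#' Tidy a simple regression result
#'
#' @param x A `linreg_result` from [linreg()].
#' @param ... Unused.
#' @return Tibble in term/estimate form (slope row only).
#' @export
tidy.linreg_result <- function(x, ...) {
  tibble(term = "x", estimate = x$slope, std.error = x$slope_sem,
         statistic = x$slope / x$slope_sem, p.value = x$p)
}

#' @rdname tidy.linreg_result
#' @export
glance.linreg_result <- function(x, ...) {
  tibble(r.squared = x$r2, p.value = x$p, nobs = x$n)
}

#' Tidy a group comparison run
#'
#' @param x A `tma_comparison` from [run_tma_comparison()].
#' @param ... Unused.
#' @return The per-metric comparison tibble.
#' @export
tidy.tma_comparison <- function(x, ...) x$comparison

#' @rdname tidy.tma_comparison
#' @export
glance.tma_comparison <- function(x, ...) {
  tibble(n_images = nrow(x$per_image), n_patients = nrow(x$per_patient),
         n_groups = length(unique(x$per_patient$group)),
         reference = x$reference_group, n_errors = nrow(x$errors))
}
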