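# Group summaries, pooled two-sample t-tests (raw or from printed summary
# statistics) and univariate OLS of collagen metrics on clinical covariates.
# The pooled (equal-variance) form is used throughout: the study reports
# Student's t-tests and its printed p-values are consistent with pooling.
# No multiplicity adjustment by default, matching the reported analyses;
# `adjust = "BH"` is available in run_association_battery().

#' Group summary: n, mean, SEM
#'
#' SEM uses the sample (n - 1) standard deviation. For a single value the
#' SEM is undefined; it is reported as 0 with `sem_defined = FALSE`.
#'
#' @param values Numeric vector (NAs dropped).
#' @return One-row tibble: `n`, `mean`, `sd`, `sem`, `sem_defined`.
#' @export
group_summary <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) abort("No values to summarise.")
  s <- if (n > 1) stats::sd(values) else NA_real_
  tibble(
    n = n,
    mean = mean(values),
    sd = ifelse(is.na(s), 0, s),
    sem = ifelse(is.na(s), 0, s / sqrt(n)),
    sem_defined = n > 1
  )
}

new_ttest_result <- function(t, df, p, estimate1, estimate2, n1, n2,
                             method, degenerate = FALSE) {
  structure(
    list(statistic = t, df = df, p.value = p,
         estimate = c(mean1 = estimate1, mean2 = estimate2),
         n = c(n1 = n1, n2 = n2), method = method, degenerate = degenerate),
    class = "pooled_ttest"
  )
}

#' @export
print.pooled_ttest <- function(x, ...) {
  cat(sprintf("Pooled two-sample t-test (%s)\n", x$method))
  cat(sprintf("  t = %.4f, df = %d, two-sided p = %.4g\n",
              x$statistic, x$df, x$p.value))
  cat(sprintf("  means: %.4g (n=%d) vs %.4g (n=%d)\n",
              x$estimate[1], x$n[1], x$estimate[2], x$n[2]))
  if (x$degenerate) cat("  [degenerate: zero pooled variance]\n")
  invisible(x)
}

pooled_t_core <- function(m1, sd1, n1, m2, sd2, n2, method) {
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (m1 == m2) {
      return(new_ttest_result(0, df, 1, m1, m2, n1, n2, method))
    }
    return(new_ttest_result(sign(m1 - m2) * Inf, df, 0, m1, m2, n1, n2,
                            method, degenerate = TRUE))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  new_ttest_result(t, df, p, m1, m2, n1, n2, method)
}

#' Pooled two-sample t-test on raw values
#'
#' Equal-variance (Student's) two-sample t-test with df = n1 + n2 - 2 and a
#' two-sided p-value. Degenerate inputs (zero pooled variance) give p = 1
#' when the means are equal and p = 0, flagged degenerate, otherwise.
#'
#' @param x,y Numeric vectors (NAs dropped), each of length >= 2.
#' @return A `pooled_ttest` object; see [tidy.pooled_ttest()].
#' @export
ttest_pooled <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("Both groups need at least 2 non-missing values.")
  }
  pooled_t_core(mean(x), stats::sd(x), length(x),
                mean(y), stats::sd(y), length(y), method = "raw values")
}

#' Pooled two-sample t-test from printed summary statistics
#'
#' Reconstructs each group's standard deviation as `sem * sqrt(n)` and runs
#' the pooled test, so published mean/SEM/n triplets can be re-analysed
#' without raw data. On any raw dataset reduced to its summary this agrees
#' with [ttest_pooled()] to machine precision.
#'
#' @param m1,m2 Group means.
#' @param sem1,sem2 Standard errors of the means (>= 0).
#' @param n1,n2 Group sizes (>= 2).
#' @return A `pooled_ttest` object.
#' @examples
#' # SHG collagen score, hyperplasia vs normal tissue: p rounds to 0.02
#' ttest_from_summary(62.52, 2.74, 11, 51.77, 3.49, 10)
#' @export
ttest_from_summary <- function(m1, sem1, n1, m2, sem2, n2) {
  if (n1 < 2 || n2 < 2) abort("Summary t-test needs n >= 2 per group.")
  if (sem1 < 0 || sem2 < 0) abort("SEMs must be nonnegative.")
  pooled_t_core(m1, sem1 * sqrt(n1), n1, m2, sem2 * sqrt(n2), n2,
                method = "summary statistics")
}

#' Simple linear regression of a metric on a covariate
#'
#' Ordinary least squares via [stats::lm()]; reports the slope, its
#' standard error, R-squared and the two-sided p-value for slope != 0
#' (t = slope / se, df = n - 2). Incomplete pairs are dropped listwise.
#'
#' @param x Covariate values.
#' @param y Response (collagen metric) values, same length.
#' @return One-row tibble (classed `linreg_result`): `slope`, `slope_sem`,
#'   `intercept`, `r2`, `p`, `n`.
#' @export
linreg <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("Need at least 3 complete pairs.")
  if (stats::var(x) == 0) abort("Covariate is constant; slope undefined.")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  out <- tibble(
    slope = co["x", "Estimate"],
    slope_sem = co["x", "Std. Error"],
    intercept = co["(Intercept)", "Estimate"],
    r2 = sm$r.squared,
    p = co["x", "Pr(>|t|)"],
    n = length(x)
  )
  class(out) <- c("linreg_result", class(out))
  out
}

#' Univariate association battery
#'
#' For one collagen metric, runs a simple regression against each continuous
#' covariate and a pooled t-test across each binary flag, with listwise
#' missing-data handling per covariate — each row of the output may use a
#' different n, as in retrospective clinical tables.
#'
#' @param records Data frame of per-patient records (metric + covariates).
#' @param metric Name of the metric column.
#' @param covariates Character vector of continuous covariate columns.
#' @param flags Character vector of binary (logical or 0/1) flag columns.
#' @param adjust `"none"` (default, matching the univariate reporting
#'   convention) or `"BH"` for Benjamini-Hochberg across the battery.
#' @return Tibble with one row per covariate/flag: `covariate`, `type`,
#'   `n`, `median`, `iqr_lo`, `iqr_hi`, `slope`, `slope_sem`, `r2`,
#'   `statistic`, `p`, `note`.
#' @export
run_association_battery <- function(records, metric, covariates = character(),
                                    flags = character(), adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!metric %in% names(records)) {
    abort(sprintf("Metric column `%s` not found.", metric))
  }
  y_all <- records[[metric]]

  cont_rows <- purrr::map(covariates, function(cv) {
    if (!cv %in% names(records)) {
      return(assoc_row(cv, "regression", note = "column missing"))
    }
    x <- records[[cv]]
    keep <- !is.na(x) & !is.na(y_all)
    if (sum(keep) < 3 || stats::var(x[keep]) == 0) {
      return(assoc_row(cv, "regression", n = sum(keep),
                       note = "insufficient data"))
    }
    fit <- linreg(x[keep], y_all[keep])
    q <- stats::quantile(x[keep], c(0.25, 0.5, 0.75), names = FALSE)
    assoc_row(cv, "regression", n = fit$n, median = q[2], iqr_lo = q[1],
              iqr_hi = q[3], slope = fit$slope, slope_sem = fit$slope_sem,
              r2 = fit$r2, statistic = fit$slope / fit$slope_sem, p = fit$p)
  })

  flag_rows <- purrr::map(flags, function(fl) {
    if (!fl %in% names(records)) {
      return(assoc_row(fl, "t-test", note = "column missing"))
    }
    f <- as.logical(records[[fl]])
    keep <- !is.na(f) & !is.na(y_all)
    y1 <- y_all[keep & f]; y0 <- y_all[keep & !f]
    if (length(y1) < 2 || length(y0) < 2) {
      return(assoc_row(fl, "t-test", n = sum(keep),
                       note = "insufficient data"))
    }
    tt <- ttest_pooled(y1, y0)
    assoc_row(fl, "t-test", n = sum(keep), statistic = tt$statistic,
              p = tt$p.value)
  })

  out <- bind_rows(cont_rows, flag_rows)
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
  }
  out
}

assoc_row <- function(covariate, type, n = NA_integer_, median = NA_real_,
                      iqr_lo = NA_real_, iqr_hi = NA_real_, slope = NA_real_,
                      slope_sem = NA_real_, r2 = NA_real_,
                      statistic = NA_real_, p = NA_real_, note = NA_character_) {
  tibble(covariate = covariate, type = type, n = as.integer(n),
         median = median, iqr_lo = iqr_lo, iqr_hi = iqr_hi, slope = slope,
         slope_sem = slope_sem, r2 = r2, statistic = statistic, p = p,
         note = note)
}
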