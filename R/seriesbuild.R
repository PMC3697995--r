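#' Build monthly mortality series from a cohort
#'
#' Aggregates patient records into one monthly series per site. For
#' `kind = "raw"` the monthly value is the mean of `died`; for
#' `kind = "expected"` it is the mean of `p_expected`, and the within-month
#' standard error of that mean (SD of patient-level `p_expected` divided by
#' \eqn{\sqrt{n_t}}) is stored in the `se` column for use as a reference
#' process by [reference_3se_chart()]. Months with no patients are masked as
#' missing.
#'
#' @param cohort a cohort data frame; `p_expected` required for expected kind.
#' @param kind `"raw"` or `"expected"`.
#' @param n_months series length; defaults to the cohort config's `n_months`
#'   or `max(month_index) + 1`.
#' @return A named list of [mortality_series()], one per site.
#' @export
build_monthly_series <- function(cohort, kind = c("raw", "expected"),
                                 n_months = NULL) {
  kind <- match.arg(kind)
  if (kind == "expected" && is.null(cohort$p_expected))
    stop_param("expected series requested but cohort lacks p_expected")
  if (is.null(n_months)) {
    cfg <- attr(cohort, "config")
    n_months <- if (!is.null(cfg)) cfg$n_months else max(cohort$month_index) + 1L
  }
  v <- if (kind == "raw") cohort$died else cohort$p_expected
  months <- 0:(n_months - 1)
  out <- lapply(split(seq_len(nrow(cohort)), factor(cohort$site_id)), function(ix) {
    mi <- cohort$month_index[ix]
    f <- factor(mi, levels = months)
    n_t <- as.integer(table(f))
    val <- as.numeric(tapply(v[ix], f, mean))
    se <- NULL
    if (kind == "expected") {
      se <- as.numeric(tapply(v[ix], f, stats::sd)) / sqrt(n_t)
      se[n_t == 0] <- NA_real_
    }
    val[n_t == 0] <- NA_real_
    mortality_series(val, month_index = months, kind = kind,
                     site_id = as.character(cohort$site_id[ix[1]]),
                     n_patients = n_t, se = se)
  })
  out
}

#' Eligibility screening of a monthly series
#'
#' Applies the continuity screens used to decide whether a site's series
#' supports lag-based analysis: (i) a gapless run long enough to assess
#' autocorrelation to `lag` — for raw series months with zero mortality are
#' excluded alongside missing months, since a zero month breaks the
#' log-odds/ratio interpretation of a raw rate; (ii) a gapless run (missing
#' months only excluded) of at least `min_months` for seasonal assessment.
#' Continuity is assessed from the series start forward: the run used is the
#' maximal eligible run beginning at the first eligible month. A Ljung–Box
#' portmanteau test at the stated lag is run on that run when it is long
#' enough.
#'
#' @param series a [mortality_series()].
#' @param lag autocorrelation horizon for the first screen (default 40).
#' @param min_months minimum run length for the second screen (default 72).
#' @param alpha significance level for the Q test.
#' @return An `eligibility_report` list: `continuous_to_lag40`,
#'   `continuous_72_months`, `n_continuous`, `q_test_significant_lag40`,
#'   and the `q_test` result (or `NULL` when the run is too short).
#' @export
screen_eligibility <- function(series, lag = 40L, min_months = 72L,
                               alpha = 0.05) {
  stopifnot(inherits(series, "mortality_series"))
  lag <- check_positive_int(lag, "lag")
  min_months <- check_positive_int(min_months, "min_months")
  is_raw <- unclass(series)$kind == "raw"
  run_lag <- continuity_run(series, exclude_zero = is_raw)
  run_all <- continuity_run(series, exclude_zero = FALSE)
  n_cont <- length(run_lag)
  to_lag <- n_cont >= lag + 1L
  q <- NULL
  q_sig <- NA
  if (to_lag) {
    vals <- as.data.frame(series)$value[run_lag]
    q <- ljung_box_q(vals, h = lag)
    q_sig <- q$p_value < alpha
  }
  structure(list(continuous_to_lag40 = to_lag,
                 continuous_72_months = length(run_all) >= min_months,
                 n_continuous = n_cont,
                 q_test_significant_lag40 = q_sig,
                 q_test = q, lag = lag, min_months = min_months),
            class = "eligibility_report")
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat(sprintf("<eligibility_report> run length %d; lag-%d assessable: %s; >= %d months: %s\n",
              x$n_continuous, x$lag, x$continuous_to_lag40, x$min_months,
              x$continuous_72_months))
  if (!is.na(x$q_test_significant_lag40))
    cat(sprintf("  Q(lag %d) significant at 0.05: %s\n", x$lag,
                x$q_test_significant_lag40))
  invisible(x)
}
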