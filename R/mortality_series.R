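#' Monthly mortality series
#'
#' Container for a monthly series at one site: the object every diagnostic,
#' model and chart in the package consumes. Month indices are 0-based.
#'
#' @param value numeric vector of monthly values (`NA` for missing months).
#' @param month_index integer vector of 0-based month indices; defaults to
#'   `0:(length(value) - 1)`.
#' @param kind one of `"raw"`, `"expected"`, `"residual"`, `"detrended"`.
#'   Raw and expected values must lie in `[0, 1]`.
#' @param site_id site identifier.
#' @param n_patients optional integer vector of monthly patient counts.
#' @param se optional numeric vector of monthly standard errors (used by
#'   [reference_3se_chart()] for expected series).
#'
#' @return An object of class `mortality_series`: a list with a `data.frame`
#'   component `$data` (columns `month_index`, `value`, `n_patients`,
#'   `missing`, and `se` when supplied), plus `kind` and `site_id`. `$value`,
#'   `$month_index` etc. are accessible directly via `$`.
#' @export
mortality_series <- function(value, month_index = seq_along(value) - 1L,
                             kind = c("raw", "expected", "residual", "detrended"),
                             site_id = "site", n_patients = NULL, se = NULL) {
  kind <- match.arg(kind)
  value <- as.numeric(value)
  month_index <- as.integer(month_index)
  if (length(month_index) != length(value))
    stop_param("month_index and value must have equal length")
  missing_mask <- is.na(value)
  if (kind %in% c("raw", "expected")) {
    ok <- missing_mask | (value >= 0 & value <= 1)
    if (!all(ok)) stop_param(kind, " series values must lie in [0, 1]")
  }
  if (is.null(n_patients)) n_patients <- rep(NA_integer_, length(value))
  d <- data.frame(month_index = month_index, value = value,
                  n_patients = as.integer(n_patients), missing = missing_mask)
  if (!is.null(se)) d$se <- as.numeric(se)
  structure(list(data = d, kind = kind, site_id = site_id),
            class = "mortality_series")
}

#' @export
`$.mortality_series` <- function(x, name) {
  if (name %in% names(unclass(x))) return(unclass(x)[[name]])
  unclass(x)$data[[name]]
}

#' @export
length.mortality_series <- function(x) nrow(unclass(x)$data)

#' @export
as.data.frame.mortality_series <- function(x, ...) unclass(x)$data

#' @export
print.mortality_series <- function(x, ...) {
  d <- unclass(x)$data
  cat(sprintf("<mortality_series> site %s, kind '%s', %d months (%d missing)\n",
              unclass(x)$site_id, unclass(x)$kind, nrow(d), sum(d$missing)))
  if (any(!d$missing))
    cat(sprintf("  mean %.4f, sd %.4f over observed months\n",
                mean(d$value, na.rm = TRUE), stats::sd(d$value, na.rm = TRUE)))
  invisible(x)
}

# gapless run of "continuous" months under the screening rule, assessed from
# the series start forward: the maximal valid run that begins at the first
# valid month. Returns integer positions into the series.
continuity_run <- function(series, exclude_zero) {
  valid_runs(series, exclude_zero, which = "first")
}

# longest valid run, used when extracting the analysis sample for modelling
longest_run <- function(series, exclude_zero) {
  valid_runs(series, exclude_zero, which = "longest")
}

valid_runs <- function(series, exclude_zero, which) {
  d <- as.data.frame(series)
  valid <- !d$missing
  if (exclude_zero) valid <- valid & (d$value != 0)
  if (!any(valid)) return(integer(0))
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  pick <- if (which == "first") runs[1] else runs[which.max(r$lengths[runs])]
  seq.int(starts[pick], ends[pick])
}
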