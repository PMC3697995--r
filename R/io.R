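#' Read and write cohort tables
#'
#' Cohorts are exchanged as plain CSV with header
#' `site_id,month_index,severity,died[,p_expected]`.
#'
#' @param cohort a cohort data frame.
#' @param path file path.
#' @return `read_cohort()` returns a cohort data frame; `write_cohort()`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c("site_id", "month_index", "severity", "died")
  if (!is.null(cohort$p_expected)) cols <- c(cols, "p_expected")
  utils::write.csv(as.data.frame(cohort)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path)
  need <- c("site_id", "month_index", "severity", "died")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop_param("cohort file lacks column(s): ",
                               paste(miss, collapse = ", "))
  d$site_id <- factor(d$site_id)
  d$month_index <- as.integer(d$month_index)
  class(d) <- c("cohort", "data.frame")
  d
}

#' Read and write monthly series
#'
#' Series CSV layout: `site_id,kind,month_index,value,n_patients,missing`
#' (plus `se` when present); missing months carry an empty value and
#' `missing = TRUE`.
#'
#' @param series a [mortality_series()].
#' @param path file path.
#' @return `read_series()` returns a [mortality_series()].
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "mortality_series"))
  d <- as.data.frame(series)
  out <- data.frame(site_id = unclass(series)$site_id,
                    kind = unclass(series)$kind, d)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  d <- utils::read.csv(path)
  need <- c("site_id", "kind", "month_index", "value", "missing")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop_param("series file lacks column(s): ",
                               paste(miss, collapse = ", "))
  mortality_series(d$value, month_index = d$month_index, kind = d$kind[1],
                   site_id = as.character(d$site_id[1]),
                   n_patients = if ("n_patients" %in% names(d)) d$n_patients,
                   se = if ("se" %in% names(d)) d$se)
}

#' Export a control chart as tidy CSV
#'
#' Columns: `month_index,monitored,centerline,lcl,ucl,signal`.
#'
#' @param chart an `ewma_chart`.
#' @param path file path.
#' @export
write_chart <- function(chart, path) {
  stopifnot(inherits(chart, "ewma_chart"))
  d <- chart$data
  utils::write.csv(data.frame(month_index = d$month_index,
                              monitored = d$monitored, centerline = d$center,
                              lcl = d$lcl, ucl = d$ucl, signal = d$signal),
                   path, row.names = FALSE)
  invisible(path)
}

#' Serialise a risk model to flat JSON
#'
#' Writes the fixed effects, random-effect covariance, severity centring
#' constant and site-level predicted deviations as a JSON document.
#'
#' @param model a `risk_model`.
#' @param path file path.
#' @return `read_risk_model()` rebuilds a prediction-capable `risk_model`
#'   (without the original fitted object).
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  doc <- list(fixed_intercept = model$fixed_intercept,
              fixed_slope = model$fixed_slope,
              random_covariance = as.numeric(model$random_covariance),
              severity_center = model$severity_center,
              loglik = model$loglik, converged = model$converged,
              fallback_glm = model$fallback_glm,
              site_effects = model$site_effects)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$random_covariance <- matrix(doc$random_covariance, 2, 2)
  doc$fit <- NULL
  class(doc) <- "risk_model"
  doc
}

#' Read and write flat key-value configuration files
#'
#' Configurations (cohort, series, pipeline) round-trip through YAML.
#'
#' @param config a named list / config object.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  cls <- class(config)
  yaml::write_yaml(c(unclass(config), list(.class = cls[1])), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  cls <- doc$.class
  doc$.class <- NULL
  # YAML reads empty sequences back as empty lists; flatten vector fields
  vecs <- c("ar_lags", "ar_coefs", "ma_lags", "ma_coefs", "arch_coefs",
            "garch_coefs", "month_effects")
  for (v in intersect(vecs, names(doc))) {
    doc[[v]] <- if (length(doc[[v]])) unlist(doc[[v]]) else numeric(0)
    if (v == "month_effects" && !length(doc[[v]])) doc[[v]] <- NULL
  }
  if (identical(cls, "cohort_config")) do.call(cohort_config, doc)
  else if (identical(cls, "series_spec"))
    do.call(series_spec, doc[setdiff(names(doc),
                                     c("stationary_ar", "variance_stationary"))])
  else doc
}
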