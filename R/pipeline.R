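#' Configuration of the end-to-end exemplar pipeline
#'
#' Bundles the stage parameters of [run_exemplar()]: the synthetic cohort,
#' the diagnostic horizons, the time-series orders, the chart settings and
#' the run-length design scenarios. The default cohort is a reduced-scale
#' panel (fewer, smaller sites) so the full workflow runs in seconds while
#' preserving the series structure the analysis targets.
#'
#' @param cohort a [cohort_config()] for the synthetic panel.
#' @param exemplar_site site whose series is taken through the full
#'   time-series workflow; `NULL` picks the site with most patients.
#' @param q_lag autocorrelation screening horizon (months).
#' @param min_months seasonal screening horizon (months).
#' @param arma_ar_lags,arma_ma_lags sparse mean-model lags for the raw-series
#'   fit.
#' @param garch_m,garch_k variance-equation orders.
#' @param scenario_pcts percentage increments designed for.
#' @param arl0 in-control ARL for the scenario designs.
#' @param design_lambda_grid lambda grid for the scenario designs.
#' @param seed master seed recorded in all outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(n_sites = 8,
                                                   patients_per_site_mean = 4500,
                                                   n_months = 120,
                                                   seed = 20),
                            exemplar_site = NULL,
                            q_lag = 40, min_months = 72,
                            arma_ar_lags = 1, arma_ma_lags = integer(0),
                            garch_m = 1, garch_k = 1,
                            scenario_pcts = c(0.05, 0.10), arl0 = 370,
                            design_lambda_grid = seq(0.01, 1, by = 0.01),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the exemplar monitoring pipeline on synthetic data
#'
#' Executes the full workflow on one generated panel: cohort simulation,
#' random-coefficient risk adjustment, monthly raw/expected series
#' construction, eligibility screening, distributional and autocorrelation
#' diagnostics, seasonal decomposition, linear detrending, sparse-lag ARMA
#' and GARCH fitting with white-noise residual checks, the full family of
#' control charts (risk-adjusted reference, fixed/time-varying EWMA,
#' moving centre-line, residual-EWMA, one-step forecast-error), and the
#' ARL-based scenario designs. Deterministic under a fixed seed.
#'
#' @param config a [pipeline_config()].
#' @return A named list (`bundle`) with components `cohort`, `risk_model`,
#'   `calibration`, `raw_series`, `expected_series`, `eligibility`,
#'   `diagnostics`, `decomposition`, `trend`, `arma_fit`, `garch_fit`,
#'   `residual_checks`, `charts`, `designs`, `seed` and `warnings`.
#' @export
run_exemplar <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  warn <- character(0)
  note <- function(w) warn <<- c(warn, conditionMessage(w))
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      note(w); invokeRestart("muffleWarning")
    }), error = function(e) stop("stage '", name, "' failed: ",
                                 conditionMessage(e), call. = FALSE))
  }

  cohort <- stage("synth", generate_cohort(config$cohort))
  model <- stage("riskadj", fit_risk_model(cohort))
  cohort <- stage("riskadj", predict_expected(model, cohort))
  calib <- stage("riskadj", calibration_discrimination(cohort))

  raw_all <- stage("seriesbuild", build_monthly_series(cohort, "raw"))
  exp_all <- stage("seriesbuild", build_monthly_series(cohort, "expected"))
  site <- config$exemplar_site
  if (is.null(site)) {
    counts <- table(cohort$site_id)
    site <- names(counts)[which.max(counts)]
  }
  raw <- raw_all[[site]]
  expd <- exp_all[[site]]
  elig <- stage("seriesbuild", screen_eligibility(raw, lag = config$q_lag,
                                                  min_months = config$min_months))

  run <- longest_run(raw, exclude_zero = TRUE)
  x <- as.data.frame(raw)$value[run]
  diag <- stage("diagnostics", list(
    moments = moments_normality(x),
    correlogram = correlogram(x, max_lag = min(config$q_lag, length(x) - 1)),
    q_test = ljung_box_q(x, h = min(config$q_lag, length(x) - 2)),
    cpgram = cumulative_periodogram_test(x),
    adf_trend = adf_test(x, include_trend = TRUE, n_lags = 2),
    lag_pairs = lag_plot_data(x, max_lag = 12)))
  dc <- stage("diagnostics", classical_decompose(x))

  tr <- stage("tsmodel", detrend_linear(x))
  det <- tr$residual_series$value
  af <- stage("tsmodel", fit_arma(det, ar_lags = config$arma_ar_lags,
                                  ma_lags = config$arma_ma_lags,
                                  seasonal_ar = 1))
  arch <- stage("tsmodel", arch_effects_test(af$residuals, h = 5))
  gf <- stage("tsmodel", fit_garch(det, ar_lags = config$arma_ar_lags,
                                   m = config$garch_m, k = config$garch_k))
  resid_checks <- stage("tsmodel", list(
    arma_lb = ljung_box_q(af$residuals, h = 20,
                          fitdf = length(af$ar) + length(af$ma) + length(af$sar)),
    garch_lb = ljung_box_q(gf$std_residuals, h = 20,
                           fitdf = length(config$arma_ar_lags)),
    garch_wald = tryCatch(joint_wald(gf), error = function(e) NULL)))

  charts <- stage("charts", list(
    reference = reference_3se_chart(
      mortality_series(as.data.frame(raw)$value[run],
                       month_index = as.data.frame(raw)$month_index[run],
                       kind = "raw", n_patients = as.data.frame(raw)$n_patients[run]),
      mortality_series(as.data.frame(expd)$value[run],
                       month_index = as.data.frame(expd)$month_index[run],
                       kind = "expected",
                       n_patients = as.data.frame(expd)$n_patients[run],
                       se = as.data.frame(expd)$se[run])),
    ewma_fixed = ewma_chart(x, target = mean(x), sigma_x = stats::sd(x),
                            lambda = 0.05),
    ewma_tv = ewma_chart(x, target = mean(x), sigma_x = stats::sd(x),
                         lambda = 0.05, time_varying = TRUE),
    moving_cl = moving_centerline_chart(x),
    residual_ewma = residual_ewma_chart(gf$std_residuals),
    forecast_error = forecast_error_chart(gf)))

  designs <- stage("arl", lapply(config$scenario_pcts, function(pct) {
    scenario_design(mean = mean(expd$value, na.rm = TRUE),
                    sd = stats::sd(expd$value, na.rm = TRUE),
                    pct_increment = pct, arl0 = config$arl0,
                    lambda_grid = config$design_lambda_grid)
  }))
  names(designs) <- paste0("pct", 100 * config$scenario_pcts)

  list(cohort = cohort, risk_model = model, calibration = calib,
       raw_series = raw, expected_series = expd, eligibility = elig,
       diagnostics = diag, decomposition = dc, trend = tr,
       arma_fit = af, arch_test = arch, garch_fit = gf,
       residual_checks = resid_checks, charts = charts, designs = designs,
       exemplar_site = site, seed = config$seed, warnings = warn)
}

#' Render the bundle's charts to image files
#'
#' One PNG per chart, drawn with the package's colour convention (navy
#' monitored line, red upper and green lower control limits).
#'
#' @param bundle a [run_exemplar()] result.
#' @param output_dir directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
render_charts <- function(bundle, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(bundle$charts)) {
    ch <- bundle$charts[[nm]]
    if (!nrow(ch$data)) { warning("chart '", nm, "' empty, skipped"); next }
    p <- file.path(output_dir, paste0(nm, ".png"))
    grDevices::png(p, width = 900, height = 480)
    plot(ch, main = nm)
    grDevices::dev.off()
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @export
plot.ewma_chart <- function(x, main = NULL, ...) {
  d <- x$data
  ylim <- range(c(d$monitored, d$lcl, d$ucl, d$x), na.rm = TRUE)
  graphics::plot(d$month_index, d$monitored, type = "l", col = "navy",
                 lwd = 2, xlab = "month", ylab = "monitored value",
                 ylim = ylim, main = if (is.null(main)) x$limit_mode else main,
                 ...)
  graphics::lines(d$month_index, d$ucl, col = "red")
  graphics::lines(d$month_index, d$lcl, col = "green4")
  graphics::lines(d$month_index, d$center, col = "grey40", lty = 2)
  if (any(d$signal, na.rm = TRUE))
    graphics::points(d$month_index[d$signal], d$monitored[d$signal],
                     pch = 19, col = "red")
  invisible(x)
}

#' @export
plot.decomposition <- function(x, ...) {
  d <- x$table
  op <- graphics::par(mfrow = c(4, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (col in c("observed", "trend", "seasonal", "remainder"))
    graphics::plot(d$month_index, d[[col]], type = "l", ylab = col, xlab = "")
  invisible(x)
}

#' @export
plot.correlogram <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  for (col in c("acf", "pacf")) {
    graphics::plot(x$table$lag, x$table[[col]], type = "h", ylim = c(-1, 1),
                   xlab = "lag", ylab = col)
    graphics::abline(h = c(-1, 1) * x$ci_bound, lty = 2, col = "blue")
    graphics::abline(h = 0)
  }
  invisible(x)
}
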