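#' EWMA smoothing
#'
#' The exponentially weighted moving average recursion
#' \eqn{z_i = \lambda x_i + (1-\lambda) z_{i-1}} with starting value `z0`.
#'
#' @param x numeric vector.
#' @param lambda smoothing constant in (0, 1].
#' @param z0 starting value (default `x[1]`).
#' @return Numeric vector of smoothed values, same length as `x`.
#' @export
ewma_smooth <- function(x, lambda, z0 = x[1]) {
  check_prob_open(lambda, "lambda")
  x <- as.numeric(x)
  if (!length(x)) stop_param("empty series")
  as.numeric(stats::filter(lambda * x, 1 - lambda, method = "recursive",
                           init = z0))
}

#' EWMA variance at observation i
#'
#' \eqn{\sigma^2_{z_i} = \sigma_x^2 \frac{\lambda}{2-\lambda}
#' (1 - (1-\lambda)^{2i})}, nondecreasing in `i` with asymptote
#' \eqn{\sigma_x^2 \lambda/(2-\lambda)}.
#'
#' @param sigma_x process standard deviation.
#' @param lambda smoothing constant in (0, 1].
#' @param i observation index (>= 1), possibly vectorised.
#' @return Variance of the EWMA statistic at each `i`.
#' @export
ewma_variance <- function(sigma_x, lambda, i) {
  check_prob_open(lambda, "lambda")
  if (any(i < 1)) stop_param("i must be >= 1")
  sigma_x^2 * lambda / (2 - lambda) * (1 - (1 - lambda)^(2 * i))
}

new_ewma_chart <- function(data, lambda, L, limit_mode, sigma_x = NA,
                           target = NA, z0 = NA, extra = list()) {
  structure(c(list(data = data, lambda = lambda, L = L,
                   limit_mode = limit_mode, sigma_x = sigma_x,
                   target = target, z0 = z0), extra),
            class = "ewma_chart")
}

#' @export
print.ewma_chart <- function(x, ...) {
  d <- x$data
  cat(sprintf("<ewma_chart> mode '%s', lambda %.4g, L %.3g; %d points, %d signal(s)\n",
              x$limit_mode, x$lambda, x$L, nrow(d), sum(d$signal, na.rm = TRUE)))
  invisible(x)
}

#' Standard EWMA control chart
#'
#' Smooths `x` with [ewma_smooth()] starting at `z0` (the target by default)
#' and flags signals where the smoothed statistic leaves
#' `target +/- L * sigma_z`. With `time_varying = TRUE` the limits use the
#' exact variance [ewma_variance()] at each `i` (narrower early on); otherwise
#' the asymptotic variance is used throughout.
#'
#' @param x monitored observations.
#' @param target process target (centre line).
#' @param sigma_x in-control process SD.
#' @param lambda smoothing constant in (0, 1].
#' @param L limit width in sigma units (default 3).
#' @param time_varying use time-varying limits.
#' @param z0 EWMA starting value.
#' @return An `ewma_chart` whose `$data` has columns `month_index`, `x`,
#'   `monitored` (the EWMA), `center`, `lcl`, `ucl`, `signal`.
#' @export
ewma_chart <- function(x, target, sigma_x, lambda, L = 3,
                       time_varying = FALSE, z0 = target) {
  if (!length(x)) stop_param("empty series")
  if (sigma_x <= 0) stop_param("sigma_x must be positive")
  check_prob_open(lambda, "lambda")
  x <- as.numeric(x)
  z <- ewma_smooth(x, lambda, z0)
  i <- seq_along(x)
  sig_z <- if (time_varying) sqrt(ewma_variance(sigma_x, lambda, i))
           else rep(sigma_x * sqrt(lambda / (2 - lambda)), length(x))
  d <- data.frame(month_index = i - 1L, x = x, monitored = z,
                  center = target, lcl = target - L * sig_z,
                  ucl = target + L * sig_z)
  d$signal <- d$monitored < d$lcl | d$monitored > d$ucl
  new_ewma_chart(d, lambda, L,
                 if (time_varying) "time_varying" else "fixed",
                 sigma_x, target, z0)
}

#' In-sample SSE-optimal smoothing constant
#'
#' Chooses \eqn{\lambda} minimising the sum of squared one-step prediction
#' errors \eqn{\sum_i (x_i - z_{i-1})^2} over a grid, the standard "optimal
#' exponential coefficient" default. The EWMA is started at the sample mean
#' and the first few (10, or n/4 if shorter) prediction errors are discarded
#' as warm-up, so the start-up transient does not dominate the criterion;
#' ties go to the smallest \eqn{\lambda} (favouring smoothing).
#'
#' @param x numeric vector, n >= 10.
#' @param grid candidate lambdas in (0, 1].
#' @return List with `lambda` (the minimiser), `sse`, and the full `profile`
#'   data frame.
#' @export
optimize_lambda_sse <- function(x, grid = seq(0.01, 1, by = 0.01)) {
  x <- as.numeric(x)
  if (length(x) < 10) stop_param("need n >= 10 to choose lambda")
  if (!length(grid)) stop_param("empty lambda grid")
  if (any(grid <= 0 | grid > 1)) stop_param("grid values must lie in (0, 1]")
  grid <- sort(grid)
  warmup <- min(10L, length(x) %/% 4L)
  sse <- vapply(grid, function(lam) {
    z <- ewma_smooth(x, lam, z0 = mean(x))
    e <- x[-1] - z[-length(x)]
    sum(e[(warmup + 1L):length(e)]^2)
  }, numeric(1))
  best <- which.min(sse)  # first minimum = smallest lambda on ties
  list(lambda = grid[best], sse = sse[best],
       profile = data.frame(lambda = grid, sse = sse))
}

#' Moving centre-line EWMA chart for autocorrelated data
#'
#' The centre line at `t` is the one-step EWMA prediction \eqn{z_{t-1}}, so
#' the chart adapts to autocorrelation; the prediction-error variance is
#' estimated by the mean squared one-step prediction error (warm-up errors
#' discarded, as in [optimize_lambda_sse()]) and the observations themselves
#' are monitored against `centerline +/- L * sigma_pred`.
#'
#' @param x monitored observations, n >= 10.
#' @param lambda smoothing constant; chosen by [optimize_lambda_sse()] when
#'   `NULL`.
#' @param L limit width (default 3).
#' @return An `ewma_chart` with `limit_mode = "moving_centerline"`; degenerate
#'   (zero prediction error) inputs are flagged via the `degenerate` field.
#' @export
moving_centerline_chart <- function(x, lambda = NULL, L = 3) {
  x <- as.numeric(x)
  if (length(x) < 10) stop_param("need n >= 10")
  if (is.null(lambda)) lambda <- optimize_lambda_sse(x)$lambda
  check_prob_open(lambda, "lambda")
  z <- ewma_smooth(x, lambda, z0 = mean(x))
  center <- c(mean(x), z[-length(x)])   # prediction of x_t given info to t-1
  warmup <- min(10L, length(x) %/% 4L)
  e <- (x[-1] - z[-length(x)])[-seq_len(warmup)]
  sse <- sum(e^2)
  s_pred <- sqrt(sse / length(e))
  degenerate <- s_pred < .Machine$double.eps^0.5
  if (degenerate) warning("constant series: zero prediction error, limits degenerate")
  d <- data.frame(month_index = seq_along(x) - 1L, x = x, monitored = x,
                  center = center, lcl = center - L * s_pred,
                  ucl = center + L * s_pred)
  d$signal <- d$monitored < d$lcl | d$monitored > d$ucl
  new_ewma_chart(d, lambda, L, "moving_centerline", sigma_x = s_pred,
                 target = mean(x), z0 = mean(x),
                 extra = list(degenerate = degenerate, sse = sse))
}

#' Risk-adjusted reference chart (3 SE of the expected series)
#'
#' Monitors the raw mortality series against control limits placed around
#' the expected (risk-adjusted) series:
#' `expected_t +/- L * SE_t`. By default `SE_t` is the monthly standard error
#' of the mean predicted probability (SD of patient-level `p_expected`
#' divided by \eqn{\sqrt{n_t}}, as stored by [build_monthly_series()]);
#' `se_mode = "series_sd"` instead uses the overall SD of the expected series
#' for every month. The raw series may optionally be EWMA-smoothed before
#' comparison.
#'
#' @param raw raw [mortality_series()].
#' @param expected expected [mortality_series()] aligned on month index.
#' @param L limit width in SE units (default 3).
#' @param se_mode `"monthly"` or `"series_sd"`.
#' @param smooth_lambda optional smoothing constant applied to the raw series
#'   before comparison.
#' @return An `ewma_chart` with `limit_mode = "reference_3se"`.
#' @export
reference_3se_chart <- function(raw, expected, L = 3,
                                se_mode = c("monthly", "series_sd"),
                                smooth_lambda = NULL) {
  se_mode <- match.arg(se_mode)
  dr <- as.data.frame(raw)
  de <- as.data.frame(expected)
  mm <- merge(dr[, c("month_index", "value", "missing")],
              de, by = "month_index", suffixes = c("_raw", "_exp"))
  if (any(mm$missing_raw | mm$missing_exp))
    stop_param("missing months in the analysed run; screen/subset first")
  se <- if (se_mode == "monthly") {
    if (is.null(mm$se) || anyNA(mm$se))
      stop_param("expected series lacks monthly se; build it from a cohort ",
                 "with build_monthly_series or use se_mode = 'series_sd'")
    mm$se
  } else rep(stats::sd(mm$value_exp), nrow(mm))
  lam <- if (is.null(smooth_lambda)) 1 else check_prob_open(smooth_lambda, "smooth_lambda")
  mon <- if (is.null(smooth_lambda)) mm$value_raw
         else ewma_smooth(mm$value_raw, smooth_lambda, z0 = mm$value_exp[1])
  d <- data.frame(month_index = mm$month_index, x = mm$value_raw,
                  monitored = mon, center = mm$value_exp,
                  lcl = mm$value_exp - L * se, ucl = mm$value_exp + L * se)
  d$signal <- d$monitored < d$lcl | d$monitored > d$ucl
  new_ewma_chart(d, lam, L, "reference_3se",
                 extra = list(se_mode = se_mode))
}

#' Residual EWMA control chart
#'
#' Standard EWMA chart applied to the residuals of a fitted time-series
#' model: target 0, process SD the residual SD, smoothing constant from
#' [optimize_lambda_sse()] when not supplied (the "optimal exponential
#' coefficient" default). Because a mean shift in the original series is
#' transmitted to the residuals, this chart monitors an autocorrelated
#' process with iid tools applied where they are valid.
#'
#' @param residuals residual vector (or `mortality_series`), length >= 10.
#' @param lambda smoothing constant; SSE-optimal when `NULL`.
#' @param L limit width (default 3).
#' @param time_varying use time-varying limits.
#' @return An `ewma_chart`.
#' @export
residual_ewma_chart <- function(residuals, lambda = NULL, L = 3,
                                time_varying = FALSE) {
  e <- series_values(residuals)
  if (length(e) < 10) stop_param("need at least 10 residuals")
  if (is.null(lambda)) lambda <- optimize_lambda_sse(e)$lambda
  ewma_chart(e, target = 0, sigma_x = stats::sd(e), lambda = lambda, L = L,
             time_varying = time_varying, z0 = 0)
}

#' One-step-forecast-error control chart
#'
#' Monitors the observed series against `prediction_t +/- L * pred_se_t`
#' from [one_step_forecast()]; for GARCH fits the limits widen and narrow
#' with the conditional SD \eqn{\sigma_t}.
#'
#' @param fit an `arma_fit` or `garch_fit`.
#' @param series the modelled series (defaults to the one stored in the fit).
#' @param L limit width (default 3).
#' @return An `ewma_chart` with `limit_mode = "forecast_error"`.
#' @export
forecast_error_chart <- function(fit, series = NULL, L = 3) {
  x <- if (is.null(series)) fit$series else series_values(series)
  fc <- one_step_forecast(fit, x)
  d <- data.frame(month_index = seq_along(x) - 1L, x = x, monitored = x,
                  center = fc$predictions,
                  lcl = fc$predictions - L * fc$pred_se,
                  ucl = fc$predictions + L * fc$pred_se)
  d$signal <- d$monitored < d$lcl | d$monitored > d$ucl
  new_ewma_chart(d, lambda = NA_real_, L, "forecast_error")
}
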