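spc_test <- function(name, statistic, df_or_n, p_value,
                     critical_values = NULL) {
  structure(list(name = name, statistic = unname(statistic),
                 df_or_n = unname(df_or_n), p_value = unname(p_value),
                 reject_at_05 = if (is.na(p_value)) NA else p_value < 0.05,
                 critical_values = critical_values),
            class = "spc_test")
}

#' @export
print.spc_test <- function(x, ...) {
  cat(sprintf("<%s> statistic %.4f (df/n %s), p = %.4g%s\n", x$name,
              x$statistic, format(x$df_or_n), x$p_value,
              if (isTRUE(x$reject_at_05)) " *" else ""))
  if (!is.null(x$critical_values))
    cat("  critical values:",
        paste(names(x$critical_values),
              sprintf("%.2f", x$critical_values), collapse = ", "), "\n")
  invisible(x)
}

#' Sample ACF and PACF with white-noise bounds
#'
#' Sample autocorrelations use the standard correlogram convention (lag-0
#' sample variance in the denominator); partial autocorrelations come from
#' the Durbin–Levinson recursion. The white-noise confidence bound is
#' \eqn{1.96/\sqrt{n}}.
#'
#' @param series [mortality_series()] or numeric vector without gaps.
#' @param max_lag largest lag (default `10 * log10(n)` as in standard
#'   correlogram displays, capped at `n - 1`).
#' @return A `correlogram`: data frame `lags`/`acf`/`pacf` plus `ci_bound`
#'   and `n`.
#' @export
correlogram <- function(series, max_lag = NULL) {
  x <- series_values(series)
  n <- length(x)
  if (stats::sd(x) == 0) stop_param("constant series: autocorrelation undefined")
  if (is.null(max_lag)) max_lag <- floor(10 * log10(n))
  max_lag <- check_positive_int(max_lag, "max_lag")
  if (max_lag >= n) stop_param("max_lag must be < series length")
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1]
  p <- stats::pacf(x, lag.max = max_lag, plot = FALSE)$acf[, 1, 1]
  structure(list(table = data.frame(lag = seq_len(max_lag), acf = a, pacf = p),
                 ci_bound = 1.96 / sqrt(n), n = n),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("<correlogram> n = %d, ci bound +/- %.3f\n", x$n, x$ci_bound))
  print(utils::head(x$table, 12))
  invisible(x)
}

#' Ljung–Box portmanteau (Q) test
#'
#' Joint test that the first `h` autocorrelations are zero, with the
#' small-sample Ljung–Box correction
#' \eqn{Q = n(n+2)\sum_{k\le h} r_k^2/(n-k)}. When applied to residuals of a
#' fitted ARMA model, `fitdf` reduces the chi-square degrees of freedom by
#' the number of estimated ARMA parameters.
#'
#' @param series series or residual vector.
#' @param h number of lags.
#' @param fitdf fitted-parameter correction to the degrees of freedom.
#' @return An `spc_test`.
#' @export
ljung_box_q <- function(series, h, fitdf = 0) {
  x <- series_values(series)
  h <- check_positive_int(h, "h")
  if (h >= length(x)) stop_param("h must be < series length")
  bt <- stats::Box.test(x, lag = h, type = "Ljung-Box", fitdf = fitdf)
  spc_test("Ljung-Box Q", bt$statistic, h - fitdf, bt$p.value)
}

#' Cumulative-periodogram white-noise test
#'
#' Bartlett-type test: under Gaussian white noise the normalised cumulative
#' periodogram ordinates behave as uniform order statistics, so a
#' Kolmogorov–Smirnov statistic against the uniform line tests the
#' white-noise null. Sharp spectral peaks (e.g. strong seasonality) produce
#' large deviations.
#'
#' @param series series or numeric vector, length at least 16.
#' @return An `spc_test` (statistic is the KS distance; `df_or_n` the number
#'   of periodogram ordinates used).
#' @export
cumulative_periodogram_test <- function(series) {
  x <- series_values(series)
  n <- length(x)
  if (n < 16) stop_param("cumulative periodogram test needs n >= 16")
  if (stats::sd(x) == 0) stop_param("constant series has no spectrum")
  m <- floor((n - 1) / 2)
  I <- (Mod(stats::fft(x - mean(x)))^2 / n)[2:(m + 1)]
  U <- cumsum(I) / sum(I)
  ks <- suppressWarnings(stats::ks.test(U[seq_len(m - 1)], "punif"))
  spc_test("cumulative periodogram (Bartlett)", ks$statistic, m, ks$p.value)
}

# Dickey-Fuller tau quantiles (studentised statistic), standard tabulation;
# rows are sample sizes 25, 50, 100, 250, 500, Inf.
.adf_probs <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
.adf_ns <- c(25, 50, 100, 250, 500, Inf)
.adf_tau_mu <- matrix(c(
  -3.75, -3.33, -3.00, -2.62, -0.37, 0.00, 0.34, 0.72,
  -3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66,
  -3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63,
  -3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62,
  -3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61,
  -3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60), 6, 8, byrow = TRUE)
.adf_tau_trend <- matrix(c(
  -4.38, -3.95, -3.60, -3.24, -1.14, -0.80, -0.50, -0.15,
  -4.15, -3.80, -3.50, -3.18, -1.19, -0.87, -0.58, -0.24,
  -4.04, -3.73, -3.45, -3.15, -1.22, -0.90, -0.62, -0.28,
  -3.99, -3.69, -3.43, -3.13, -1.23, -0.92, -0.64, -0.31,
  -3.98, -3.68, -3.42, -3.13, -1.24, -0.93, -0.65, -0.32,
  -3.96, -3.66, -3.41, -3.12, -1.25, -0.94, -0.66, -0.33), 6, 8, byrow = TRUE)

#' Augmented Dickey–Fuller unit-root test
#'
#' Regression of the first difference on the lagged level, `n_lags` lagged
#' differences and a constant (plus a linear trend when
#' `include_trend = TRUE`); the studentised coefficient on the lagged level
#' is compared with the Dickey–Fuller tau distribution (embedded standard
#' quantile tabulation, interpolated in sample size and probability). The
#' null hypothesis is the presence of a unit root.
#'
#' @param series series or numeric vector, n >= 25.
#' @param include_trend include a deterministic linear trend (test of trend
#'   stationarity).
#' @param n_lags number of augmentation lags, or `"auto"` for the Schwert
#'   rule \eqn{\lfloor 12 (n/100)^{1/4} \rfloor}.
#' @return An `spc_test` with 1%/5%/10% critical values.
#' @export
adf_test <- function(series, include_trend = FALSE, n_lags = "auto") {
  x <- series_values(series)
  n <- length(x)
  if (n < 25) stop_param("ADF test needs n >= 25")
  if (identical(n_lags, "auto")) n_lags <- floor(12 * (n / 100)^0.25)
  if (n_lags < 0 || n_lags >= n / 2) stop_param("n_lags must be in [0, n/2)")
  dx <- diff(x)
  t_use <- (n_lags + 2):n           # indices of x whose difference is modelled
  y <- dx[t_use - 1]
  X <- cbind(level = x[t_use - 1], intercept = 1)
  if (n_lags > 0) {
    lagged <- sapply(seq_len(n_lags), function(k) dx[t_use - 1 - k])
    X <- cbind(X, lagged)
  }
  if (include_trend) X <- cbind(X, trend = t_use)
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  dfree <- length(y) - ncol(X)
  s2 <- sum(res^2) / dfree
  XtXinv <- chol2inv(chol(crossprod(X)))
  stat <- fit$coefficients[1] / sqrt(s2 * XtXinv[1, 1])
  tab <- if (include_trend) .adf_tau_trend else .adf_tau_mu
  # interpolate across sample size (in 1/n), then across probability
  w <- 1 / pmin(n, 1e6)
  qs <- apply(tab, 2, function(col) stats::approx(1 / .adf_ns, col, w, rule = 2)$y)
  p <- stats::approx(qs, .adf_probs, xout = stat, rule = 2)$y
  spc_test("augmented Dickey-Fuller", stat, length(y), p,
           critical_values = c(`1%` = qs[1], `5%` = qs[3], `10%` = qs[4]))
}

#' Normality and moment summaries
#'
#' Shapiro–Wilk test plus moment-based skewness \eqn{m_3/m_2^{3/2}} and
#' non-excess kurtosis \eqn{m_4/m_2^2} (normal series give 3).
#'
#' @param series series or numeric vector, 3 <= n <= 5000.
#' @return List with `shapiro_w` (`spc_test`), `skewness`, `kurtosis`.
#' @export
moments_normality <- function(series) {
  x <- series_values(series)
  n <- length(x)
  if (n < 3 || n > 5000) stop_param("moments_normality needs 3 <= n <= 5000")
  if (stats::sd(x) == 0) stop_param("constant series: moments undefined")
  m <- x - mean(x)
  m2 <- mean(m^2); m3 <- mean(m^3); m4 <- mean(m^4)
  sw <- stats::shapiro.test(x)
  list(shapiro_w = spc_test("Shapiro-Wilk", sw$statistic, n, sw$p.value),
       skewness = m3 / m2^1.5, kurtosis = m4 / m2^2)
}

#' Classical additive seasonal decomposition
#'
#' Additive decomposition into a centred 2x12 moving-average trend, period-12
#' seasonal means of the detrended series (re-centred to sum to zero), and a
#' remainder. Trend and remainder are missing on the first and last six
#' months, as in the classical method.
#'
#' @param series series or numeric vector without gaps, n >= 2 * period.
#' @param period seasonal period (default 12 months).
#' @return A `decomposition`: data frame `month_index`, `observed`, `trend`,
#'   `seasonal`, `remainder` plus the seasonal figure.
#' @export
classical_decompose <- function(series, period = 12) {
  x <- series_values(series)
  if (length(x) < 2 * period) stop_param("decomposition needs n >= 2 * period")
  dc <- stats::decompose(stats::ts(x, frequency = period), type = "additive")
  structure(list(table = data.frame(month_index = seq_along(x) - 1L,
                                    observed = x,
                                    trend = as.numeric(dc$trend),
                                    seasonal = as.numeric(dc$seasonal),
                                    remainder = as.numeric(dc$random)),
                 figure = as.numeric(dc$figure), period = period),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> period %d; seasonal amplitude (max-min) %.4f\n",
              x$period, diff(range(x$figure))))
  invisible(x)
}

#' Lagged-scatter data for autocorrelation plots
#'
#' Pairs \eqn{(x_{t-k}, x_t)} for each lag `k = 1..max_lag`, the data behind
#' a lag-plot grid.
#'
#' @param series series or numeric vector.
#' @param max_lag largest lag.
#' @return Data frame with columns `lag`, `t`, `x_t`, `x_lagged`
#'   (`n - k` rows for lag `k`).
#' @export
lag_plot_data <- function(series, max_lag) {
  x <- series_values(series)
  max_lag <- check_positive_int(max_lag, "max_lag")
  if (max_lag >= length(x)) stop_param("max_lag must be < series length")
  do.call(rbind, lapply(seq_len(max_lag), function(k) {
    t_idx <- (k + 1):length(x)
    data.frame(lag = k, t = t_idx - 1L, x_t = x[t_idx], x_lagged = x[t_idx - k])
  }))
}
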