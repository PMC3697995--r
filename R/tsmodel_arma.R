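#' Linear detrending of a series
#'
#' Ordinary least squares of the series on its month index; the residual
#' series (exact zero mean, orthogonal to time) is the input to subsequent
#' stationary modelling when the series is trend-stationary.
#'
#' @param series [mortality_series()] or numeric vector without gaps.
#' @return A `trend_fit`: `intercept`, `slope` (per month), `residual_series`
#'   (a detrended [mortality_series()]), and the `lm` fit.
#' @export
detrend_linear <- function(series) {
  x <- series_values(series)
  if (length(x) < 3) stop_param("detrending needs n >= 3")
  tt <- if (inherits(series, "mortality_series"))
    as.data.frame(series)$month_index else seq_along(x) - 1L
  fit <- stats::lm(x ~ tt)
  res <- stats::residuals(fit)
  structure(list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
                 residual_series = mortality_series(res, month_index = tt,
                                                    kind = "detrended"),
                 fit = fit),
            class = "trend_fit")
}

# expand a sparse lag specification into arima()'s fixed-coefficient vector
sparse_fixed <- function(lags, maxlag) {
  f <- rep(0, maxlag)
  f[lags] <- NA
  f
}

#' Fit a sparse-lag (seasonal) ARMA model
#'
#' Maximum-likelihood/conditional-sum-of-squares estimation (via
#' [stats::arima()]) of an ARMA model in which only the requested AR and MA
#' lags are free; all intermediate lags are fixed at zero. A multiplicative
#' seasonal component \eqn{(1-\Phi_1 B^{s})} (and/or seasonal MA) may be
#' added, giving the model
#' \eqn{(1-\phi(B))(1-\Phi(B^s)) x_t = (1+\theta(B))(1+\Theta(B^s))\omega_t}.
#' With a non-zero mean \eqn{\mu} the implied constant is
#' \eqn{\alpha = \mu(1-\sum\phi)(1-\sum\Phi)}.
#'
#' The default `"CSS"` method conditions on the first `max(lag)` observations
#' with zero-initialised pre-sample innovations; `"CSS-ML"` or `"ML"` refine
#' with the exact Gaussian likelihood.
#'
#' @param series stationary (e.g. detrended) series or numeric vector.
#' @param ar_lags,ma_lags integer sets of free AR/MA lags (possibly empty).
#' @param include_constant estimate the process mean.
#' @param seasonal_ar,seasonal_ma number of multiplicative seasonal AR/MA
#'   terms (0 or 1 in practice).
#' @param period seasonal period (default 12).
#' @param method estimation method passed to [stats::arima()].
#' @return An `arma_fit` with named coefficient maps `ar`, `ma`, `sar`, `sma`,
#'   mean `mu`, constant `alpha`, `sigma_w`, `residuals`, `loglik`, `aic`,
#'   `bic`, `coef_se`, `converged`, `n_used`, `k_free`.
#' @export
fit_arma <- function(series, ar_lags = integer(0), ma_lags = integer(0),
                     include_constant = TRUE, seasonal_ar = 0, seasonal_ma = 0,
                     period = 12, method = c("CSS", "CSS-ML", "ML")) {
  method <- match.arg(method)
  x <- series_values(series)
  n <- length(x)
  if (anyDuplicated(ar_lags) || anyDuplicated(ma_lags))
    stop_param("duplicate lags in specification")
  ar_lags <- sort(as.integer(ar_lags))
  ma_lags <- sort(as.integer(ma_lags))
  maxlag <- max(c(ar_lags, ma_lags, 0))
  if (maxlag >= n / 2) stop_param("largest lag must be < n/2")
  p <- if (length(ar_lags)) max(ar_lags) else 0L
  q <- if (length(ma_lags)) max(ma_lags) else 0L
  fixed <- c(sparse_fixed(ar_lags, p), sparse_fixed(ma_lags, q),
             rep(NA, seasonal_ar + seasonal_ma),
             if (include_constant) NA)
  fit <- stats::arima(x, order = c(p, 0L, q),
                      seasonal = list(order = c(seasonal_ar, 0L, seasonal_ma),
                                      period = period),
                      include.mean = include_constant,
                      fixed = fixed, transform.pars = FALSE, method = method)
  cf <- stats::coef(fit)
  pick <- function(prefix, lags) {
    if (!length(lags)) return(stats::setNames(numeric(0), character(0)))
    stats::setNames(cf[paste0(prefix, lags)], lags)
  }
  ar <- pick("ar", ar_lags)
  ma <- pick("ma", ma_lags)
  sar <- if (seasonal_ar) cf[paste0("sar", seq_len(seasonal_ar))] else numeric(0)
  sma <- if (seasonal_ma) cf[paste0("sma", seq_len(seasonal_ma))] else numeric(0)
  mu <- if (include_constant) unname(cf["intercept"]) else 0
  free <- which(is.na(fixed))
  se <- sqrt(pmax(diag(fit$var.coef), 0))
  n_used <- fit$nobs
  ll <- fit$loglik
  k <- length(free) + 1L   # free coefficients plus innovation variance
  conv <- is.null(fit$code) || fit$code == 0
  structure(list(ar = ar, ma = ma, sar = sar, sma = sma, mu = mu,
                 alpha = mu * (1 - sum(ar)) * (1 - sum(sar)),
                 sigma_w = sqrt(fit$sigma2),
                 residuals = as.numeric(stats::residuals(fit)),
                 loglik = ll, aic = -2 * ll + 2 * k,
                 bic = -2 * ll + k * log(n_used),
                 coef_se = se, converged = conv, n_used = n_used,
                 k_free = k, period = period, method = method,
                 series = x, fit = fit),
            class = "arma_fit")
}

#' @export
print.arma_fit <- function(x, ...) {
  cat(sprintf("<arma_fit> %s; mu %.4f, sigma_w %.4f; logLik %.2f, AIC %.2f, BIC %.2f%s\n",
              x$method, x$mu, x$sigma_w, x$loglik, x$aic, x$bic,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  if (length(x$ar)) cat("  AR:", paste0("L", names(x$ar), "=",
                                        sprintf("%.3f", x$ar), collapse = " "), "\n")
  if (length(x$ma)) cat("  MA:", paste0("L", names(x$ma), "=",
                                        sprintf("%.3f", x$ma), collapse = " "), "\n")
  if (length(x$sar)) cat("  seasonal AR:", sprintf("%.3f", x$sar), "\n")
  if (length(x$sma)) cat("  seasonal MA:", sprintf("%.3f", x$sma), "\n")
  invisible(x)
}

#' Tidy coefficient table of a fitted mean/variance model
#'
#' @param fit an `arma_fit` or `garch_fit`.
#' @return Data frame with columns `term`, `estimate`, `se`, `z`, `p`.
#' @export
coef_table <- function(fit) {
  if (inherits(fit, "arma_fit")) {
    est <- stats::coef(fit$fit)[colnames(fit$fit$var.coef)]
    se <- sqrt(pmax(diag(fit$fit$var.coef), 0))
  } else if (inherits(fit, "garch_fit")) {
    est <- fit$coefficients
    se <- fit$coef_se
  } else stop_param("unsupported fit object")
  z <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p = 2 * stats::pnorm(-abs(unname(z))))
}

#' LM test for ARCH effects
#'
#' Regresses squared residuals on their first `h` lags; the Lagrange
#' multiplier statistic \eqn{n R^2} is chi-square with `h` degrees of freedom
#' under conditional homoscedasticity. The partial autocorrelations of the
#' squared residuals are returned alongside for graphical inspection.
#'
#' @param residuals residuals of a fitted mean model.
#' @param h number of lags (default 5).
#' @return List with `test` (`spc_test`) and `pacf_sq` (a [correlogram()] of
#'   the squared residuals).
#' @export
arch_effects_test <- function(residuals, h = 5) {
  e <- series_values(residuals)
  h <- check_positive_int(h, "h")
  n <- length(e)
  if (h >= n / 2) stop_param("h must be < n/2")
  e2 <- e^2
  y <- e2[(h + 1):n]
  X <- cbind(1, sapply(seq_len(h), function(k) e2[(h + 1 - k):(n - k)]))
  fit <- stats::lm.fit(X, y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  stat <- length(y) * r2
  list(test = spc_test("ARCH LM", stat, h,
                       stats::pchisq(stat, h, lower.tail = FALSE)),
       pacf_sq = correlogram(e2, max_lag = max(h, 10)))
}

#' Rank candidate models by information criteria
#'
#' @param fits named list of `arma_fit`/`garch_fit` objects estimated on the
#'   same usable sample.
#' @return Data frame ordered by AIC with columns `model`, `k`, `loglik`,
#'   `aic`, `bic`, `rank_aic`, `rank_bic`, `criteria_agree`.
#' @export
select_model <- function(fits) {
  if (inherits(fits, c("arma_fit", "garch_fit"))) fits <- list(fits)
  if (is.null(names(fits)))
    names(fits) <- paste0("model", seq_along(fits))
  ns <- vapply(fits, function(f) f$n_used, numeric(1))
  if (length(unique(ns)) > 1L)
    stop_param("candidates fitted on differing sample lengths; not comparable")
  tab <- data.frame(model = names(fits),
                    k = vapply(fits, function(f) f$k_free, numeric(1)),
                    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
                    aic = vapply(fits, function(f) f$aic, numeric(1)),
                    bic = vapply(fits, function(f) f$bic, numeric(1)))
  tab$rank_aic <- rank(tab$aic, ties.method = "first")
  tab$rank_bic <- rank(tab$bic, ties.method = "first")
  tab$criteria_agree <- tab$rank_aic == tab$rank_bic
  tab[order(tab$rank_aic), , drop = FALSE]
}

#' One-step-ahead forecasts and their standard errors
#'
#' Within-sample one-step predictions: the prediction at `t` uses information
#' to `t - 1`. For a homoscedastic ARMA fit the one-step standard error is
#' the innovation SD; for a GARCH fit it is the conditional SD
#' \eqn{\sigma_t} from the variance recursion.
#'
#' @param fit an `arma_fit` or `garch_fit`.
#' @param series the series the model was fitted to (defaults to the stored
#'   one); supplied values must match in length.
#' @return List with `predictions` and `pred_se`, both of series length.
#' @export
one_step_forecast <- function(fit, series = NULL) {
  x <- if (is.null(series)) fit$series else series_values(series)
  if (length(x) != length(fit$residuals))
    stop_param("series length does not match fitted residuals")
  if (inherits(fit, "garch_fit")) {
    list(predictions = x - fit$residuals, pred_se = sqrt(fit$cond_variance))
  } else if (inherits(fit, "arma_fit")) {
    list(predictions = x - fit$residuals,
         pred_se = rep(fit$sigma_w, length(x)))
  } else stop_param("unsupported fit object")
}
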