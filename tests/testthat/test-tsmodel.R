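test_that("linear detrending satisfies the OLS normal equations exactly", {
  x <- 2 + 0.1 * (0:49)
  tf <- detrend_linear(x)
  expect_equal(tf$slope, 0.1, tolerance = 1e-10)
  expect_lt(max(abs(tf$residual_series$value)), 1e-10)

  set.seed(61)
  y <- cumsum(rnorm(80))
  tf2 <- detrend_linear(y)
  r <- tf2$residual_series$value
  expect_lt(abs(mean(r)), 1e-10)
  expect_lt(abs(stats::cov(r, seq_along(r))), 1e-8)
  expect_error(detrend_linear(c(1, 2)), "n >= 3")
})

test_that("detrended trend-stationary series pass the no-trend ADF screen", {
  set.seed(62)
  ok <- replicate(30, {
    x <- 0.01 * (1:200) + sim_ar1(200, 0.4, sample.int(2^30, 1))
    d <- detrend_linear(x)$residual_series$value
    adf_test(d, include_trend = FALSE, n_lags = 2)$p_value < 0.05
  })
  expect_gte(mean(ok), 0.9)
})

test_that("constant-only ARMA fit reduces to sample moments (ML scaling)", {
  set.seed(63)
  x <- rnorm(400, 5, 2)
  f <- fit_arma(x)
  expect_lt(abs(f$mu - mean(x)), 1e-6)
  expect_lt(abs(f$sigma_w - sqrt(mean((x - mean(x))^2))), 1e-6)
  expect_equal(f$alpha, f$mu)
})

test_that("AIC and BIC match a brute-force Gaussian likelihood evaluation", {
  set.seed(64)
  x <- rnorm(20)
  f <- fit_arma(x)
  ll <- sum(stats::dnorm(x, mean(x), sqrt(mean((x - mean(x))^2)), log = TRUE))
  expect_equal(f$loglik, ll, tolerance = 1e-6)
  expect_equal(f$aic, -2 * ll + 2 * 2, tolerance = 1e-6)   # mean + variance
  expect_equal(f$bic, -2 * ll + 2 * log(f$n_used), tolerance = 1e-6)
})

test_that("sparse-lag ARMA estimation recovers an AR(1) within 2 SE most of the time", {
  set.seed(65)
  hits <- replicate(20, {
    x <- sim_ar1(2000, 0.5, sample.int(2^30, 1))
    f <- fit_arma(x, ar_lags = 1)
    abs(f$ar[["1"]] - 0.5) <= 2 * f$coef_se["ar1"]
  })
  expect_gte(sum(hits), 16)
  expect_error(fit_arma(rnorm(100), ar_lags = c(1, 1)), "duplicate")
  expect_error(fit_arma(rnorm(20), ar_lags = 15), "lag")
})

test_that("ARCH LM test has power against ARCH(1) and its PACF shows the lag-1 spike", {
  set.seed(66)
  res <- replicate(40, {
    s <- generate_structured_series(series_spec(n = 500, arch_coefs = 0.5,
                                                garch_const = 0.5,
                                                seed = sample.int(2^30, 1)))
    a <- arch_effects_test(s$value, h = 5)
    c(a$test$p_value < 0.05,
      abs(a$pacf_sq$table$pacf[1]) > a$pacf_sq$ci_bound)
  })
  expect_gte(mean(res[1, ]), 0.9)
  expect_gte(mean(res[2, ]), 0.9)
  expect_error(arch_effects_test(rnorm(20), h = 10), "n/2")
})

test_that("GARCH conditional variance follows the hand-rolled recursion", {
  set.seed(67)
  s <- generate_structured_series(series_spec(n = 300, arch_coefs = 0.2,
                                              garch_coefs = 0.6,
                                              garch_const = 0.2, seed = 9))
  f <- fit_garch(s$value, m = 1, k = 1)
  cf <- f$coefficients
  eps <- f$residuals
  # brute-force recursion on the first 10 points
  init <- mean(eps^2)
  s2 <- numeric(10)
  for (t in 1:10) {
    e2l <- if (t == 1) init else eps[t - 1]^2
    s2l <- if (t == 1) init else s2[t - 1]
    s2[t] <- cf["gamma0"] + cf["gamma1"] * e2l + cf["delta1"] * s2l
  }
  expect_equal(f$cond_variance[1:10], s2, tolerance = 1e-10)
  # one-step forecast SE is the conditional SD
  fc <- one_step_forecast(f)
  expect_equal(fc$pred_se, sqrt(f$cond_variance), tolerance = 1e-12)
  expect_true(all(f$cond_variance > 0))
})

test_that("GARCH fitting on iid data shrinks the ARCH term and prefers the ARCH-free model", {
  set.seed(68)
  res <- replicate(20, {
    x <- rnorm(600)
    g <- fit_garch(x, m = 1, k = 0)
    f0 <- fit_arma(x)
    c(g$coefficients[["gamma1"]], g$aic > f0$aic)
  })
  expect_lt(stats::median(res[1, ]), 0.05)
  expect_gte(mean(res[2, ]), 0.85)
})

test_that("alternative error distributions fit without failure on ARCH-free data", {
  set.seed(69)
  ft <- fit_garch(rnorm(300), m = 1, k = 0, error_dist = "t")
  expect_true(is.finite(ft$loglik))
  expect_gt(ft$shape, 10)   # df large (or at bound) when errors are normal
  fg <- fit_garch(rnorm(300), m = 1, k = 0, error_dist = "ged")
  expect_true(is.finite(fg$loglik))
})

test_that("joint Wald test has the right df, conservative null behaviour, and power", {
  set.seed(70)
  s <- generate_structured_series(series_spec(n = 800, arch_coefs = 0.3,
                                              garch_coefs = 0.5,
                                              garch_const = 0.2, seed = 13))
  f <- fit_garch(s$value, m = 1, k = 1)
  w <- joint_wald(f, "both")
  expect_equal(w$df_or_n, 2)
  expect_lt(w$p_value, 0.001)
  expect_equal(joint_wald(f, "arch")$df_or_n, 1)

  # under the iid null the boundary makes the test conservative, never inflated
  pv <- replicate(40, tryCatch(
    joint_wald(fit_garch(rnorm(400), m = 1, k = 0), "arch")$p_value,
    error = function(e) NA))
  expect_lte(mean(pv < 0.05, na.rm = TRUE), 0.08)
})

test_that("one-step forecasts reproduce closed forms", {
  set.seed(71)
  x <- sim_ar1(300, 0.6, seed = 72) + 5
  f <- fit_arma(x, ar_lags = 1)
  fc <- one_step_forecast(f)
  manual <- f$mu + f$ar[["1"]] * (x[-300] - f$mu)
  expect_lt(max(abs(fc$predictions[-1] - manual)), 1e-10)
  expect_equal(fc$pred_se, rep(f$sigma_w, 300))

  f0 <- fit_arma(x)
  fc0 <- one_step_forecast(f0)
  expect_true(all(abs(fc0$predictions - f0$mu) < 1e-10))
  expect_error(one_step_forecast(f, rnorm(10)), "length")
})

test_that("model selection ranks by penalised likelihood and flags comparability", {
  fake <- function(k, ll, n = 100) structure(
    list(k_free = k, loglik = ll, aic = -2 * ll + 2 * k,
         bic = -2 * ll + k * log(n), n_used = n), class = "arma_fit")
  tab <- select_model(list(big = fake(5, -50), small = fake(2, -50)))
  expect_equal(tab$model[1], "small")
  expect_true(all(tab$criteria_agree))
  expect_error(select_model(list(a = fake(2, -50, 100), b = fake(2, -50, 90))),
               "differing")
  one <- select_model(list(only = fake(1, -10)))
  expect_equal(nrow(one), 1)

  set.seed(73)
  pref <- replicate(30, {
    x <- sim_ar1(1000, 0.5, sample.int(2^30, 1))
    f1 <- fit_arma(x, ar_lags = 1)
    f0 <- fit_arma(x)
    f1$aic < f0$aic
  })
  expect_gte(mean(pref), 0.95)
})

test_that("correctly specified ARMA residuals pass the portmanteau closure check", {
  set.seed(74)
  pass <- replicate(40, {
    x <- sim_ar1(300, 0.6, sample.int(2^30, 1))
    f <- fit_arma(x, ar_lags = 1)
    ljung_box_q(f$residuals, h = 20, fitdf = 1)$p_value >= 0.05
  })
  expect_gt(mean(pass), 0.85)
})

test_that("multiplicative seasonal AR fits the expected-series exemplar structure", {
  set.seed(75)
  # simulate (1 - 0.145 B)(1 - 0.132 B^12) x = w via equivalent sparse lags
  s <- generate_structured_series(series_spec(
    n = 2000, ar_lags = c(1, 12, 13),
    ar_coefs = c(0.145, 0.132, -0.145 * 0.132), garch_const = 1, seed = 14))
  f <- fit_arma(s$value, ar_lags = 1, seasonal_ar = 1)
  expect_true(f$converged)
  expect_lt(abs(f$ar[["1"]] - 0.145), 3 * f$coef_se["ar1"])
  expect_lt(abs(f$sar[[1]] - 0.132), 3 * f$coef_se["sar1"])
})
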