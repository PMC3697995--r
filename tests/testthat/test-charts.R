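test_that("EWMA recursion is exact", {
  expect_equal(ewma_smooth(c(1, 1, 1), 0.5, z0 = 0), c(0.5, 0.75, 0.875))
  x <- rnorm(50)
  expect_equal(ewma_smooth(x, 1), x)                       # lambda = 1 identity
  expect_equal(ewma_smooth(rep(3, 20), 0.2, z0 = 3), rep(3, 20))  # fixed point
  # reconstruction to machine precision
  z <- ewma_smooth(x, 0.3, z0 = 0)
  z_manual <- Reduce(function(zp, xi) 0.3 * xi + 0.7 * zp, x, accumulate = TRUE,
                     init = 0)[-1]
  expect_lt(max(abs(z - z_manual)), 1e-12)
  expect_error(ewma_smooth(x, 0), "\\(0, 1\\]")
  expect_error(ewma_smooth(x, 1.2), "\\(0, 1\\]")
})

test_that("EWMA variance formula matches the brute-force unrolled recursion", {
  # z_i = lambda * sum_k (1-lambda)^k x_{i-k} + (1-lambda)^i z0, so
  # Var(z_i) = sigma^2 lambda^2 sum_{k=0}^{i-1} (1-lambda)^{2k}
  for (lam in c(0.1, 0.4, 0.8)) for (i in c(1, 2, 5, 20)) {
    brute <- lam^2 * sum((1 - lam)^(2 * (0:(i - 1))))
    expect_equal(ewma_variance(1, lam, i), brute, tolerance = 1e-12)
  }
  expect_equal(ewma_variance(2, 1, 1:5), rep(4, 5))        # lambda = 1
  expect_equal(ewma_variance(1, 0.4, 1), 0.16)             # Var(lambda x1)
  expect_equal(ewma_variance(1, 0.05, 1e6), 0.05 / 1.95, tolerance = 1e-12)
  expect_true(all(diff(ewma_variance(1, 0.3, 1:100)) >= 0))
  expect_error(ewma_variance(1, 0.5, 0), ">= 1")
})

test_that("chart limits behave: early narrowing, convergence, signal monotonicity", {
  set.seed(81)
  x <- rnorm(3000)
  tv <- ewma_chart(x, 0, 1, 0.05, time_varying = TRUE)
  fx <- ewma_chart(x, 0, 1, 0.05, time_varying = FALSE)
  expect_true(all(tv$data$ucl[1:50] < fx$data$ucl[1:50]))
  expect_lt(abs(tv$data$ucl[2500] - fx$data$ucl[2500]), 1e-9)

  sig_counts <- sapply(c(2, 2.5, 3, 3.5), function(L)
    sum(ewma_chart(x, 0, 1, 0.2, L = L)$data$signal))
  expect_true(all(diff(sig_counts) <= 0))
  expect_error(ewma_chart(numeric(0), 0, 1, 0.2), "empty")
  expect_error(ewma_chart(x, 0, 0, 0.2), "sigma_x")
})

test_that("Shewhart-limit in-control signal rate matches 0.0027", {
  set.seed(82)
  x <- rnorm(2e5)
  frac <- mean(ewma_chart(x, 0, 1, lambda = 1, L = 3)$data$signal)
  se <- sqrt(0.0027 * (1 - 0.0027) / 2e5)
  expect_lt(abs(frac - 0.0027), 3 * se)
})

test_that("SSE-optimal lambda matches the EWMA/IMA equivalence", {
  set.seed(83)
  x <- as.numeric(stats::arima.sim(list(order = c(0, 1, 1), ma = -0.7), 2000))
  expect_lt(abs(optimize_lambda_sse(x)$lambda - 0.3), 0.05)
  # iid data picks the smallest grid value
  expect_equal(optimize_lambda_sse(rnorm(2000))$lambda, 0.01)
  expect_equal(optimize_lambda_sse(rnorm(100), grid = 0.37)$lambda, 0.37)
  expect_error(optimize_lambda_sse(rnorm(100), grid = numeric(0)), "empty")
  expect_error(optimize_lambda_sse(rnorm(5)), "n >= 10")
})

test_that("moving centre-line chart adapts to autocorrelation", {
  set.seed(84)
  frac <- mean(replicate(50, {
    x <- sim_ar1(200, 0.9, sample.int(2^30, 1))
    mean(moving_centerline_chart(x)$data$signal)
  }))
  expect_lte(frac, 0.02)

  # white noise: flat centre line near the mean, limits near mean +/- 3 SD
  x <- rnorm(500)
  ch <- moving_centerline_chart(x)
  expect_lt(max(abs(ch$data$center - mean(x))), 0.5 * stats::sd(x))
  expect_lt(abs((ch$data$ucl[100] - ch$data$center[100]) / (3 * stats::sd(x)) - 1),
            0.15)

  # a gross outlier signals at its own position
  y <- rnorm(100); y[50] <- 8
  expect_true(moving_centerline_chart(y)$data$signal[50])

  expect_warning(moving_centerline_chart(rep(1, 50)), "degenerate")
})

test_that("reference chart signals exactly where the raw series leaves the band", {
  v <- rep(0.15, 30)
  raw <- mortality_series(v, kind = "raw")
  expd <- mortality_series(v, kind = "expected", se = rep(0.01, 30))
  expect_equal(sum(reference_3se_chart(raw, expd)$data$signal), 0)

  v2 <- v
  v2[17] <- 0.15 + 4 * 0.01
  ch <- reference_3se_chart(mortality_series(v2, kind = "raw"), expd)
  expect_equal(which(ch$data$signal), 17)

  # missing month refused
  v3 <- v; v3[5] <- NA
  expect_error(reference_3se_chart(mortality_series(v3, kind = "raw"), expd),
               "missing")
  # absent monthly se: informative error, series_sd fallback works
  expd2 <- mortality_series(v, kind = "expected")
  expect_error(reference_3se_chart(raw, expd2), "se")
  ch2 <- reference_3se_chart(mortality_series(v2, kind = "raw"),
                             mortality_series(v + rnorm(30, 0, 1e-3),
                                              kind = "expected"),
                             se_mode = "series_sd")
  expect_s3_class(ch2, "ewma_chart")
})

test_that("volatile series signal more often than matched iid series on reference limits", {
  set.seed(85)
  frac <- function(dist_vals) {
    raw <- mortality_series(pmin(pmax(0.15 + dist_vals, 0), 1), kind = "raw")
    expd <- mortality_series(rep(0.15, length(dist_vals)), kind = "expected",
                             se = rep(0.015, length(dist_vals)))
    mean(reference_3se_chart(raw, expd)$data$signal)
  }
  res <- replicate(120, {
    g <- generate_structured_series(series_spec(
      n = 120, ar_lags = 1, ar_coefs = 0.4, arch_coefs = 0.35,
      garch_coefs = 0.55, garch_const = 0.0001 * 0.1,
      seed = sample.int(2^30, 1)))
    v <- g$value
    iid <- rnorm(120, mean(v), stats::sd(v))   # matched mean and SD
    c(frac(v), frac(iid))
  })
  expect_gte(mean(res[1, ]) / mean(res[2, ]), 1.5)
})

test_that("residual EWMA chart is in control on white-noise residuals", {
  set.seed(86)
  nosig <- mean(replicate(100, sum(residual_ewma_chart(rnorm(180))$data$signal) == 0))
  expect_gte(nosig, 0.9)

  # lambda = 1 reduces to a Shewhart chart of residuals
  x <- rnorm(2e5)
  frac <- mean(residual_ewma_chart(x, lambda = 1)$data$signal)
  se <- sqrt(0.0027 * 0.9973 / 2e5)
  expect_lt(abs(frac - 0.0027), 4 * se)
  expect_error(residual_ewma_chart(rnorm(5)), "10")
})

test_that("a mean shift in the series is transmitted to the residual chart", {
  set.seed(87)
  detected <- replicate(30, {
    x <- sim_ar1(200, 0.5, sample.int(2^30, 1))
    f <- fit_arma(x[1:100], ar_lags = 1)   # fitted on pre-shift data
    xs <- inject_shift(x, 100, 3 * f$sigma_w)
    res <- spcmort:::arma_css_resid_cpp(xs - f$mu, 0, 1L, f$ar[["1"]],
                                        integer(0), numeric(0))
    ch <- residual_ewma_chart(res, lambda = 0.2)
    any(ch$data$signal[101:200])
  })
  expect_gte(mean(detected), 0.9)
})

test_that("forecast-error chart has nominal rate and variance-tracking limits", {
  set.seed(88)
  # correctly specified AR(1): aggregate signal fraction near 0.0027
  sig <- unlist(replicate(40, {
    x <- sim_ar1(500, 0.6, sample.int(2^30, 1))
    forecast_error_chart(fit_arma(x, ar_lags = 1))$data$signal[-1]
  }, simplify = FALSE))
  se <- sqrt(0.0027 * 0.9973 / length(sig))
  expect_lt(abs(mean(sig) - 0.0027), 4 * se)

  # GARCH limits track the true conditional SD
  s <- generate_structured_series(series_spec(n = 1000, arch_coefs = 0.15,
                                              garch_coefs = 0.75,
                                              garch_const = 0.1, seed = 33))
  f <- fit_garch(s$value, m = 1, k = 1)
  w <- with(forecast_error_chart(f)$data, ucl - lcl)
  set.seed(33)
  e <- spcmort:::draw_innovations(1500, "normal", NULL)
  sim <- spcmort:::arma_garch_sim_cpp(e, integer(0), numeric(0), integer(0),
                                      numeric(0), 0.1, 0.15, 0.75)
  expect_gt(stats::cor(w, sqrt(sim$sigma2[501:1500])), 0.9)

  # an adapted AR fit gives materially narrower one-step limits than a
  # white-noise fit of the same autocorrelated series
  x <- sim_ar1(1000, 0.9, seed = 89)
  w_ar <- mean(with(forecast_error_chart(fit_arma(x, ar_lags = 1))$data, ucl - lcl))
  w_wn <- mean(with(forecast_error_chart(fit_arma(x))$data, ucl - lcl))
  expect_lt(w_ar, 0.6 * w_wn)
})
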