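test_that("correlogram matches AR(1) theory and its PACF cuts off", {
  x <- sim_ar1(5000, 0.6, seed = 51)
  cg <- correlogram(x, max_lag = 10)
  expect_lt(max(abs(cg$table$acf[1:5] - 0.6^(1:5))), 0.03)
  # PACF(1) = ACF(1) exactly
  expect_equal(cg$table$pacf[1], cg$table$acf[1], tolerance = 1e-10)
  expect_equal(cg$ci_bound, 1.96 / sqrt(5000))
  expect_error(correlogram(rep(1, 50)), "constant")

  set.seed(52)
  cut <- replicate(40, {
    cgi <- correlogram(sim_ar1(600, 0.6, seed = sample.int(2^30, 1)), 6)
    all(abs(cgi$table$pacf[3:6]) < cgi$ci_bound)
  })
  expect_gte(mean(cut), 0.6)   # joint over 4 lags; each ~95%
})

test_that("white-noise ACF coverage matches the Bartlett bound", {
  set.seed(53)
  cov <- replicate(50, {
    cg <- correlogram(rnorm(400), max_lag = 40)
    mean(abs(cg$table$acf) < cg$ci_bound)
  })
  expect_lt(abs(mean(cov) - 0.95), 0.02)
  # bounds always respected
  cg <- correlogram(rnorm(200), 30)
  expect_true(all(abs(cg$table$acf) <= 1 & abs(cg$table$pacf) <= 1))
})

test_that("Ljung-Box Q rejects strong autocorrelation and validates inputs", {
  set.seed(54)
  p <- replicate(100, ljung_box_q(sim_ar1(200, 0.9, sample.int(2^30, 1)),
                                  h = 20)$p_value)
  expect_gte(mean(p < 0.001), 0.99)
  expect_error(ljung_box_q(rnorm(50), h = 0), "positive")
  expect_error(ljung_box_q(rnorm(50), h = 50), "<")
  # fitdf reduces the reference df
  q <- ljung_box_q(rnorm(100), h = 10, fitdf = 3)
  expect_equal(q$df_or_n, 7)
})

test_that("cumulative periodogram test flags concentrated spectra", {
  set.seed(55)
  t <- 1:240
  x <- sin(2 * pi * t / 12) + rnorm(240, sd = 0.2)
  expect_lt(cumulative_periodogram_test(x)$p_value, 0.01)
  expect_error(cumulative_periodogram_test(rep(2, 100)), "constant")
  expect_error(cumulative_periodogram_test(rnorm(10)), "n >= 16")
})

test_that("ADF test separates unit roots from (trend-)stationary series", {
  set.seed(56)
  # stationary AR(1): strong rejection of the unit-root null
  pow <- mean(replicate(60, adf_test(sim_ar1(500, 0.5, sample.int(2^30, 1)),
                                     n_lags = 2)$p_value < 0.05))
  expect_gte(pow, 0.95)
  # trend-stationary series: detected with the trend term, missed without
  reps <- replicate(60, {
    x <- 0.02 * (1:300) + rnorm(300)
    c(adf_test(x, include_trend = TRUE, n_lags = 2)$p_value < 0.05,
      adf_test(x, include_trend = FALSE, n_lags = 2)$p_value < 0.05)
  })
  expect_gte(mean(reps[1, ]), 0.9)
  expect_lt(mean(reps[2, ]), mean(reps[1, ]) - 0.3)
  # random walk: null typically retained
  rw_p <- replicate(60, adf_test(cumsum(rnorm(300)))$p_value)
  expect_lt(mean(rw_p < 0.05), 0.15)

  tst <- adf_test(cumsum(rnorm(100)))
  expect_named(tst$critical_values, c("1%", "5%", "10%"))
  expect_error(adf_test(rnorm(20)), "n >= 25")
  expect_error(adf_test(rnorm(100), n_lags = 60), "n_lags")
})

test_that("moment summaries are exact on constructed samples", {
  m <- moments_normality(rep(c(-1, 0, 1), 20))
  expect_equal(m$skewness, 0, tolerance = 1e-12)
  m2 <- moments_normality(rep(c(-1, 1), 30))
  expect_equal(m2$kurtosis, 1, tolerance = 1e-12)
  expect_error(moments_normality(rep(1, 10)), "constant")
  expect_error(moments_normality(rnorm(2)), "n")
})

test_that("classical decomposition reproduces closed forms and reconstructs exactly", {
  t <- 0:119
  x <- 10 + sin(2 * pi * t / 12)
  dc <- classical_decompose(x)
  int <- !is.na(dc$table$trend)
  expect_lt(max(abs(dc$table$seasonal[int] - sin(2 * pi * t / 12)[int])), 1e-6)
  expect_lt(max(abs(dc$table$remainder[int])), 1e-6)
  # seasonal component has period 12 and sums to ~0
  expect_lt(abs(sum(dc$figure)), 1e-10)
  expect_equal(dc$table$seasonal[1:12], dc$table$seasonal[13:24])

  dc2 <- classical_decompose(rep(5, 48))
  expect_true(all(abs(dc2$table$seasonal) < 1e-12))
  int2 <- !is.na(dc2$table$remainder)
  expect_true(all(abs(dc2$table$remainder[int2]) < 1e-12))

  # moving average of a line is the line
  dc3 <- classical_decompose(2 + 0.3 * t)
  int3 <- !is.na(dc3$table$trend)
  expect_lt(max(abs(dc3$table$trend[int3] - (2 + 0.3 * t)[int3])), 1e-10)
  expect_lt(max(abs(dc3$table$seasonal)), 1e-10)

  # additive reconstruction identity on arbitrary data
  set.seed(57)
  y <- rnorm(60)
  dc4 <- classical_decompose(y)
  with(dc4$table, {
    ok <- !is.na(trend)
    expect_lt(max(abs(observed[ok] - trend[ok] - seasonal[ok] - remainder[ok])),
              1e-10)
  })
  expect_error(classical_decompose(rnorm(20)), "period")
})

test_that("lag-plot pairs have the right counts and correlation", {
  x <- rnorm(10)
  lp <- lag_plot_data(x, 1)
  expect_equal(nrow(lp), 9)
  lp2 <- lag_plot_data(x, 9)
  expect_equal(sum(lp2$lag == 9), 1)

  y <- sim_ar1(1000, 0.5, seed = 58)
  lp3 <- lag_plot_data(y, 3)
  r <- sapply(1:3, function(k) {
    d <- lp3[lp3$lag == k, ]
    stats::cor(d$x_t, d$x_lagged)
  })
  a <- correlogram(y, 3)$table$acf
  expect_lt(max(abs(r - a)), 0.02)
})
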