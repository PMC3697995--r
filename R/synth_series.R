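#' Specification of a structured monthly series
#'
#' Describes a simulated series with sparse-lag ARMA autocorrelation,
#' (G)ARCH conditional heteroscedasticity, a deterministic linear trend and
#' period-12 seasonality — the features the monitoring methods in this
#' package are designed to confront.
#'
#' The variance recursion is
#' \deqn{\sigma^2_t = \gamma_0 + \sum_i \gamma_i \epsilon^2_{t-i} +
#'       \sum_j \delta_j \sigma^2_{t-j},}
#' so with no ARCH/GARCH terms `garch_const` is simply the innovation
#' variance. Specifications with \eqn{\sum\gamma + \sum\delta \ge 1} are
#' permitted (integrated-variance processes occur in practice) but are
#' labelled non-covariance-stationary.
#'
#' @param n series length in months (after burn-in).
#' @param mean process mean added to the stationary path.
#' @param ar_lags,ar_coefs sparse autoregressive lags and coefficients.
#' @param ma_lags,ma_coefs sparse moving-average lags and coefficients.
#' @param arch_coefs,garch_coefs,garch_const variance-equation parameters
#'   (\eqn{\gamma_{1..m}}, \eqn{\delta_{1..k}}, \eqn{\gamma_0}).
#' @param seasonal_amplitude amplitude of the period-12 sinusoid.
#' @param trend_slope deterministic linear trend per month.
#' @param innovation_dist `"normal"`, `"t"` or `"ged"`.
#' @param innovation_shape degrees of freedom (t) or shape (ged).
#' @param require_stationary error if the AR polynomial has a root on or
#'   inside the unit circle.
#' @param burn_in transient steps discarded before returning the path.
#' @param seed integer RNG seed.
#' @return An object of class `series_spec`.
#' @export
series_spec <- function(n = 180, mean = 0,
                        ar_lags = integer(0), ar_coefs = numeric(0),
                        ma_lags = integer(0), ma_coefs = numeric(0),
                        arch_coefs = numeric(0), garch_coefs = numeric(0),
                        garch_const = 1,
                        seasonal_amplitude = 0, trend_slope = 0,
                        innovation_dist = c("normal", "t", "ged"),
                        innovation_shape = NULL,
                        require_stationary = TRUE,
                        burn_in = 500L, seed = 1L) {
  innovation_dist <- match.arg(innovation_dist)
  n <- check_positive_int(n, "n")
  if (length(ar_lags) != length(ar_coefs)) stop_param("ar_lags/ar_coefs length mismatch")
  if (length(ma_lags) != length(ma_coefs)) stop_param("ma_lags/ma_coefs length mismatch")
  if (anyDuplicated(ar_lags) || anyDuplicated(ma_lags))
    stop_param("duplicate lags in lag specification")
  if (garch_const <= 0) stop_param("garch_const (gamma0) must be positive")
  if (any(arch_coefs < 0) || any(garch_coefs < 0))
    stop_param("ARCH/GARCH coefficients must be nonnegative")
  if (seasonal_amplitude < 0) stop_param("seasonal_amplitude must be nonnegative")
  stationary_ar <- TRUE
  if (length(ar_lags)) {
    poly <- numeric(max(ar_lags) + 1L)
    poly[1] <- 1
    poly[ar_lags + 1L] <- -ar_coefs
    roots <- polyroot(poly)
    stationary_ar <- all(Mod(roots) > 1 + 1e-8)
    if (require_stationary && !stationary_ar)
      stop_param("AR polynomial has a root on or inside the unit circle; ",
                 "explosive path refused with require_stationary = TRUE")
  }
  variance_stationary <- (sum(arch_coefs) + sum(garch_coefs)) < 1
  structure(c(as.list(environment())[c(
    "n", "mean", "ar_lags", "ar_coefs", "ma_lags", "ma_coefs",
    "arch_coefs", "garch_coefs", "garch_const", "seasonal_amplitude",
    "trend_slope", "innovation_dist", "innovation_shape",
    "require_stationary", "burn_in", "seed")],
    list(stationary_ar = stationary_ar,
         variance_stationary = variance_stationary)),
    class = "series_spec")
}

#' Simulate a structured monthly series
#'
#' Generates the ARMA-(G)ARCH path from [series_spec()], discards the burn-in
#' transient, and adds the deterministic mean, trend and seasonal components.
#'
#' @param spec a [series_spec()].
#' @param kind `kind` label of the returned [mortality_series()]; simulated
#'   paths are unconstrained reals, so the default is `"detrended"`.
#' @return A [mortality_series()] of length `spec$n` with attributes
#'   `variance_stationary` and `spec`.
#' @export
generate_structured_series <- function(spec, kind = "detrended") {
  stopifnot(inherits(spec, "series_spec"))
  set.seed(spec$seed)
  n_total <- spec$n + spec$burn_in
  e <- draw_innovations(n_total, spec$innovation_dist, spec$innovation_shape)
  sim <- arma_garch_sim_cpp(e,
                            as.integer(spec$ar_lags), as.numeric(spec$ar_coefs),
                            as.integer(spec$ma_lags), as.numeric(spec$ma_coefs),
                            spec$garch_const, as.numeric(spec$arch_coefs),
                            as.numeric(spec$garch_coefs))
  x <- sim$x[(spec$burn_in + 1):n_total]
  t0 <- 0:(spec$n - 1)
  x <- x + spec$mean + spec$trend_slope * t0 +
    spec$seasonal_amplitude * sin(2 * pi * t0 / 12)
  out <- mortality_series(x, kind = kind, site_id = "simulated")
  attr(out, "variance_stationary") <- spec$variance_stationary
  attr(out, "spec") <- spec
  out
}

#' Inject a sustained step shift into a series
#'
#' Adds `size` to every value from month position `t0` (0-based, matching the
#' series month indexing) onwards; values before `t0` are unchanged. Used to
#' build out-of-control scenarios for run-length studies.
#'
#' @param series a [mortality_series()] or numeric vector.
#' @param t0 0-based position of the first shifted month.
#' @param size shift size (same units as the series values).
#' @return Same type as the input.
#' @export
inject_shift <- function(series, t0, size) {
  is_ms <- inherits(series, "mortality_series")
  v <- if (is_ms) series$value else as.numeric(series)
  if (t0 < 0 || t0 >= length(v)) stop_param("t0 out of range")
  idx <- seq.int(t0 + 1L, length(v))
  v[idx] <- v[idx] + size
  if (!is_ms) return(v)
  d <- as.data.frame(series)
  mortality_series(v, month_index = d$month_index, kind = unclass(series)$kind,
                   site_id = unclass(series)$site_id,
                   n_patients = d$n_patients,
                   se = if ("se" %in% names(d)) d$se else NULL)
}
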