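#' Configuration for a synthetic ICU cohort
#'
#' Describes the generative model for patient-level data: a random-coefficient
#' logistic model of hospital mortality with site-specific random intercepts
#' and severity slopes, an APACHE-III-like severity score, a deterministic
#' monthly trend on the logit scale, and period-12 sinusoidal seasonality.
#'
#' Defaults emulate the scale and structure of a bi-national adult ICU
#' database: 137 sites, roughly 3,600 patients per site over 180 months
#' (about 491,000 records in total), with the fixed intercept calibrated so
#' that marginal hospital mortality at the default case-mix is close to
#' 14.07%. The monthly trend is centred at mid-series so it does not move the
#' overall mean.
#'
#' @param n_sites number of ICU sites.
#' @param patients_per_site_mean expected patients per site over the whole
#'   period; monthly counts are Poisson with mean
#'   `patients_per_site_mean / n_months`.
#' @param n_months length of the observation window in months.
#' @param fixed_intercept,fixed_slope fixed effects on the logit scale
#'   (slope per centred severity unit).
#' @param random_intercept_sd,random_slope_sd,random_corr site random-effect
#'   distribution (bivariate normal).
#' @param severity_mean,severity_sd severity score distribution (normal
#'   truncated below at 0).
#' @param trend_per_month linear logit-scale trend, centred at mid-series.
#' @param seasonal_amplitude amplitude of the period-12 logit-scale sinusoid.
#' @param month_effects optional length-12 numeric vector of logit-scale month
#'   effects used instead of the sinusoid (recycled over the calendar year).
#' @param seed integer RNG seed.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_sites = 137,
                          patients_per_site_mean = 3586,
                          n_months = 180,
                          fixed_intercept = -2.3236,
                          fixed_slope = 0.04,
                          random_intercept_sd = 0.5,
                          random_slope_sd = 0.005,
                          random_corr = 0,
                          severity_mean = 52,
                          severity_sd = 28,
                          trend_per_month = -0.002,
                          seasonal_amplitude = 0.1,
                          month_effects = NULL,
                          seed = 1L) {
  n_sites <- check_positive_int(n_sites, "n_sites")
  n_months <- check_positive_int(n_months, "n_months")
  if (patients_per_site_mean <= 0) stop_param("patients_per_site_mean must be positive")
  if (severity_sd <= 0) stop_param("severity_sd must be positive")
  if (random_intercept_sd < 0 || random_slope_sd < 0)
    stop_param("random-effect SDs must be nonnegative")
  if (abs(random_corr) > 1) stop_param("random_corr must lie in [-1, 1]")
  if (seasonal_amplitude < 0) stop_param("seasonal_amplitude must be nonnegative")
  if (!is.null(month_effects) && length(month_effects) != 12L)
    stop_param("month_effects must have length 12")
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic patient-level cohort
#'
#' Draws site random effects, monthly Poisson patient counts, truncated-normal
#' severity scores and Bernoulli hospital-mortality outcomes from the logistic
#' model described in [cohort_config()]. Mortality probabilities are clipped
#' to `(1e-6, 1 - 1e-6)` to avoid degenerate likelihoods downstream.
#'
#' @param config a [cohort_config()].
#' @return A `cohort`: a `data.frame` with columns `site_id` (factor),
#'   `month_index` (0-based integer), `severity`, `died` and attribute
#'   `config`. Identical seeds give identical cohorts.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  ns <- config$n_sites
  nm <- config$n_months
  Sigma <- matrix(c(config$random_intercept_sd^2,
                    rep(config$random_corr * config$random_intercept_sd *
                          config$random_slope_sd, 2),
                    config$random_slope_sd^2), 2, 2)
  re <- matrix(MASS::mvrnorm(ns, mu = c(0, 0), Sigma = Sigma), ncol = 2)
  t_centred <- (0:(nm - 1)) - (nm - 1) / 2
  seas <- if (is.null(config$month_effects)) {
    config$seasonal_amplitude * sin(2 * pi * (0:(nm - 1)) / 12)
  } else {
    config$month_effects[(0:(nm - 1)) %% 12 + 1]
  }
  time_effect <- config$trend_per_month * t_centred + seas

  counts <- matrix(stats::rpois(ns * nm, config$patients_per_site_mean / nm),
                   nrow = ns)
  total <- sum(counts)
  site_id <- rep(rep(seq_len(ns), nm), as.vector(counts))
  month_index <- rep(rep(0:(nm - 1), each = ns), as.vector(counts))
  sev <- rtrunc_norm(total, config$severity_mean, config$severity_sd)
  eta <- config$fixed_intercept + re[site_id, 1] +
    (config$fixed_slope + re[site_id, 2]) * (sev - config$severity_mean) +
    time_effect[month_index + 1]
  p <- pmin(pmax(invlogit(eta), 1e-6), 1 - 1e-6)
  died <- stats::rbinom(total, 1, p)
  cohort <- data.frame(
    site_id = factor(sprintf("S%03d", site_id)),
    month_index = as.integer(month_index),
    severity = sev,
    died = as.integer(died)
  )
  o <- order(cohort$site_id, cohort$month_index)
  cohort <- cohort[o, , drop = FALSE]
  rownames(cohort) <- NULL
  attr(cohort, "config") <- config
  class(cohort) <- c("cohort", "data.frame")
  cohort
}
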