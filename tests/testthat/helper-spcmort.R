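# small simulation helpers shared across test files

sim_ar1 <- function(n, phi, seed) {
  set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = phi), n))
}

# a toy cohort with known structure: two sites, explicit months
toy_cohort <- function() {
  d <- data.frame(
    site_id = factor(rep("S001", 5)),
    month_index = c(0L, 0L, 0L, 1L, 1L),
    severity = c(50, 60, 70, 55, 65),
    died = c(0L, 1L, 1L, 0L, 0L)
  )
  class(d) <- c("cohort", "data.frame")
  d
}

# a hand-built risk model object (predict_expected only needs the fields)
manual_risk_model <- function(intercept = 0, slope = 0, center = 0,
                              site_effects = data.frame(site_id = character(0),
                                                        intercept = numeric(0),
                                                        slope = numeric(0))) {
  structure(list(fixed_intercept = intercept, fixed_slope = slope,
                 random_covariance = matrix(0, 2, 2),
                 site_effects = site_effects, severity_center = center,
                 loglik = NA_real_, converged = TRUE, fallback_glm = TRUE),
            class = "risk_model")
}
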