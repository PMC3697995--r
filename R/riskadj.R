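#' Fit the random-coefficient logistic risk model
#'
#' Risk adjustment for case-mix: hospital mortality is modelled by a logistic
#' regression with a fixed intercept and a fixed slope on the (internally
#' centred) severity score, plus site-level random intercepts and severity
#' slopes with unstructured covariance. Estimation uses the Laplace
#' approximation via [lme4::glmer()]. With a single site the model degenerates
#' and an ordinary logistic fit is used instead (flagged, with a warning).
#'
#' @param cohort a `cohort` data frame with columns `site_id`, `severity`,
#'   `died`.
#' @return An object of class `risk_model` with components `fixed_intercept`,
#'   `fixed_slope`, `random_covariance` (2x2), `site_effects` (per-site
#'   predicted deviations), `severity_center`, `loglik`, `converged`,
#'   `fallback_glm`, and the underlying `fit`.
#' @export
fit_risk_model <- function(cohort) {
  need <- c("site_id", "severity", "died")
  if (!all(need %in% names(cohort))) stop_param("cohort must have columns ",
                                                paste(need, collapse = ", "))
  if (anyNA(cohort$severity)) stop_param("missing severity values in cohort")
  if (length(unique(cohort$died)) < 2L)
    stop_param("degenerate cohort: outcome is constant, model not estimable")
  ctr <- mean(cohort$severity)
  d <- data.frame(site_id = factor(cohort$site_id),
                  sev_c = cohort$severity - ctr,
                  died = cohort$died)
  one_site <- nlevels(d$site_id) < 2L
  if (one_site) {
    warning("single site: falling back to ordinary logistic regression")
    fit <- stats::glm(died ~ sev_c, family = stats::binomial(), data = d)
    fe <- stats::coef(fit)
    out <- list(fixed_intercept = unname(fe[1]), fixed_slope = unname(fe[2]),
                random_covariance = matrix(0, 2, 2),
                site_effects = data.frame(site_id = levels(d$site_id),
                                          intercept = 0, slope = 0),
                severity_center = ctr,
                loglik = as.numeric(stats::logLik(fit)),
                converged = fit$converged, fallback_glm = TRUE, fit = fit)
  } else {
    fit <- lme4::glmer(died ~ sev_c + (1 + sev_c | site_id),
                       family = stats::binomial(), data = d,
                       control = lme4::glmerControl(calc.derivs = FALSE))
    fe <- lme4::fixef(fit)
    vc <- lme4::VarCorr(fit)[["site_id"]]
    re <- lme4::ranef(fit)[["site_id"]]
    conv <- length(fit@optinfo$conv$lme4) == 0L &&
      fit@optinfo$conv$opt == 0L
    if (!conv) warning("risk model did not converge cleanly; inspect fit")
    out <- list(fixed_intercept = unname(fe[1]), fixed_slope = unname(fe[2]),
                random_covariance = matrix(as.numeric(vc), 2, 2),
                site_effects = data.frame(site_id = rownames(re),
                                          intercept = re[, 1], slope = re[, 2]),
                severity_center = ctr,
                loglik = as.numeric(stats::logLik(fit)),
                converged = conv, fallback_glm = FALSE, fit = fit)
  }
  ev <- eigen(out$random_covariance, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) warning("random-effect covariance not PSD")
  class(out) <- "risk_model"
  out
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> intercept %.4f, slope %.4f (per centred severity unit)\n",
              x$fixed_intercept, x$fixed_slope))
  cat(sprintf("  random SDs: intercept %.4f, slope %.4f; %s; logLik %.1f\n",
              sqrt(x$random_covariance[1, 1]), sqrt(x$random_covariance[2, 2]),
              if (x$fallback_glm) "ordinary-logistic fallback" else "Laplace glmer",
              x$loglik))
  invisible(x)
}

#' Predict expected mortality probabilities
#'
#' Fills `p_expected` for every patient row using the fitted fixed effects and
#' site-level predicted random deviations; sites unseen at fit time receive
#' random effects of zero.
#'
#' @param model a [fit_risk_model()] result.
#' @param cohort a cohort data frame with `site_id` and `severity`.
#' @return The cohort with a `p_expected` column in `(0, 1)`.
#' @export
predict_expected <- function(model, cohort) {
  stopifnot(inherits(model, "risk_model"))
  if (anyNA(cohort$severity)) {
    bad <- which(is.na(cohort$severity))
    stop_param("missing severity at row(s) ", paste(head(bad, 5), collapse = ", "))
  }
  sev_c <- cohort$severity - model$severity_center
  idx <- match(as.character(cohort$site_id), model$site_effects$site_id)
  u0 <- ifelse(is.na(idx), 0, model$site_effects$intercept[idx])
  u1 <- ifelse(is.na(idx), 0, model$site_effects$slope[idx])
  eta <- model$fixed_intercept + u0 + (model$fixed_slope + u1) * sev_c
  cohort$p_expected <- pmin(pmax(invlogit(eta), 1e-12), 1 - 1e-12)
  cohort
}

#' Calibration and discrimination summaries
#'
#' Hosmer–Lemeshow goodness-of-fit statistic over groups of predicted risk and
#' the ROC area under the curve computed from the Wilcoxon rank statistic
#' (ties averaged).
#'
#' The HL statistic is \eqn{\sum_g (O_g - E_g)^2 / (E_g (1 - E_g/n_g))} with
#' groups formed by predicted-risk quantiles (ties kept in one group).
#'
#' @param cohort cohort with `p_expected` and `died`.
#' @param hl_groups number of HL groups (default 10).
#' @return A `calibration_report` list: `hosmer_lemeshow_stat`, `hl_groups`
#'   (groups actually formed), `hl_p_value`, `roc_auc`, `mean_predicted`,
#'   `mean_observed`.
#' @export
calibration_discrimination <- function(cohort, hl_groups = 10) {
  if (is.null(cohort$p_expected)) stop_param("cohort lacks p_expected; run predict_expected first")
  hl_groups <- check_positive_int(hl_groups, "hl_groups")
  if (hl_groups < 2) stop_param("hl_groups must be >= 2")
  p <- cohort$p_expected
  y <- cohort$died
  if (length(unique(p)) < 2L)
    stop_param("constant predictions: AUC undefined")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop_param("both outcomes required for AUC")
  r <- rank(p)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = hl_groups + 1)))
  g <- cut(p, breaks = br, include.lowest = TRUE)
  O <- tapply(y, g, sum)
  E <- tapply(p, g, sum)
  n_g <- tapply(y, g, length)
  hl <- sum((O - E)^2 / (E * (1 - E / n_g)))
  k <- length(levels(droplevels(g)))
  structure(list(hosmer_lemeshow_stat = unname(hl), hl_groups = k,
                 hl_p_value = stats::pchisq(unname(hl), df = max(k - 2, 1),
                                            lower.tail = FALSE),
                 roc_auc = unname(auc),
                 mean_predicted = mean(p), mean_observed = mean(y)),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> HL %.2f on %d groups (p %.3g); AUC %.3f\n",
              x$hosmer_lemeshow_stat, x$hl_groups, x$hl_p_value, x$roc_auc))
  cat(sprintf("  mean predicted %.4f vs observed %.4f\n",
              x$mean_predicted, x$mean_observed))
  invisible(x)
}
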