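# log-density of standardised (unit-variance) innovations z for each family
std_innov_logdens <- function(z, dist, shape) {
  switch(dist,
    normal = -0.5 * (log(2 * pi) + z^2),
    t = {
      df <- shape
      lgamma((df + 1) / 2) - lgamma(df / 2) - 0.5 * log(pi * (df - 2)) -
        (df + 1) / 2 * log1p(z^2 / (df - 2))
    },
    ged = {
      nu <- shape
      lam <- sqrt(2^(-2 / nu) * gamma(1 / nu) / gamma(3 / nu))
      log(nu) - 0.5 * abs(z / lam)^nu - (1 + 1 / nu) * log(2) -
        log(lam) - lgamma(1 / nu)
    })
}

# per-observation log-likelihood at natural parameters
garch_obs_loglik <- function(par, x, ar_lags, ma_lags, m, k, dist,
                             include_constant) {
  i <- 1L
  mu <- if (include_constant) par[i] else 0
  if (include_constant) i <- i + 1L
  phi <- if (length(ar_lags)) par[i:(i + length(ar_lags) - 1L)] else numeric(0)
  i <- i + length(ar_lags)
  theta <- if (length(ma_lags)) par[i:(i + length(ma_lags) - 1L)] else numeric(0)
  i <- i + length(ma_lags)
  gamma0 <- par[i]; i <- i + 1L
  gam <- if (m > 0) par[i:(i + m - 1L)] else numeric(0)
  i <- i + m
  del <- if (k > 0) par[i:(i + k - 1L)] else numeric(0)
  i <- i + k
  shape <- if (dist != "normal") par[i] else NA_real_
  if (gamma0 <= 0 || any(gam < 0) || any(del < 0)) return(rep(-Inf, length(x)))
  if (dist == "t" && shape <= 2.01) return(rep(-Inf, length(x)))
  if (dist == "ged" && shape <= 0.1) return(rep(-Inf, length(x)))
  eps <- arma_css_resid_cpp(x, mu, as.integer(ar_lags), phi,
                            as.integer(ma_lags), theta)
  s2 <- garch_filter_cpp(eps^2, gamma0, gam, del, mean(eps^2))
  if (any(!is.finite(s2)) || any(s2 <= 0)) return(rep(-Inf, length(x)))
  z <- eps / sqrt(s2)
  std_innov_logdens(z, dist, shape) - 0.5 * log(s2)
}

#' Fit an ARMA mean equation with (G)ARCH errors
#'
#' Joint conditional maximum likelihood of a sparse-lag ARMA mean equation
#' and a GARCH(m, k) variance equation
#' \deqn{\sigma^2_t = \gamma_0 + \sum_{i=1}^m \gamma_i \epsilon^2_{t-i} +
#'       \sum_{j=1}^k \delta_j \sigma^2_{t-j}}
#' with normal, Student-t or generalised-error standardised innovations.
#' Pre-sample innovations are zero-initialised (conditional sum of squares);
#' pre-sample squared innovations and variances are set to the sample mean of
#' the squared mean-equation residuals. Variance parameters are kept
#' nonnegative through log transforms during optimisation, so
#' \eqn{\sum\gamma + \sum\delta \ge 1} (integrated variance) is permitted and
#' flagged rather than refused.
#'
#' Standard errors come from the outer product of per-observation score
#' vectors (OPG), evaluated numerically at the optimum.
#'
#' @param series series or numeric vector (typically a detrended series or
#'   the residuals of a trend fit).
#' @param ar_lags,ma_lags sparse mean-equation lags.
#' @param m,k ARCH and GARCH orders (`m >= 1`, `k >= 0`).
#' @param error_dist `"normal"`, `"t"` or `"ged"`.
#' @param include_constant estimate the process mean.
#' @return A `garch_fit` with `coefficients` (named vector: `mu`, `ar.l*`,
#'   `ma.l*`, `gamma0`, `gamma*`, `delta*`, `shape`), `coef_se`, `vcov`,
#'   `cond_variance`, `residuals` (mean-equation innovations),
#'   `std_residuals`, `loglik`, `aic`, `bic`, `converged`,
#'   `variance_stationary`.
#' @export
fit_garch <- function(series, ar_lags = integer(0), ma_lags = integer(0),
                      m = 1, k = 1, error_dist = c("normal", "t", "ged"),
                      include_constant = TRUE) {
  error_dist <- match.arg(error_dist)
  x <- series_values(series)
  n <- length(x)
  m <- as.integer(m); k <- as.integer(k)
  if (m < 1) stop_param("ARCH order m must be >= 1")
  if (k < 0) stop_param("GARCH order k must be >= 0")
  if (n < 50) stop_param("too few observations for (G)ARCH estimation")
  ar_lags <- sort(unique(as.integer(ar_lags)))
  ma_lags <- sort(unique(as.integer(ma_lags)))

  v0 <- stats::var(x)
  start_nat <- c(if (include_constant) mean(x),
                 rep(0.05, length(ar_lags)), rep(0.05, length(ma_lags)),
                 v0 * (if (k > 0) 0.1 else 0.7),
                 rep(0.1 / m, m), if (k > 0) rep(0.8 / k, k),
                 if (error_dist == "t") 8 else if (error_dist == "ged") 1.5)
  n_mean <- (if (include_constant) 1L else 0L) + length(ar_lags) + length(ma_lags)
  n_var <- 1L + m + k
  has_shape <- error_dist != "normal"

  to_work <- function(nat) {
    w <- nat
    vi <- n_mean + seq_len(n_var)
    w[vi] <- log(nat[vi])
    if (has_shape) {
      si <- n_mean + n_var + 1L
      w[si] <- if (error_dist == "t") log(nat[si] - 2) else log(nat[si])
    }
    w
  }
  to_nat <- function(w) {
    nat <- w
    vi <- n_mean + seq_len(n_var)
    nat[vi] <- exp(w[vi])
    if (has_shape) {
      si <- n_mean + n_var + 1L
      nat[si] <- if (error_dist == "t") 2 + exp(w[si]) else exp(w[si])
    }
    nat
  }
  negll_work <- function(w) {
    ll <- garch_obs_loglik(to_nat(w), x, ar_lags, ma_lags, m, k, error_dist,
                           include_constant)
    v <- -sum(ll)
    if (!is.finite(v)) 1e10 else v
  }
  w0 <- to_work(start_nat)
  opt1 <- stats::optim(w0, negll_work, method = "Nelder-Mead",
                       control = list(maxit = 2000))
  opt <- stats::optim(opt1$par, negll_work, method = "BFGS",
                      control = list(maxit = 500))
  if (opt$value > opt1$value) opt <- opt1
  par <- to_nat(opt$par)
  converged <- opt$convergence == 0 && is.finite(opt$value)
  if (!converged) warning("GARCH estimation did not converge cleanly")

  nm <- c(if (include_constant) "mu",
          if (length(ar_lags)) paste0("ar.l", ar_lags),
          if (length(ma_lags)) paste0("ma.l", ma_lags),
          "gamma0",
          paste0("gamma", seq_len(m)),
          if (k > 0) paste0("delta", seq_len(k)),
          if (has_shape) "shape")
  names(par) <- nm

  # OPG covariance from numerical per-observation scores at the optimum
  f_obs <- function(nat) garch_obs_loglik(nat, x, ar_lags, ma_lags, m, k,
                                          error_dist, include_constant)
  J <- matrix(0, n, length(par))
  for (j in seq_along(par)) {
    h <- pmax(1e-5, 1e-4 * abs(par[j]))
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    J[, j] <- (f_obs(up) - f_obs(dn)) / (2 * h)
  }
  V <- tryCatch(solve(crossprod(J)), error = function(e) {
    warning("singular OPG information; standard errors unavailable — refit ",
            "with a simpler specification")
    matrix(NA_real_, length(par), length(par))
  })
  dimnames(V) <- list(nm, nm)
  se <- sqrt(pmax(diag(V), 0))

  mu <- if (include_constant) par[["mu"]] else 0
  phi <- if (length(ar_lags)) par[paste0("ar.l", ar_lags)] else numeric(0)
  theta <- if (length(ma_lags)) par[paste0("ma.l", ma_lags)] else numeric(0)
  eps <- arma_css_resid_cpp(x, mu, as.integer(ar_lags), as.numeric(phi),
                            as.integer(ma_lags), as.numeric(theta))
  gam <- par[paste0("gamma", seq_len(m))]
  del <- if (k > 0) par[paste0("delta", seq_len(k))] else numeric(0)
  s2 <- garch_filter_cpp(eps^2, par[["gamma0"]], as.numeric(gam),
                         as.numeric(del), mean(eps^2))
  ll <- -opt$value
  kp <- length(par)
  vs <- sum(gam) + sum(del) < 1
  if (!vs) warning("ARCH+GARCH coefficients sum to >= 1: ",
                   "conditional variance is not covariance-stationary")
  structure(list(coefficients = par, coef_se = se, vcov = V,
                 ar_lags = ar_lags, ma_lags = ma_lags, m = m, k = k,
                 error_dist = error_dist,
                 shape = if (has_shape) par[["shape"]] else NA_real_,
                 residuals = as.numeric(eps), cond_variance = as.numeric(s2),
                 std_residuals = as.numeric(eps / sqrt(s2)),
                 loglik = ll, aic = -2 * ll + 2 * kp,
                 bic = -2 * ll + kp * log(n),
                 k_free = kp, n_used = n, converged = converged,
                 variance_stationary = vs, series = x),
            class = "garch_fit")
}

#' @export
print.garch_fit <- function(x, ...) {
  cat(sprintf("<garch_fit> GARCH(%d,%d), %s errors; logLik %.2f, AIC %.2f, BIC %.2f%s\n",
              x$m, x$k, x$error_dist, x$loglik, x$aic, x$bic,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  tab <- coef_table(x)
  print(tab, digits = 4, row.names = FALSE)
  if (!x$variance_stationary)
    cat("  note: integrated variance (sum of ARCH+GARCH terms >= 1)\n")
  invisible(x)
}

#' Wald test of joint significance of variance parameters
#'
#' Chi-square Wald test that the selected ARCH (\eqn{\gamma_i}) and/or GARCH
#' (\eqn{\delta_j}) parameters are jointly zero, using the OPG covariance of
#' the fit. Because the null places the parameters on the boundary of the
#' parameter space, the chi-square reference is approximate (conservative).
#'
#' @param fit a converged `garch_fit`.
#' @param which `"arch"`, `"garch"` or `"both"`.
#' @return An `spc_test` with df equal to the number of tested parameters.
#' @export
joint_wald <- function(fit, which = c("both", "arch", "garch")) {
  which <- match.arg(which)
  stopifnot(inherits(fit, "garch_fit"))
  sel <- c(if (which %in% c("arch", "both")) paste0("gamma", seq_len(fit$m)),
           if (which %in% c("garch", "both") && fit$k > 0)
             paste0("delta", seq_len(fit$k)))
  if (!length(sel)) stop_param("no parameters selected for testing")
  V <- fit$vcov[sel, sel, drop = FALSE]
  if (anyNA(V)) stop_param("singular covariance; refit before testing")
  est <- fit$coefficients[sel]
  W <- tryCatch(drop(t(est) %*% solve(V, est)),
                error = function(e) stop_param(
                  "singular covariance; refit with a simpler specification"))
  spc_test(paste("joint Wald:", which), W, length(sel),
           stats::pchisq(W, length(sel), lower.tail = FALSE))
}
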