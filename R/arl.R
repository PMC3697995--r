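new_arl_design <- function(lambda, L, shift, arl0, arl_shift, method,
                           mc_se = NA_real_, profile = NULL) {
  structure(list(lambda = lambda, L = L, shift = shift,
                 arl_in_control = arl0, arl_at_shift = arl_shift,
                 p_exceed = 1 / arl0, method = method, mc_se = mc_se,
                 profile = profile),
            class = "arl_design")
}

#' @export
print.arl_design <- function(x, ...) {
  cat(sprintf("<arl_design> lambda %.3g, L %.4g (%s): ARL0 %.1f, ARL at %.3g SD shift %.2f\n",
              x$lambda, x$L, x$method, x$arl_in_control, x$shift,
              x$arl_at_shift))
  invisible(x)
}

# transition matrix of the discretised EWMA chain; exact normal-CDF mass per
# state interval (Brook-Evans construction), asymptotic-variance limits
ewma_transition <- function(lambda, L, delta, n_states) {
  h <- L * sqrt(lambda / (2 - lambda))
  edges <- seq(-h, h, length.out = n_states + 1)
  mid <- (edges[-1] + edges[-(n_states + 1)]) / 2
  carry <- (1 - lambda) * mid
  lo <- (outer(-carry, edges[-(n_states + 1)], `+`)) / lambda - delta
  hi <- (outer(-carry, edges[-1], `+`)) / lambda - delta
  stats::pnorm(hi) - stats::pnorm(lo)
}

arl_markov_value <- function(lambda, L, delta, n_states, initial = "zero") {
  Q <- ewma_transition(lambda, L, delta, n_states)
  a <- tryCatch(solve(diag(n_states) - Q, rep(1, n_states)),
                error = function(e) stop_param(
                  "singular transient system in ARL computation (L too large?)"))
  if (initial == "zero") return(a[(n_states + 1) / 2])  # z0 = 0 (chart target)
  # steady-state: weight by the in-control stationary distribution of the
  # chart statistic conditioned on no alarm (left Perron eigenvector)
  Q0 <- if (delta == 0) Q else ewma_transition(lambda, L, 0, n_states)
  ev <- eigen(t(Q0))
  i <- which.max(Re(ev$values))
  psi <- abs(Re(ev$vectors[, i]))
  psi <- psi / sum(psi)
  drop(psi %*% a)
}

#' Markov-chain average run length of an EWMA chart
#'
#' Discretises the EWMA statistic over the asymptotic control interval
#' `+/- L * sigma_z` into `n_states` equal states and solves the
#' fundamental-matrix equations for the expected run length, with
#' observations `N(delta, 1)` in process-SD units. With `lambda = 1` the
#' chart is Shewhart and the in-control ARL is \eqn{1/(2(1-\Phi(L)))}.
#'
#' `initial = "zero"` starts the statistic at the chart target (zero-state
#' run length, the design convention); `initial = "steady"` averages over the
#' in-control stationary distribution of the statistic, the relevant quantity
#' for the detection delay of a shift arriving after the chart has settled.
#'
#' @param lambda smoothing constant in (0, 1].
#' @param L limit width in sigma units.
#' @param delta sustained mean shift in process-SD units.
#' @param n_states odd number of states (default 201).
#' @param initial `"zero"` or `"steady"`.
#' @return An `arl_design` with `method = "markov"`.
#' @export
arl_markov <- function(lambda, L, delta = 0, n_states = 201,
                       initial = c("zero", "steady")) {
  initial <- match.arg(initial)
  check_prob_open(lambda, "lambda")
  if (L <= 0) stop_param("L must be positive")
  n_states <- check_positive_int(n_states, "n_states")
  if (n_states < 51 || n_states %% 2 == 0)
    stop_param("n_states must be an odd integer >= 51")
  arl_shift <- arl_markov_value(lambda, L, delta, n_states, initial)
  arl0 <- if (delta == 0) arl_shift
          else arl_markov_value(lambda, L, 0, n_states, initial)
  new_arl_design(lambda, L, delta, arl0, arl_shift, "markov")
}

#' Monte-Carlo average run length of an EWMA chart
#'
#' Simulates run lengths of the EWMA chart with asymptotic-variance limits
#' (`z0 = 0`, observations `N(delta, 1)`); the stochastic counterpart and
#' independent check of [arl_markov()].
#'
#' @param lambda smoothing constant in (0, 1].
#' @param L limit width.
#' @param delta sustained mean shift in process-SD units.
#' @param reps number of simulated run lengths (>= 1000).
#' @param seed RNG seed.
#' @param max_len censoring bound per run (default 1e6).
#' @return An `arl_design` with `method = "montecarlo"` and `mc_se` the
#'   standard error of the mean run length.
#' @export
arl_montecarlo <- function(lambda, L, delta = 0, reps = 10000, seed = 1,
                           max_len = 1e6) {
  check_prob_open(lambda, "lambda")
  if (L <= 0) stop_param("L must be positive")
  if (reps < 1000) stop_param("reps must be >= 1000")
  set.seed(seed)
  rl <- ewma_run_lengths_cpp(lambda, L, delta, as.integer(reps),
                             as.integer(max_len))
  arl <- mean(rl)
  mc_se <- stats::sd(rl) / sqrt(reps)
  d <- new_arl_design(lambda, L, delta, arl0 = if (delta == 0) arl else NA_real_,
                      arl_shift = arl, method = "montecarlo", mc_se = mc_se)
  if (delta != 0) d$arl_in_control <- NA_real_
  d
}

# bisection for the limit width giving in-control ARL = arl0 (rel. tol 0.5%)
solve_limit_width <- function(lambda, arl0, n_states, tol = 0.005,
                              L_range = c(0.5, 8)) {
  lo <- L_range[1]; hi <- L_range[2]
  # an ill-conditioned fundamental system means the ARL is astronomically
  # large at that width; treat it as +Inf for the bisection
  safe_arl <- function(L) tryCatch(arl_markov_value(lambda, L, 0, n_states),
                                   error = function(e) Inf)
  if (safe_arl(hi) < arl0)
    stop_param("requested in-control ARL unattainable within L <= ", hi)
  if (safe_arl(lo) > arl0)
    stop_param("requested in-control ARL below the ARL at L = ", lo)
  L <- NA_real_
  for (it in 1:80) {
    L <- (lo + hi) / 2
    v <- safe_arl(L)
    if (abs(v - arl0) / arl0 < tol * 0.2) break
    if (v > arl0) hi <- L else lo <- L
  }
  L
}

#' ARL-optimal EWMA design
#'
#' For each smoothing constant on the grid, solves (by bisection) the limit
#' width `L` such that the Markov-chain in-control ARL equals `arl0` to
#' within 0.5%, then evaluates the out-of-control ARL at the stated shift;
#' returns the grid value minimising it (ties to the smallest lambda). The
#' full (lambda, L, ARL) profile is attached for audit.
#'
#' @param delta sustained shift to detect, in process-SD units (> 0).
#' @param arl0 required in-control ARL (default 370).
#' @param lambda_grid candidate smoothing constants.
#' @param n_states Markov-chain states (default 201).
#' @return An `arl_design` for the optimal design, with `$profile` a data
#'   frame of `lambda`, `L`, `arl0`, `arl_shift` over the whole grid.
#' @export
optimal_lambda <- function(delta, arl0 = 370,
                           lambda_grid = seq(0.01, 1, by = 0.01),
                           n_states = 201) {
  if (delta <= 0) stop_param("delta must be positive")
  if (arl0 <= 1) stop_param("arl0 must exceed 1")
  lambda_grid <- sort(lambda_grid)
  prof <- lapply(lambda_grid, function(lam) {
    L <- solve_limit_width(lam, arl0, n_states)
    c(L = L, arl0 = arl_markov_value(lam, L, 0, n_states),
      arl_shift = arl_markov_value(lam, L, delta, n_states))
  })
  prof <- data.frame(lambda = lambda_grid, do.call(rbind, prof))
  best <- which.min(prof$arl_shift)
  new_arl_design(prof$lambda[best], prof$L[best], delta,
                 prof$arl0[best], prof$arl_shift[best], "markov",
                 profile = prof)
}

#' Scenario design for a percentage increment in mean mortality
#'
#' Converts a percentage increment of the process mean into an SD-unit shift
#' (`target_mean = mean * (1 + pct_increment)`,
#' `shift = (target_mean - mean)/sd`) and delegates the (lambda, L) choice to
#' [optimal_lambda()].
#'
#' @param mean in-control process mean (e.g. mean expected mortality).
#' @param sd in-control process SD.
#' @param pct_increment fractional increment (0.05 for a 5% increase; > 0).
#' @param arl0 required in-control ARL (default 370).
#' @param ... passed to [optimal_lambda()].
#' @return A `scenario_design` list: `process_mean`, `process_sd`,
#'   `pct_increment`, `target_mean`, `shift_sd_units`, `lambda`, `L`, and the
#'   underlying `design`.
#' @export
scenario_design <- function(mean, sd, pct_increment, arl0 = 370, ...) {
  if (sd <= 0) stop_param("sd must be positive")
  if (pct_increment <= 0)
    stop_param("pct_increment must be positive: no shift to design for")
  target <- mean * (1 + pct_increment)
  shift <- (target - mean) / sd
  des <- optimal_lambda(shift, arl0 = arl0, ...)
  structure(list(process_mean = mean, process_sd = sd,
                 pct_increment = pct_increment, target_mean = target,
                 shift_sd_units = shift, lambda = des$lambda, L = des$L,
                 design = des),
            class = "scenario_design")
}

#' @export
print.scenario_design <- function(x, ...) {
  cat(sprintf("<scenario_design> mean %.4f -> target %.4f (+%.0f%%), shift %.3f SD\n",
              x$process_mean, x$target_mean, 100 * x$pct_increment,
              x$shift_sd_units))
  cat(sprintf("  chosen lambda %.2f, L %.3f (ARL0 %.1f, ARL at shift %.1f)\n",
              x$lambda, x$L, x$design$arl_in_control, x$design$arl_at_shift))
  invisible(x)
}
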