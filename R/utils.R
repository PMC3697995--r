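invlogit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

stop_param <- function(...) stop(..., call. = FALSE)

check_positive_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x))
    stop_param(name, " must be a positive integer")
  as.integer(x)
}

check_prob_open <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x > 1)
    stop_param(name, " must lie in (0, 1]")
  x
}

# numeric payload of a series-like input; errors on missing values when
# a gapless run is required
series_values <- function(x, require_complete = TRUE) {
  v <- if (inherits(x, "mortality_series")) x$value else as.numeric(x)
  if (require_complete && anyNA(v))
    stop_param("series contains missing values; extract a gapless run first")
  v
}

# draw from a normal truncated below at `lower` by inverse-CDF sampling
rtrunc_norm <- function(n, mean, sd, lower = 0) {
  plo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, plo, 1)
  stats::qnorm(pmin(u, 1 - 1e-16), mean, sd)
}

# standardised (unit-variance) innovations from the supported families
draw_innovations <- function(n, dist = c("normal", "t", "ged"), shape = NULL) {
  dist <- match.arg(dist)
  switch(dist,
    normal = stats::rnorm(n),
    t = {
      df <- if (is.null(shape)) 8 else shape
      if (df <= 2) stop_param("t innovations need shape (df) > 2")
      stats::rt(n, df) * sqrt((df - 2) / df)
    },
    ged = {
      nu <- if (is.null(shape)) 1.5 else shape
      if (nu <= 0) stop_param("generalised-error shape must be positive")
      lam <- sqrt(2^(-2 / nu) * gamma(1 / nu) / gamma(3 / nu))
      y <- (2 * stats::rgamma(n, shape = 1 / nu))^(1 / nu)
      sign(stats::runif(n) - 0.5) * lam * y
    }
  )
}
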