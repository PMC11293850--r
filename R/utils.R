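#' Draw from a truncated normal distribution
#'
#' Inverse-CDF sampler for a Normal(mean, sd) restricted to `[lower, upper]`.
#' Used for prior draws of the trophic position and of the trophic
#' discrimination factor (TDF), whose supports are bounded.
#'
#' @param n number of draws.
#' @param mean,sd parameters of the untruncated normal (`sd > 0`).
#' @param lower,upper truncation bounds (may be infinite).
#' @return numeric vector of `n` draws in `[lower, upper]`.
#' @export
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper)
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

#' Log-density of a truncated normal
#'
#' @param x evaluation points.
#' @inheritParams rtruncnorm
#' @return log-density, `-Inf` outside the support.
#' @keywords internal
dtruncnorm_log <- function(x, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  lz <- log(stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd))
  out <- stats::dnorm(x, mean, sd, log = TRUE) - lz
  out[x < lower | x > upper] <- -Inf
  out
}

# Gaussian log-likelihood of a sample summarised by (n, mean, ss) where
# ss = sum((x - mean(x))^2); exact, avoids touching raw data in the sampler.
norm_loglik_suff <- function(n, xbar, ss, mu, sigma) {
  if (sigma <= 0) return(-Inf)
  -n * log(sigma) - (ss + n * (xbar - mu)^2) / (2 * sigma^2)
}

suff_stats <- function(x) {
  n <- length(x)
  xbar <- mean(x)
  list(n = n, mean = xbar, ss = sum((x - xbar)^2))
}

# Derive a per-chain / per-stage seed from the master seed, kept < 2^31.
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2048L + as.integer(k) %% 2048L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
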