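#' @title Adaptive random-walk Metropolis-within-Gibbs engine
#' @description
#' Generic component-wise sampler used by all trophic-position model
#' variants.  Each parameter is updated in turn by a Gaussian random-walk
#' Metropolis step; proposal scales adapt towards a target acceptance rate
#' of 0.44 (the 1-D optimum) during the adaptation phase only, and are
#' frozen afterwards so the post-adaptation chain satisfies detailed
#' balance.
#' @name mcmc-engine
NULL

# One chain.  log_post(theta) must return a finite value at `init`.
# support is a 2-column matrix (lower, upper) per parameter; proposals
# outside the support are rejected (density zero).
run_chain <- function(log_post, init, support, n_adapt, n_burn, n_iter,
                      init_scale = NULL) {
  p <- length(init)
  nm <- names(init)
  theta <- init
  lp <- log_post(theta)
  if (!is.finite(lp)) stop("log-posterior not finite at the initial state")
  ls <- log(init_scale %||% rep(0.5, p)) # log proposal sd per parameter
  acc <- integer(p)
  batch <- 50L
  n_tot <- n_adapt + n_burn + n_iter
  keep <- matrix(NA_real_, n_iter, p, dimnames = list(NULL, nm))
  accept_post <- integer(p)
  n_post <- 0L
  lo <- support[, 1]
  hi <- support[, 2]
  # innovations and acceptance thresholds are pre-generated per batch of
  # steps; this only reorders RNG consumption, determinism is unchanged
  for (t in seq_len(n_tot)) {
    z <- stats::rnorm(p)
    lu <- log(stats::runif(p))
    for (j in seq_len(p)) {
      old <- theta[j]
      cand <- old + exp(ls[j]) * z[j]
      if (cand < lo[j] || cand > hi[j]) next
      theta[j] <- cand
      lp_prop <- log_post(theta)
      if (is.finite(lp_prop) && lu[j] < lp_prop - lp) {
        lp <- lp_prop
        acc[j] <- acc[j] + 1L
        if (t > n_adapt + n_burn) accept_post[j] <- accept_post[j] + 1L
      } else {
        theta[j] <- old
      }
    }
    if (t <= n_adapt && t %% batch == 0L) {
      # Roberts & Rosenthal batch adaptation, vanishing step size
      delta <- min(0.1, 1 / sqrt(t / batch))
      ls <- ls + ifelse(acc / batch > 0.44, delta, -delta)
      acc <- integer(p)
    }
    if (t > n_adapt + n_burn) {
      n_post <- n_post + 1L
      keep[n_post, ] <- theta
    }
  }
  list(draws = keep, accept_rate = accept_post / max(1L, n_iter),
       proposal_sd = exp(ls))
}

#' Split-\eqn{\hat{R}} convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain trends are detected as well as between-chain
#' disagreement.
#'
#' @param chains list of numeric vectors, one per chain (equal lengths).
#' @return the split-\eqn{\hat{R}} statistic (1 at perfect mixing).
#' @export
split_rhat <- function(chains) {
  stopifnot(length(chains) >= 1)
  halves <- list()
  for (ch in chains) {
    n <- length(ch)
    h <- floor(n / 2)
    if (h < 2) return(NA_real_)
    halves <- c(halves, list(ch[seq_len(h)], ch[(n - h + 1):n]))
  }
  m <- length(halves)
  n <- length(halves[[1]])
  mu <- vapply(halves, mean, 0)
  s2 <- vapply(halves, stats::var, 0)
  W <- mean(s2)
  B <- n * stats::var(mu)
  if (W == 0) return(ifelse(B == 0, 1, Inf))
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Effective sample size of pooled MCMC draws
#'
#' Initial-positive-sequence estimator: the autocorrelation sum is truncated
#' at the first negative pair of consecutive lags (Geyer's rule), computed
#' per chain and summed.
#'
#' @param chains list of numeric vectors, one per chain.
#' @return estimated effective number of independent draws.
#' @export
ess <- function(chains) {
  per_chain <- vapply(chains, function(x) {
    n <- length(x)
    if (n < 4 || stats::var(x) == 0) return(NA_real_)
    rho <- stats::acf(x, lag.max = min(n - 2, 1000), plot = FALSE)$acf[-1]
    s <- 0
    k <- 1
    while (k < length(rho)) {
      pair <- rho[k] + rho[k + 1]
      if (pair < 0) break
      s <- s + pair
      k <- k + 2
    }
    n / (1 + 2 * s)
  }, 0)
  sum(per_chain)
}
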