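# Independent oracle for the one-baseline posterior: dense-grid quadrature
# over (TP, mu_d, mu_b) with the dispersions profiled at their sample
# values.  Shares no code with the sampler.
grid_median_oracle <- function(xc, xb, cfg = model_config()) {
  tp <- seq(cfg$tp_prior$min, cfg$tp_prior$max, length.out = 901)
  muD <- seq(0.5, 7, length.out = 401)
  muB <- seq(mean(xb) - 0.5, mean(xb) + 0.5, length.out = 81)
  sc <- sd(xc)
  sb <- sd(xb)
  lp_tp <- dnorm(tp, cfg$tp_prior$mean, cfg$tp_prior$sd, log = TRUE)
  lp_muD <- dnorm(muD, cfg$tdf_n$mean, cfg$tdf_n$sd, log = TRUE)
  nt <- cfg$tdf_n$n_obs
  if (nt > 0)
    lp_muD <- lp_muD - nt * (cfg$tdf_n$mean - muD)^2 / (2 * cfg$tdf_n$sd^2)
  dens <- matrix(0, length(tp), length(muD))
  for (k in seq_along(muB)) {
    lb <- -length(xb) * (mean(xb) - muB[k])^2 / (2 * sb^2)
    mc <- muB[k] + outer(tp - cfg$lambda, muD)
    lc <- -length(xc) * (mean(xc) - mc)^2 / (2 * sc^2)
    dens <- dens + exp(lb + lc + outer(lp_tp, lp_muD, "+"))
  }
  m <- rowSums(dens)
  cdf <- cumsum(m) / sum(m)
  tp[which.min(abs(cdf - 0.5))]
}

test_that("tp_point evaluates the closed form and rejects bad TDFs", {
  expect_equal(tp_point(10, 10, 3.4, 2), 2)
  expect_equal(tp_point(16.8, 10, 3.4, 2), 4)
  expect_error(tp_point(10, 10, 0), "tdf_n")
  expect_error(model_config(tdf_n = list(mean = -1, sd = 1, n_obs = 0)))
})

test_that("sampler agrees with the quadrature oracle away from the prior mean", {
  set.seed(61)
  xb <- rnorm(30, 10, 0.3)
  xc <- rnorm(40, 10 + 3.4 * 1.2, 0.3) # true TP = 3.2, off the prior mean
  cfg <- mid_config(seed = 61)
  f <- fit_one_baseline(xc, xb, cfg)
  expect_equal(median(f$draws), grid_median_oracle(xc, xb, cfg),
               tolerance = 0.03)
})

test_that("a consumer matching its baseline sits at the baseline level", {
  set.seed(62)
  xb <- rnorm(30, 10, 0.3)
  xc <- rnorm(30, 10, 0.3)
  f <- fit_one_baseline(xc, xb, mid_config(seed = 62))
  expect_equal(median(f$draws), 2.0, tolerance = 0.05)
  expect_true(all(f$draws > 1 & f$draws < 10))
})

test_that("identical seed, config and data give identical pooled draws", {
  set.seed(63)
  xb <- rnorm(10, 10, 0.3)
  xc <- rnorm(10, 12, 0.3)
  f1 <- fit_one_baseline(xc, xb, fast_config(seed = 7))
  f2 <- fit_one_baseline(xc, xb, fast_config(seed = 7))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$pooled_params, f2$pooled_params)
  f3 <- fit_one_baseline(xc, xb, fast_config(seed = 8))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("posterior recovery: small error and calibrated intervals", {
  # matched experiment: each dataset's true discrimination factor is drawn
  # from the sampling distribution of the meta-analytic TDF mean the model
  # conditions on, so nominal and actual interval coverage can agree
  n_rep <- 100
  err <- numeric(n_rep)
  cover <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(7000 + r)
    tp_true <- runif(1, 2.5, 4.5)
    tdf_true <- rnorm(1, 3.4, 0.98 / sqrt(56))
    xb <- rnorm(30, 8, 0.3)
    xc <- rnorm(30, true_consumer_mean(tp_true, 8, tdf_true, 2), 0.3)
    f <- fit_one_baseline(xc, xb, fast_config(seed = 7000 + r))
    med <- median(f$draws)
    ci <- quantile(f$draws, c(0.025, 0.975))
    err[r] <- abs(med - tp_true)
    cover[r] <- tp_true >= ci[1] && tp_true <= ci[2]
  }
  expect_lt(median(err), 0.1)
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("pooling thins evenly, interleaves chains and keeps means", {
  # chains occupy disjoint value ranges so membership identifies the source
  chains <- lapply(1:5, function(i) seq(1000 * i, by = 0.001,
                                        length.out = 10000))
  out <- pool_posterior(chains, 5000)
  expect_length(out, 5000)
  # 1000 per chain, chain-interleaved: first 5 entries are draw 1 of each
  expect_equal(out[1:5], vapply(chains, `[`, 0, 1))
  for (i in 1:5)
    expect_equal(sum(out %in% chains[[i]]), 1000)
  # identity when target equals the total
  two <- list(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sort(pool_posterior(two, 6)), 1:6)
  expect_error(pool_posterior(two, 10), "insufficient")
  # thinned mean stays close to the full mean on autocorrelated chains
  set.seed(64)
  ar <- lapply(1:3, function(i) as.numeric(arima.sim(list(ar = 0.9), 4000)))
  pooled <- pool_posterior(ar, 1200)
  full_mean <- mean(unlist(ar))
  se <- sd(unlist(ar)) / sqrt(ess(ar))
  expect_lt(abs(mean(pooled) - full_mean), 2 * se)
})

test_that("two-baseline mixing weight is identifiable from carbon", {
  set.seed(65)
  mkpool <- function(c13, n15, n = 30)
    data.frame(d13C = rnorm(n, c13, 0.3), d15N = rnorm(n, n15, 0.3))
  b1 <- mkpool(-18, 5)   # benthic
  b2 <- mkpool(-23, 5)   # pelagic, 5 permil depleted
  cons_on_b1 <- mkpool(-18, 5 + 3.4 * 1.5, 40)
  f <- fit_two_baseline(cons_on_b1, b1, b2, mid_config(seed = 65))
  alpha <- f$pooled_params[, "alpha"]
  expect_gt(median(alpha), 0.9)
  expect_length(f$draws, 3000)

  cons_mid <- mkpool(-20.5, 5 + 3.4 * 1.5, 40)
  f2 <- fit_two_baseline(cons_mid, b1, b2, mid_config(seed = 66))
  expect_equal(mean(f2$pooled_params[, "alpha"]), 0.5, tolerance = 0.1)
})

test_that("identical baselines raise the unidentifiability flag", {
  set.seed(67)
  b <- data.frame(d13C = rnorm(20, -18, 0.2), d15N = rnorm(20, 5, 0.2))
  cons <- data.frame(d13C = rnorm(20, -18, 0.2), d15N = rnorm(20, 10, 0.2))
  f <- fit_two_baseline(cons, b, b, fast_config(seed = 67))
  expect_match(f$flags, "unidentifiable", all = FALSE)
})

test_that("model comparison recommends the generating variant", {
  # data truly one-baseline (consumer on the benthic source)
  n_rep <- 12
  rec <- character(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(800 + r)
    b1 <- data.frame(d13C = rnorm(20, -18, 0.3), d15N = rnorm(20, 5, 0.3))
    b2 <- data.frame(d13C = rnorm(20, -23, 0.3), d15N = rnorm(20, 5, 0.3))
    cons <- data.frame(d13C = rnorm(30, -18, 0.3),
                       d15N = rnorm(30, 5 + 3.4 * 1.3, 0.3))
    f1 <- fit_one_baseline(cons$d15N, b1$d15N, fast_config(seed = 800 + r))
    f2 <- fit_two_baseline(cons, b1, b2, fast_config(seed = 800 + r))
    rec[r] <- compare_models(one_baseline = f1, two_baseline = f2)$recommendation
  }
  expect_gte(mean(rec == "one_baseline"), 0.9)

  # genuine 50/50 mixture: the two-baseline model must be recommended
  set.seed(820)
  b1 <- data.frame(d13C = rnorm(25, -18, 0.3), d15N = rnorm(25, 5, 0.3))
  b2 <- data.frame(d13C = rnorm(25, -24, 0.3), d15N = rnorm(25, 8, 0.3))
  cons <- data.frame(d13C = rnorm(40, -21, 0.3),
                     d15N = rnorm(40, 6.5 + 3.4 * 1.3, 0.3))
  f1 <- fit_one_baseline(cons$d15N, b1$d15N, mid_config(seed = 820))
  f2 <- fit_two_baseline(cons, b1, b2, mid_config(seed = 821))
  cmp <- compare_models(one_baseline = f1, two_baseline = f2)
  expect_equal(cmp$recommendation, "two_baseline")

  # single fit degenerates to that variant
  expect_equal(compare_models(one_baseline = f1)$recommendation,
               "one_baseline")
  # mismatched consumer data across fits is an error
  set.seed(821)
  other <- fit_one_baseline(rnorm(10, 12, 0.3), rnorm(10, 5, 0.3),
                            fast_config(seed = 9))
  expect_error(compare_models(a = f1, b = other), "same consumer data")
})
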