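# Exhaustive enumeration oracles for the rank tests, independent of stats::
kw_H_oracle <- function(groups) {
  x <- unlist(groups)
  r <- rank(x)
  n <- length(x)
  splits <- split(r, rep(seq_along(groups), lengths(groups)))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(splits, function(ri) sum(ri)^2 / length(ri), 0)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

wilcox_p_oracle <- function(a, b) {
  # two-sided exact p by enumerating all assignments of the pooled sample
  pool <- c(a, b)
  na <- length(a)
  u_obs <- sum(rank(pool)[seq_len(na)]) - na * (na + 1) / 2
  combos <- combn(length(pool), na)
  u_all <- apply(combos, 2, function(ia)
    sum(rank(pool)[ia]) - na * (na + 1) / 2)
  mu <- na * length(b) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

test_that("normality screen accepts gaussians and rejects skewed draws", {
  ok <- 0L
  bad <- 0L
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    set.seed(2000 + r)
    if (normality_screen(rnorm(500))$p > 0.05) ok <- ok + 1L
    if (normality_screen(rexp(500))$p < 0.001) bad <- bad + 1L
  }
  expect_gte(ok / n_rep, 0.90)
  expect_gte(bad / n_rep, 0.95)
  expect_error(normality_screen(rep(1, 10)), "constant")
  expect_error(normality_screen(c(1, 2)), "n >= 3")
  # large samples are subsampled, not refused
  set.seed(1)
  expect_no_error(normality_screen(rnorm(20000)))
})

test_that("Kruskal-Wallis matches the rank-sum formula and handles ties", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))$H, 3.857143,
               tolerance = 1e-6)
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))$H,
               kw_H_oracle(list(c(1, 2, 3), c(4, 5, 6))))
  same <- list(rep(2, 3), rep(2, 4), rep(2, 3), rep(2, 5))
  expect_equal(kruskal_wallis(same), list(H = 0, df = 3, p = 1))
  set.seed(41)
  for (r in 1:5) {
    g <- list(rnorm(6), rnorm(5), rnorm(7))
    expect_equal(kruskal_wallis(g)$H, kw_H_oracle(g), tolerance = 1e-9)
  }
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
})

test_that("pairwise Wilcoxon agrees with exhaustive enumeration", {
  p <- pairwise_wilcoxon(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(p["a", "b"], 0.1)
  expect_equal(p["a", "b"], wilcox_p_oracle(c(1, 2, 3), c(4, 5, 6)))
  set.seed(42)
  for (r in 1:5) {
    a <- rnorm(5)
    b <- rnorm(6)
    expect_equal(pairwise_wilcoxon(list(a = a, b = b))["a", "b"],
                 wilcox_p_oracle(a, b), tolerance = 1e-9)
  }
  # identical groups: p = 1
  z <- rnorm(50)
  expect_equal(pairwise_wilcoxon(list(a = z, b = z))["a", "b"], 1)
  # normal approximation close to exact at moderate n
  set.seed(43)
  a <- rnorm(20)
  b <- rnorm(20, 0.3)
  p_exact <- suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value)
  p_approx <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                           correct = TRUE)$p.value)
  expect_equal(p_exact, p_approx, tolerance = 0.01)
  # holm adjustment is monotone and >= unadjusted
  g3 <- list(a = rnorm(10), b = rnorm(10, 1), c = rnorm(10, 2))
  p0 <- pairwise_wilcoxon(g3, adjust = "none")
  ph <- pairwise_wilcoxon(g3, adjust = "holm")
  expect_true(all(ph >= p0, na.rm = TRUE))
  expect_error(pairwise_wilcoxon(list(a = numeric(0), b = 1:3)), "empty")
})

test_that("quantile test is powered, calibrated and safe on identical input", {
  set.seed(44)
  a <- rnorm(5000)
  expect_equal(quantile95_test(a, a)$p, 1)
  expect_error(quantile95_test(rnorm(100), rnorm(100)), "undersized")

  hits <- 0L
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    set.seed(3000 + r)
    q <- quantile95_test(rnorm(5000), rnorm(5000, 0.5))
    if (q$p < 0.001) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)

  # null samples at the pooled posterior size used throughout (5000), where the
  # continuity-corrected statistic sits at its nominal level
  rej <- 0L
  n_null <- 500
  for (r in seq_len(n_null)) {
    set.seed(4000 + r)
    q <- quantile95_test(rnorm(5000), rnorm(5000))
    if (q$p <= 0.05) rej <- rej + 1L
  }
  expect_gte(rej / n_null, 0.02)
  expect_lte(rej / n_null, 0.09)
})

test_that("summaries use interpolated quantiles and are order-invariant", {
  s <- summarize_posteriors(list(A = c(1, 2, 3, 4, 5)))
  expect_equal(s$median, 3)
  expect_equal(s$min, 1)
  expect_equal(s$max, 5)
  set.seed(45)
  x <- rnorm(1001) # odd n: the median is an exact order statistic
  s1 <- summarize_posteriors(list(A = x))
  s2 <- summarize_posteriors(list(A = sort(x)))
  expect_equal(s1, s2)
  # monotone transformation moves the median equivariantly
  s3 <- summarize_posteriors(list(A = exp(x)))
  expect_equal(s3$median, exp(s1$median), tolerance = 1e-12)
  expect_true(with(s1, min <= q25 && q25 <= median && median <= q75 &&
                     q75 <= max))
})

test_that("ordering strings follow medians and pairwise significance", {
  med <- c(GC = 3.49, GP = 3.49, GS = 3.11, GT = 3.05)
  p <- matrix(1e-4, 4, 4, dimnames = list(names(med), names(med)))
  p["GC", "GP"] <- p["GP", "GC"] <- 0.4
  s <- ordering_string(med, p, fra_areas = c("GC", "GP"))
  expect_equal(as.character(s), "GC=GP>GS>GT")
  expect_true(attr(s, "emphasis"))

  p_all_ns <- matrix(0.5, 4, 4, dimnames = dimnames(p))
  s2 <- ordering_string(med, p_all_ns, fra_areas = c("GC", "GP"))
  expect_equal(as.character(s2), "GC=GP=GS=GT")
  expect_false(attr(s2, "emphasis"))

  s3 <- ordering_string(c(A = 2, B = 1),
                        matrix(c(NA, 0.01, 0.01, NA), 2, 2,
                               dimnames = list(c("A", "B"), c("A", "B"))),
                        fra_areas = "A")
  expect_equal(as.character(s3), "A>B")
  expect_error(ordering_string(med, p[1:3, 1:3], "GC"), "missing pairwise")
})

test_that("response classification nests strong within intermediate", {
  mk_cr <- function(draw_shift, seed = 46) {
    set.seed(seed)
    draws <- list(GC = rnorm(5000, 4.0, 0.12), GP = rnorm(5000, 4.0, 0.12),
                  GS = rnorm(5000, 4.0 - draw_shift, 0.12),
                  GT = rnorm(5000, 4.0 - draw_shift, 0.12))
    prot <- c(GC = "fra", GP = "fra", GS = "trawled", GT = "trawled")
    compare_areas(area_posteriors(draws, prot, species = "MUT"))
  }
  cr_strong <- mk_cr(0.5)
  expect_equal(cr_strong$response_class, "strong")
  expect_equal(cr_strong$erosion_dTP, 0.5, tolerance = 0.02)
  expect_true(attr(cr_strong$ordering_median, "emphasis"))

  # forced intermediate: one trawled maximum raised above the FRA maxima
  cr_mid <- mk_cr(0.5)
  cr_mid$maxima["GS"] <- cr_mid$maxima["GC"] + 1
  expect_equal(classify_response(cr_mid, c("GC", "GP"), c("GS", "GT")),
               "intermediate")

  # null truth: classification is almost always none
  n_rep <- 100
  none <- 0L
  for (r in seq_len(n_rep)) {
    cr0 <- mk_cr(0, seed = 5000 + r)
    if (cr0$response_class == "none") none <- none + 1L
  }
  expect_gte(none / n_rep, 0.90)
})

test_that("erosion effect is the difference of group mean medians", {
  cr <- list(medians = c(GC = 4, GP = 4, GS = 3.5, GT = 3.5))
  expect_equal(erosion_effect(cr, c("GC", "GP"), c("GS", "GT")), 0.5)
  expect_equal(erosion_effect(cr, c("GC", "GP"), c("GC", "GP")), 0)
  expect_error(erosion_effect(cr, character(0), "GS"), "at least one")
})

test_that("comparison results carry the i.i.d.-draws advisory", {
  set.seed(47)
  draws <- list(GC = rnorm(1000, 4, 0.1), GT = rnorm(1000, 3.5, 0.1))
  cr <- compare_areas(area_posteriors(
    draws, c(GC = "fra", GT = "trawled"), species = "HAK"))
  expect_match(cr$advisory, "autocorrelated")
  expect_true(cr$kw_p >= 0 && cr$kw_p <= 1)
})
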