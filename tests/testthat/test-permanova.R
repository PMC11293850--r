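# Independent oracle: direct sums-of-squares partition for a one-way layout
# from first principles, SS_total = (1/N) sum_{i<j} d^2 and within-group
# SS via per-group (1/n_g) sums, without hat matrices.
oneway_F_oracle <- function(d, groups) {
  d2 <- d^2
  n <- nrow(d)
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_a <- ss_tot - ss_w
  k <- length(unique(groups))
  (ss_a / (k - 1)) / (ss_w / (n - k))
}

test_that("distance metrics behave as defined", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  d <- distance_matrix(x, "euclidean")
  expect_equal(d[1, 2], 1)
  expect_equal(d[1, 3], 10)
  expect_equal(diag(unclass(d)), rep(0, 4))
  expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)

  dup <- distance_matrix(rbind(c(-18, 12), c(-18, 12)), "bray_curtis_shifted")
  expect_equal(dup[1, 2], 0)

  set.seed(4)
  y <- cbind(d13C = rnorm(12, -18), d15N = rnorm(12, 9))
  d1 <- distance_matrix(y, "bray_curtis_shifted")
  y2 <- y
  y2[, "d13C"] <- y2[, "d13C"] + 100 # shift invariance per variable
  d2 <- distance_matrix(y2, "bray_curtis_shifted")
  expect_equal(unclass(d1), unclass(d2), tolerance = 1e-12)
})

test_that("hand-computable 1-D example gives F = 200 and exhaustive p = 1/3", {
  dm <- distance_matrix(matrix(c(0, 1, 10, 11), ncol = 1), "euclidean")
  g <- factor(c("a", "a", "b", "b"))
  r <- permanova(dm, g, exhaustive = TRUE)
  expect_equal(r$pseudo_F, 200)
  expect_equal(r$p, 1 / 3)
  expect_equal(r$df_num, 1)
  expect_equal(r$df_den, 2)
  tab <- r$ss_table
  expect_equal(tab$ss[tab$term == "design"], 100)
  expect_equal(tab$ss[tab$term == "residual"], 1)
  expect_equal(tab$ss[tab$term == "total"], 101)
})

test_that("pseudo-F matches an independent partition oracle and vegan", {
  set.seed(21)
  for (rep in 1:5) {
    x <- matrix(rnorm(30), 15, 2)
    g <- factor(sample(rep(c("a", "b", "c"), each = 5)))
    d <- distance_matrix(x, "euclidean")
    r <- permanova(d, g, n_perm = 19, seed = rep)
    expect_equal(r$pseudo_F, oneway_F_oracle(unclass(d), g), tolerance = 1e-9)
  }
  x <- matrix(rnorm(40), 20, 2)
  g <- factor(rep(c("a", "b"), each = 10))
  r <- permanova(distance_matrix(x, "euclidean"), g, n_perm = 99, seed = 1)
  ad <- vegan::adonis2(dist(x) ~ g, permutations = 99)
  expect_equal(r$pseudo_F, ad$F[1], tolerance = 1e-9)
})

test_that("permutation p agrees with brute-force enumeration at small N", {
  set.seed(31)
  for (rep in 1:4) {
    x <- matrix(rnorm(14), 7, 2)
    g <- factor(c("a", "a", "a", "b", "b", "b", "b"))
    d <- distance_matrix(x, "bray_curtis_shifted")
    r_ex <- permanova(d, g, exhaustive = TRUE)
    # oracle: recompute F over every assignment with the direct formula
    perms <- combn(7, 3, simplify = FALSE)
    f_all <- vapply(perms, function(ia) {
      gg <- rep("b", 7)
      gg[ia] <- "a"
      oneway_F_oracle(unclass(d), gg)
    }, 0)
    f_obs <- oneway_F_oracle(unclass(d), as.character(g))
    expect_equal(r_ex$p, mean(f_all >= f_obs - 1e-12), tolerance = 1e-12)
    expect_equal(r_ex$n_perm, choose(7, 3))
  }
})

test_that("sums of squares are conserved and invariant to relabeling", {
  sim <- generate_survey(default_scenario(n_per_group = 4L, seed = 6))
  base <- as.data.frame(sim$dataset[sim$dataset$role != "consumer", ])
  d <- distance_matrix(base[, c("d13C", "d15N")])
  design <- data.frame(trawl = ifelse(base$protection == "trawled", "yes", "no"),
                       area = base$area, taxon = base$taxon)
  r <- permanova(d, design, n_perm = 49, seed = 2)
  tab <- r$ss_table
  ss_terms <- sum(tab$ss[!tab$term %in% "total"])
  expect_equal(ss_terms, tab$ss[tab$term == "total"], tolerance = 1e-9)
  expect_equal(r$df_num, 6) # (taxa-1) x (areas - trawl levels) = 3 x 2

  # relabeling samples consistently leaves the statistic unchanged
  perm <- sample(nrow(base))
  r2 <- permanova(unclass(d)[perm, perm], design[perm, ], n_perm = 49, seed = 2)
  expect_equal(r2$pseudo_F, r$pseudo_F, tolerance = 1e-9)
})

test_that("exhaustive p is invariant to relabeling that preserves groups", {
  set.seed(13)
  x <- matrix(rnorm(12), 6, 2)
  g <- factor(c("a", "a", "a", "b", "b", "b"))
  d <- distance_matrix(x, "euclidean")
  r <- permanova(d, g, exhaustive = TRUE)
  perm <- sample(6)
  r2 <- permanova(unclass(d)[perm, perm], g[perm], exhaustive = TRUE)
  expect_equal(r2$p, r$p, tolerance = 1e-12)
  expect_equal(r2$pseudo_F, r$pseudo_F, tolerance = 1e-9)
})

test_that("incomplete nested layouts fall back to one-way with a warning", {
  sim <- generate_survey(default_scenario(n_per_group = 4L, seed = 8))
  base <- as.data.frame(sim$dataset[sim$dataset$role != "consumer", ])
  drop <- !(base$area == "GC" & base$taxon == "ZOO")
  base <- base[drop, ]
  d <- distance_matrix(base[, c("d13C", "d15N")])
  design <- data.frame(trawl = ifelse(base$protection == "trawled", "yes", "no"),
                       area = base$area, taxon = base$taxon)
  expect_warning(r <- permanova(d, design, n_perm = 19, seed = 1),
                 "incomplete")
  expect_equal(r$term, "design")
})

test_that("type-I error of the permutation test is calibrated", {
  n_rep <- 200
  rej <- 0L
  set.seed(99)
  for (r in seq_len(n_rep)) {
    x <- matrix(rnorm(36), 18, 2) # two groups from one distribution
    g <- factor(rep(c("a", "b"), each = 9))
    res <- permanova(distance_matrix(x, "euclidean"), g,
                     n_perm = 199, seed = 10000 + r)
    if (res$p <= 0.05) rej <- rej + 1L
  }
  expect_gte(rej / n_rep, 0.02)
  expect_lte(rej / n_rep, 0.09)
})
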