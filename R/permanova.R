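#' Pairwise dissimilarity matrix of isotope samples
#'
#' Bray-Curtis is undefined on signed delta values, so the default metric
#' first translates each variable by its global minimum (all values become
#' `>= 0`) and then applies `d(i,j) = sum|xi - xj| / sum(xi + xj)`; the
#' result is invariant to adding a constant to a variable.  `euclidean`
#' uses the raw delta values.  Two all-zero samples (0/0 under Bray-Curtis)
#' are defined to be at distance 0.
#'
#' @param x numeric matrix or data.frame, one row per sample (e.g. columns
#'   `d13C`, `d15N`); row names become labels.
#' @param metric `"bray_curtis_shifted"` or `"euclidean"`.
#' @return a `distance_matrix`: symmetric nonnegative matrix with zero
#'   diagonal and a `metric` attribute.
#' @export
distance_matrix <- function(x, metric = c("bray_curtis_shifted", "euclidean")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (!all(is.finite(x))) stop("non-finite values in sample matrix")
  n <- nrow(x)
  if (metric == "euclidean") {
    d <- as.matrix(stats::dist(x))
  } else {
    xs <- sweep(x, 2, apply(x, 2, min)) # translate each variable to >= 0
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      num <- sum(abs(xs[i, ] - xs[j, ]))
      den <- sum(xs[i, ] + xs[j, ])
      d[i, j] <- d[j, i] <- if (den == 0) 0 else num / den
    }
  }
  dimnames(d) <- list(rownames(x), rownames(x))
  structure(d, metric = metric, class = c("distance_matrix", "matrix"))
}

# Gower-centred inner-product matrix of squared dissimilarities;
# tr(G) = SS_total = (1/N) sum_{i<j} d_ij^2.
gower_center <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(a)
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

# Sequential (Type I) hat matrices for the nested three-factor design
# trawl / area(trawl) / taxon.  Returns a list of hat matrices of
# increasing span and the term labels/dfs.
build_terms <- function(design) {
  design <- as.data.frame(design)
  for (k in names(design)) design[[k]] <- factor(design[[k]])
  if (ncol(design) == 1) {
    forms <- list(stats::as.formula(paste("~", names(design))))
    labels <- names(design)
  } else if (all(c("trawl", "area", "taxon") %in% names(design))) {
    forms <- list(~trawl, ~trawl + area, ~trawl + area + taxon,
                  ~trawl + area + taxon + trawl:taxon,
                  ~trawl + area + taxon + trawl:taxon + area:taxon)
    labels <- c("trawl", "area(trawl)", "taxon", "trawl:taxon",
                "taxon:area(trawl)")
  } else {
    stop("design must be a single factor or have columns trawl, area, taxon")
  }
  hats <- vector("list", length(forms))
  ranks <- integer(length(forms))
  for (i in seq_along(forms)) {
    X <- stats::model.matrix(forms[[i]], design)
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    hats[[i]] <- tcrossprod(Q)
    ranks[i] <- q$rank
  }
  list(hats = hats, labels = labels, ranks = ranks, design = design)
}

all_group_assignments <- function(groups) {
  # all distinct assignments of samples to the observed group slots, as
  # index vectors usable to permute the distance matrix; within-group order
  # is irrelevant to the statistic so one ordering per combination suffices
  fg <- factor(groups, levels = unique(as.character(groups)))
  pos <- split(seq_along(groups), fg) # positions per group, level order
  sizes <- lengths(pos)
  recurse <- function(remaining, k) {
    if (k > length(sizes)) return(list(integer(0)))
    out <- list()
    for (f in utils::combn(remaining, sizes[k], simplify = FALSE))
      for (rest in recurse(setdiff(remaining, f), k + 1))
        out[[length(out) + 1L]] <- c(f, rest)
    out
  }
  lapply(recurse(seq_along(groups), 1), function(perm) {
    out <- integer(length(groups))
    out[unlist(pos)] <- perm
    out
  })
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Distance-based partition of sums of squares (Gower-centred matrix with
#' sequential hat-matrix projections), with a permutation test of one term.
#' Supports a one-way design (a single grouping factor) and the nested
#' three-factor design used for baseline screening: `trawl` (2 levels),
#' `area` nested in trawl, and `taxon`, with sequential terms trawl,
#' area(trawl), taxon, trawl:taxon and taxon:area(trawl).
#'
#' The pseudo-F for the tested term is
#' `(SS_term/df_num) / (SS_resid/df_den)`.  The permutation p-value uses
#' the `(1 + b)/(1 + m)` convention so it is never exactly zero; with
#' `exhaustive = TRUE` (one-way only) all distinct label assignments are
#' enumerated and `p = #\{F* >= F\}/#assignments`.  Permutations are
#' unrestricted for one-way designs and for `trawl`; any other term of the
#' nested design is tested with permutations restricted within levels of
#' the nesting parent (trawl).  Incomplete nested layouts (empty
#' area x taxon cells) fall back, with a warning, to a one-way analysis on
#' the area-taxon cell factor.
#'
#' @param dm a [distance_matrix()] (or any symmetric dissimilarity matrix).
#' @param design grouping factor, or data.frame with columns
#'   `trawl`, `area`, `taxon`.
#' @param term which term to test (default: the single factor, or the
#'   highest-order interaction `"taxon:area(trawl)"` for nested designs).
#' @param n_perm number of random permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param exhaustive enumerate all assignments instead of sampling
#'   (one-way, small samples).
#' @return a `permanova_result`: `pseudo_F`, `df_num`, `df_den`, `p`,
#'   `n_perm`, `term`, and an anova-style table `ss_table` of all terms
#'   (SS conservation holds: terms + residual = total).
#' @export
permanova <- function(dm, design, term = NULL, n_perm = 999, seed = 1,
                      exhaustive = FALSE) {
  d <- unclass(as.matrix(dm))
  n <- nrow(d)
  if (is.data.frame(design) && ncol(design) > 1) {
    df_design <- as.data.frame(design)
    complete <- all(table(df_design$area, df_design$taxon) > 0)
    if (!complete) {
      warning("incomplete nested layout; falling back to one-way on the ",
              "area-taxon cell factor")
      design <- interaction(df_design$area, df_design$taxon, drop = TRUE)
    }
  }
  tb <- build_terms(design)
  if (nrow(tb$design) != n) stop("design rows must match distance matrix size")
  if (is.null(term))
    term <- tb$labels[length(tb$labels)]
  ti <- match(term, tb$labels)
  if (is.na(ti)) stop("unknown term: ", term, "; available: ",
                      paste(tb$labels, collapse = ", "))
  if (ncol(tb$design) == 1 && nlevels(tb$design[[1]]) < 2)
    stop("tested term must have >= 2 levels")
  if (n_perm < 1) stop("n_perm must be >= 1")

  G <- gower_center(d)
  ss_total <- sum(diag(G))
  prev_rank <- 1L # intercept
  ss <- numeric(length(tb$labels))
  df <- integer(length(tb$labels))
  prev_hat <- matrix(1 / n, n, n)
  for (i in seq_along(tb$labels)) {
    ss[i] <- sum((tb$hats[[i]] - prev_hat) * G) # tr((Hi - Hprev) G)
    df[i] <- tb$ranks[i] - prev_rank
    prev_hat <- tb$hats[[i]]
    prev_rank <- tb$ranks[i]
  }
  if (df[ti] < 1)
    stop("tested term '", term, "' has no degrees of freedom in this design")
  h_full <- tb$hats[[length(tb$hats)]]
  ss_res <- sum((diag(n) - h_full) * G)
  df_res <- n - tb$ranks[length(tb$ranks)]
  if (df_res < 1) stop("no residual degrees of freedom for the design")
  f_stat <- function(Gp) {
    h_lo <- if (ti == 1) matrix(1 / n, n, n) else tb$hats[[ti - 1]]
    ss_t <- sum((tb$hats[[ti]] - h_lo) * Gp)
    ss_r <- sum((diag(n) - h_full) * Gp)
    (ss_t / df[ti]) / (ss_r / df_res)
  }
  f_obs <- f_stat(G)

  # permutation strata: restricted within the nesting parent except for
  # one-way designs and the top-level factor itself
  strata <- if (ncol(tb$design) > 1 && term != "trawl")
    tb$design$trawl else factor(rep(1, n))
  perm_indices <- function() {
    idx <- seq_len(n)
    for (lv in levels(strata)) {
      w <- which(strata == lv)
      idx[w] <- w[sample.int(length(w))]
    }
    idx
  }
  if (exhaustive) {
    if (ncol(tb$design) > 1) stop("exhaustive enumeration is one-way only")
    perms <- all_group_assignments(tb$design[[1]])
    f_perm <- vapply(perms, function(pm) f_stat(G[pm, pm]), 0)
    p <- mean(f_perm >= f_obs - 1e-12)
    n_perm <- length(perms)
  } else {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      pm <- perm_indices()
      if (f_stat(G[pm, pm]) >= f_obs - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_perm)
  }
  ss_table <- data.frame(
    term = c(tb$labels, "residual", "total"),
    df = c(df, df_res, n - 1),
    ss = c(ss, ss_res, ss_total))
  structure(list(term = term, pseudo_F = f_obs, df_num = df[ti],
                 df_den = df_res, p = p, n_perm = n_perm,
                 ss_table = ss_table),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA term %s: pseudo-F(%d,%d) = %.3f, p = %.4g (%d permutations)\n",
              x$term, x$df_num, x$df_den, x$pseudo_F, x$p, x$n_perm))
  print(x$ss_table, row.names = FALSE)
  invisible(x)
}
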