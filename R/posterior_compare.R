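#' @title Comparing posterior trophic-position distributions across areas
#' @description
#' Implements the test battery applied to pooled posterior TP draws
#' (n = 5000 per species and area): Shapiro-Wilk normality pre-checks,
#' Kruskal-Wallis across areas, pairwise Wilcoxon (Mann-Whitney) tests,
#' two-sample 95th-percentile quantile tests, maxima ranking, Table-style
#' ordering strings, and a response classification (none / intermediate /
#' strong) for the fishery-restricted versus trawled contrast.
#'
#' Advisory: treating MCMC draws as independent observations inflates test
#' statistics; the battery applies the conventional procedure and attaches
#' this advisory to its results rather than correcting for it.
#' @name posterior-compare
NULL

ADVISORY <- paste(
  "posterior draws are autocorrelated MCMC samples;",
  "rank and quantile tests treating them as i.i.d. observations",
  "overstate evidence against the null")

#' Shapiro-Wilk normality pre-check
#'
#' Standard Royston-approximation Shapiro-Wilk test; samples larger than
#' 5000 are evenly subsampled to 5000 (the test's supported maximum).
#'
#' @param draws numeric sample, `n >= 3`, non-constant.
#' @return list with `W` and `p`.
#' @export
normality_screen <- function(draws) {
  if (length(draws) < 3) stop("need n >= 3")
  if (stats::var(draws) == 0) stop("constant sample: W undefined")
  if (length(draws) > 5000)
    draws <- draws[unique(round(seq(1, length(draws), length.out = 5000)))]
  ht <- stats::shapiro.test(draws)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected H with a chi-squared reference on k - 1 degrees of
#' freedom.  If every observation is identical the statistic is 0 and
#' p = 1 by convention.
#'
#' @param groups list of `>= 2` numeric samples.
#' @return list with `H`, `df` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3) stop("need >= 3 observations in total")
  if (stats::var(x) == 0)
    return(list(H = 0, df = length(groups) - 1, p = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::kruskal.test(x, g)
  list(H = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Pairwise Wilcoxon (Mann-Whitney) tests
#'
#' Two-sided tests for every pair of groups: exact enumeration for small
#' tie-free samples, normal approximation with tie and continuity
#' correction otherwise (the standard switch at n = 50).  A group compared
#' with an identical copy gives p = 1.
#'
#' @param groups named list of numeric samples.
#' @param adjust `"none"` (default: report raw pairwise p-values) or
#'   `"holm"`.
#' @return symmetric matrix of p-values (diagonal NA).
#' @export
pairwise_wilcoxon <- function(groups, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (any(lengths(groups) < 1)) stop("empty group")
  k <- length(groups)
  nm <- names(groups) %||% as.character(seq_len(k))
  p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- groups[[i]]
    b <- groups[[j]]
    pv <- if (identical(a, b)) 1
    else suppressWarnings(stats::wilcox.test(a, b)$p.value)
    p[i, j] <- p[j, i] <- pv
  }
  if (adjust == "holm") {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], "holm")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  p
}

#' Two-sample quantile test
#'
#' Mood-type construction for a difference at quantile `q` (default the
#' 95th percentile): both samples are pooled, the pooled `q`-quantile
#' (linear interpolation) is computed, and the 2x2 table of exceedances
#' (above vs not above, per sample) is tested by chi-squared with
#' continuity correction, or by Fisher's exact test when any expected cell
#' count is below 5.
#'
#' @param a,b numeric samples, each of size `>= 20 / (1 - q)` so the tail
#'   is populated.
#' @param q tested quantile in (0, 1), default 0.95.
#' @return list with `statistic` (chi-squared, NA for Fisher), `p`,
#'   `method`, and the exceedance `table`.
#' @export
quantile95_test <- function(a, b, q = 0.95) {
  stopifnot(q > 0, q < 1)
  n_min <- 20 / (1 - q)
  if (length(a) < n_min || length(b) < n_min)
    stop("undersized samples: need n >= ", ceiling(n_min), " per sample")
  thr <- stats::quantile(c(a, b), q, names = FALSE) # type 7
  tab <- rbind(a = c(above = sum(a > thr), not_above = sum(a <= thr)),
               b = c(above = sum(b > thr), not_above = sum(b <= thr)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ht <- stats::fisher.test(tab)
    list(statistic = NA_real_, p = ht$p.value, method = "fisher", table = tab)
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    list(statistic = unname(ht$statistic), p = ht$p.value,
         method = "chisq", table = tab)
  }
}

#' Bundle per-area posterior draws for one species
#'
#' @param draws named list (area code -> numeric vector) of pooled
#'   posterior TP draws, equal lengths, `>= 2` areas.
#' @param protection named character vector mapping each area to `"fra"` or
#'   `"trawled"`.
#' @param species optional species code.
#' @return an `area_posteriors` object.
#' @export
area_posteriors <- function(draws, protection, species = NULL) {
  stopifnot(length(draws) >= 2, !is.null(names(draws)),
            length(unique(lengths(draws))) == 1,
            all(names(draws) %in% names(protection)),
            all(protection[names(draws)] %in% PROTECTIONS))
  structure(list(draws = draws,
                 protection = protection[names(draws)],
                 species = species),
            class = "area_posteriors")
}

#' Per-area posterior summary metrics
#'
#' Median, quartiles, extremes and the 95th percentile per area, using
#' linear-interpolation quantiles (R type 7) throughout so summaries are
#' reproducible bit-for-bit from the same draws.
#'
#' @param ap an [area_posteriors()] object (or named list of draw vectors).
#' @return data.frame with one row per area: `area`, `median`, `q25`,
#'   `q75`, `min`, `max`, `q95`.
#' @export
summarize_posteriors <- function(ap) {
  draws <- if (inherits(ap, "area_posteriors")) ap$draws else ap
  out <- do.call(rbind, lapply(names(draws), function(a) {
    x <- draws[[a]]
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75, 0.95), names = FALSE)
    data.frame(area = a, median = qs[2], q25 = qs[1], q75 = qs[3],
               min = min(x), max = max(x), q95 = qs[4])
  }))
  rownames(out) <- NULL
  out
}

#' Table-style ordering string of areas
#'
#' Areas sorted descending by a statistic; adjacent areas are joined by
#' `"="` when their pairwise test is non-significant at `alpha`, by `">"`
#' otherwise (e.g. `"GC=GP>GS>GT"`).  The `emphasis` attribute is TRUE
#' when both fishery-restricted areas significantly exceed both trawled
#' areas (the condition conventionally typeset in bold in summary tables).
#'
#' @param stat named numeric vector (area -> statistic, e.g. medians).
#' @param pairwise symmetric matrix of pairwise p-values (areas in
#'   dimnames).
#' @param fra_areas codes of the fishery-restricted areas.
#' @param alpha significance level (default 0.05).
#' @return character scalar with attribute `emphasis`.
#' @export
ordering_string <- function(stat, pairwise, fra_areas, alpha = 0.05) {
  areas <- names(sort(stat, decreasing = TRUE))
  if (!all(areas %in% rownames(pairwise)) || !all(areas %in% colnames(pairwise)))
    stop("missing pairwise entry for some area")
  sep <- vapply(seq_len(length(areas) - 1), function(i) {
    pv <- pairwise[areas[i], areas[i + 1]]
    if (is.na(pv)) stop("missing pairwise entry: ", areas[i], "-", areas[i + 1])
    if (pv < alpha) ">" else "="
  }, "")
  s <- paste0(areas[1], paste0(sep, areas[-1], collapse = ""))
  trawled <- setdiff(names(stat), fra_areas)
  emph <- length(fra_areas) > 0 && length(trawled) > 0 &&
    all(vapply(fra_areas, function(f) all(vapply(trawled, function(t)
      stat[f] > stat[t] && pairwise[f, t] < alpha, TRUE)), TRUE))
  attr(s, "emphasis") <- emph
  s
}

#' Full cross-area comparison for one species
#'
#' Runs the battery on an [area_posteriors()] bundle: Shapiro-Wilk
#' pre-checks, Kruskal-Wallis across areas, pairwise Wilcoxon on the
#' draws, pairwise quantile tests at `q`, per-area summaries, ordering
#' strings for the median and the 95th percentile, the maxima ranking,
#' and the response classification.
#'
#' @param ap an [area_posteriors()] object.
#' @param alpha significance level (default 0.05).
#' @param adjust p-value adjustment for pairwise tests (`"none"` default).
#' @param q upper quantile tested (default 0.95).
#' @return a `comparison_result` list; see [classify_response()] and
#'   [erosion_effect()].
#' @export
compare_areas <- function(ap, alpha = 0.05, adjust = "none", q = 0.95) {
  stopifnot(inherits(ap, "area_posteriors"))
  draws <- ap$draws
  fra <- names(ap$protection)[ap$protection == "fra"]
  trawled <- names(ap$protection)[ap$protection == "trawled"]
  shapiro <- lapply(draws, normality_screen)
  kw <- kruskal_wallis(draws)
  pw <- pairwise_wilcoxon(draws, adjust = adjust)
  areas <- names(draws)
  qp <- matrix(NA_real_, length(areas), length(areas),
               dimnames = list(areas, areas))
  for (i in seq_len(length(areas) - 1)) for (j in (i + 1):length(areas)) {
    qt <- quantile95_test(draws[[i]], draws[[j]], q = q)
    qp[i, j] <- qp[j, i] <- qt$p
  }
  summary <- summarize_posteriors(ap)
  med <- stats::setNames(summary$median, summary$area)
  q95 <- stats::setNames(summary$q95, summary$area)
  mx <- stats::setNames(summary$max, summary$area)
  cr <- structure(list(
    species = ap$species,
    protection = ap$protection,
    shapiro = shapiro,
    kw_chi2 = kw$H, kw_df = kw$df, kw_p = kw$p,
    pairwise_wilcoxon = pw,
    quantile95 = qp,
    summary = summary,
    medians = med, p95s = q95, maxima = mx,
    ordering_median = ordering_string(med, pw, fra, alpha),
    ordering_q95 = ordering_string(q95, qp, fra, alpha),
    maxima_ranking = paste(names(sort(mx, decreasing = TRUE)),
                           collapse = ">"),
    alpha = alpha, q = q,
    advisory = ADVISORY), class = "comparison_result")
  cr$response_class <- classify_response(cr, fra, trawled)
  cr$erosion_dTP <- erosion_effect(cr, fra, trawled)
  cr
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Species %s: KW chi2 = %.1f (df %d, p = %.3g)\n",
              x$species %||% "?", x$kw_chi2, x$kw_df, x$kw_p))
  cat("  median ordering:", x$ordering_median,
      if (isTRUE(attr(x$ordering_median, "emphasis"))) "(FRAs > trawled)" else "",
      "\n")
  cat("  q95 ordering:   ", x$ordering_q95, "\n")
  cat("  maxima ranking: ", x$maxima_ranking, "\n")
  cat(sprintf("  response class: %s; median-scale erosion %.3f\n",
              x$response_class, x$erosion_dTP))
  invisible(x)
}

#' Classify the response to the trawl ban
#'
#' `intermediate`: every FRA-vs-trawled pair is significant for both the
#' median (Wilcoxon) and the tested upper percentile (quantile test), and
#' both FRA medians and upper percentiles exceed both trawled values.
#' `strong`: additionally every FRA maximum exceeds every trawled maximum.
#' `none` otherwise.  Strong implies the intermediate conditions hold.
#'
#' @param cr a `comparison_result` from [compare_areas()].
#' @param fra_areas,trawled_areas area codes per protection group.
#' @return `"none"`, `"intermediate"` or `"strong"`.
#' @export
classify_response <- function(cr, fra_areas, trawled_areas) {
  pairs_ok <- all(vapply(fra_areas, function(f)
    all(vapply(trawled_areas, function(t)
      cr$pairwise_wilcoxon[f, t] < cr$alpha &&
        cr$quantile95[f, t] < cr$alpha &&
        cr$medians[f] > cr$medians[t] &&
        cr$p95s[f] > cr$p95s[t], TRUE)), TRUE))
  if (!pairs_ok) return("none")
  maxima_ok <- all(vapply(fra_areas, function(f)
    all(cr$maxima[f] > cr$maxima[trawled_areas]), TRUE))
  if (maxima_ok) "strong" else "intermediate"
}

#' Median-scale erosion effect
#'
#' Mean of the FRA per-area posterior medians minus the mean of the
#' trawled per-area posterior medians (TP units).
#'
#' @inheritParams classify_response
#' @return difference in median trophic position.
#' @export
erosion_effect <- function(cr, fra_areas, trawled_areas) {
  if (!length(fra_areas) || !length(trawled_areas))
    stop("need at least one area per group")
  mean(cr$medians[fra_areas]) - mean(cr$medians[trawled_areas])
}
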