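---
title: "Detecting trophic position erosion from stable isotopes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting trophic position erosion from stable isotopes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bottom trawling removes large, high-trophic-position fish, but it also
reworks the seafloor community that demersal fish feed on. If prey fields
are impoverished, a predator of a *given body size* may feed lower in the
food web than the same-sized predator in an untrawled area. We call this
*trophic position (TP) erosion*: a drop in TP at fixed size, invisible to
catch-composition indicators because the species and sizes landed are
unchanged.

`tperosion` estimates consumer TP from nitrogen stable isotopes with a
Bayesian one-baseline model and compares posterior TP distributions
between fishery-restricted areas (FRAs) and trawled areas. The package
covers the full chain: survey data handling, baseline selection,
Bayesian fitting, and the cross-area nonparametric test battery — plus a
synthetic survey generator with known ground truth so every stage can be
validated by parameter recovery.

## The trophic position model

Nitrogen isotope ratios (δ¹⁵N, per-mil vs Atmospheric Air) enrich by a
roughly constant trophic discrimination factor (TDF, Δ¹⁵N) per trophic
step. With a baseline of known trophic level λ (here λ = 2: the benthic
crustacean pool consists of primary consumers), the deterministic
skeleton is

    TP = (δ¹⁵N_consumer − δ¹⁵N_baseline) / Δ¹⁵N + λ

(`tp_point()`). The Bayesian model (`fit_one_baseline()`) treats all
quantities as uncertain:

* baseline observations `b_i ~ Normal(mu_b, sigma_b)`;
* consumer observations `x_j ~ Normal(mu_b + Delta * (TP − lambda), sigma_c)`;
* `TP ~ Normal(4, 0.5)` truncated to (1, 10);
* `Delta ~ Normal(3.4, 0.98)` truncated to positive values, **and**
  conditioned on a meta-analytic sample of discrimination measurements
  (by default 56 values with mean 3.4 and s.d. 0.98 per-mil, entered
  through sufficient statistics);
* `mu_b ~ Normal(empirical pool mean, 10)`; all dispersions
  `~ Uniform(0, 10)` per-mil.

### Why the TDF is data, not only a prior

In the one-baseline model, the likelihood constrains only the *product*
`Delta * (TP − lambda)`. If Δ¹⁵N were a free parameter with s.d. 0.98,
the TP prior would drag every estimate toward its mean of 4 and
compress differences between areas — a 1.7 per-mil separation in
consumer δ¹⁵N would *not* map to the 0.5 trophic steps that the central
TDF of 3.4 implies. The classic aquatic TDF of 3.4 ± 0.98 per-mil is an
empirical compilation (n = 56 feeding trials), so the package treats it
as such: the TDF mean is a parameter whose posterior is informed by
those 56 measurements, concentrating near 3.4 with spread
`0.98/sqrt(56) ≈ 0.13` per-mil. This keeps TP identified while
propagating realistic TDF uncertainty. Setting
`model_config(tdf_n = list(mean = 3.4, sd = 0.98, n_obs = 0))` recovers
the prior-only variant for sensitivity analyses.

Because the model is additive in λ, the choice of λ (and of the TP
prior's centre) shifts absolute TP but cancels in the FRA-vs-trawled
*differences* that are the package's object.

### Support bounds and dispersions

TP is truncated to (1, 10): the lower bound sits a full trophic level
below the baseline so the λ-identity case (consumer ≡ baseline, TP = 2)
is interior and boundary bias cannot distort it; the upper bound is far
above any marine consumer. Dispersions get Uniform(0, 10) per-mil
priors — weakly informative on the δ scale, where within-group spreads
are a few tenths of a per-mil.

### Model variants for baseline screening

`fit_two_baseline()` adds a mixing weight `alpha ~ Uniform(0, 1)` for a
second (pelagic) baseline in both elements; the `full` variant adds a
carbon TDF (`Normal(0.4, 1.3)`, prior-only by default).
`compare_models()` reports a deviance information criterion computed on
the consumer nitrogen likelihood (the data shared by all variants, so
the criterion is comparable) and the posterior of the pelagic weight
`1 − alpha`; the one-baseline model is recommended when the pelagic
weight is negligible (posterior mass below 0.1 exceeding one half) or
when DIC favours it by more than 2. Two isotopically indistinguishable
baselines (pool means within the 0.2 per-mil instrument precision on
both elements) make `alpha` unidentifiable; the fit completes and is
flagged.

## Sampling and diagnostics

The sampler is an adaptive random-walk Metropolis-within-Gibbs: one
Gaussian random-walk block per parameter, proposal scales adapted in
batches of 50 towards the 1-D optimal acceptance rate of 0.44, with a
vanishing adaptation step. Adaptation runs only during the dedicated
adaptation phase (default 10^4 steps) and is frozen afterwards, so the
burn-in (10^4) and sampling (10^4) phases satisfy detailed balance.
Likelihoods are evaluated from sufficient statistics, so each update is
O(1) in the sample sizes.

Five chains are run from jittered starts, and the kept iterations are
thinned *evenly within each chain* (1000 of 10^4 per chain by default)
and interleaved across chains to exactly 5000 pooled draws — chain
balance is preserved and the pooling is deterministic given the draws.
Convergence is summarised by split-R̂ (threshold 1.05) and an
initial-positive-sequence effective sample size per parameter.
Non-convergence is a reported flag, never an exception, so multi-species
pipelines always complete and disclose. The test suite verifies the
sampler against (i) the analytic truncated-normal priors under a
prior-only run, (ii) a dense-grid quadrature oracle for the one-baseline
posterior, and (iii) recovery of injected TPs with calibrated credible
intervals; in that recovery experiment each dataset's true TDF is drawn
from `Normal(3.4, 0.98/sqrt(56))`, the sampling distribution of the
meta-analytic mean the model conditions on — with the TDF pinned exactly
at 3.4 the intervals would (correctly) over-cover.

## Baseline selection

Three steps mirror standard practice:

1. **Permutational MANOVA** (`permanova()`) on the baseline taxa across
   areas. Sums of squares are partitioned from the Gower-centred matrix
   of squared dissimilarities with sequential hat-matrix projections,
   supporting the nested design *trawl* / *area(trawl)* / *taxon* with
   the taxon-by-area-within-trawl interaction as the default tested term
   (6 numerator degrees of freedom in the complete four-area,
   four-taxon layout). Bray–Curtis is undefined on signed δ values, so
   the default metric first translates each variable by its global
   minimum (`bray_curtis_shifted`), making the index well defined and
   invariant to per-variable shifts; Euclidean distance is available.
   The permutation p-value uses the `(1 + b)/(1 + m)` convention (never
   exactly zero); permutations are unrestricted for one-way designs and
   for the top-level factor, and restricted within trawl levels for
   nested terms. Incomplete nested layouts fall back, with a warning, to
   a one-way analysis on the area-taxon cell factor; layouts with a
   single area per trawl level are likewise tested one-way by the
   pipeline. For small samples, `exhaustive = TRUE` enumerates all
   assignments, and the suite checks equivalence against a brute-force
   oracle.

2. **Biplot screen** (`screen_baselines()`). In practice this check is
   visual; the package formalizes it: a candidate baseline is excluded
   when the consumer cluster's mean δ¹³C is at least 5 per-mil away
   (the depletion observed for zooplankton) *and* the consumers do not
   lie strictly between the two baselines in δ¹³C (a consumer sitting on
   one baseline is not a mixture). The threshold is explicit and
   configurable precisely because the original rule was a judgement
   call.

3. **Model comparison** (`compare_models()`, above) on the candidate
   variants.

## Comparing posterior distributions across areas

`compare_areas()` runs the conventional battery on the pooled draws
(n = 5000 per species and area): Shapiro–Wilk pre-checks (samples
evenly subsampled to the test's 5000-value limit), Kruskal–Wallis
across areas, two-sided pairwise Wilcoxon tests (exact for small
tie-free samples, normal approximation with continuity and tie
correction otherwise), and a two-sample test at the 95th percentile.
The quantile test is a Mood-type construction: pool both samples, take
the pooled 0.95 quantile (linear-interpolation, R type 7 — used for
*all* quantiles in the package so summaries are bit-reproducible),
and test the 2×2 exceedance table by continuity-corrected chi-squared,
or Fisher's exact test when any expected cell is below 5.

Significance is α = 0.05 throughout; pairwise p-values are unadjusted by
default (Holm available). Ordering strings such as `GC=GP>GS>GT` sort
areas by the statistic and join adjacent pairs with `=` when their test
is non-significant. The response classification is monotone:
*intermediate* requires every FRA-vs-trawled pair significant for both
the median and the 95th percentile with the FRA values higher; *strong*
additionally requires every FRA maximum to exceed every trawled maximum
(maxima are ranked, never tested). `erosion_effect()` reports the mean
FRA median minus the mean trawled median.

One caveat is attached to every result object rather than corrected
for: the 5000 draws are autocorrelated MCMC samples, and rank tests
treating them as independent observations overstate evidence (this is
visible in the enormous Kruskal–Wallis statistics such comparisons
produce). The package applies the conventional procedure by design and
carries the advisory; effective-sample-size-corrected testing is a
deliberate non-goal.

## The synthetic survey generator

`generate_survey()` emulates a Mediterranean trawl-ban survey: two FRAs (GC, GP) and two
trawled gulfs (GS, GT); twelve consumer species at species-typical true
TPs between 3.2 and 4.0; three benthic crustacean baseline taxa plus
mesozooplankton per area; zooplankton depleted by 5 per-mil in δ¹³C
relative to the benthic cluster; instrument noise of 0.2 per-mil (the
stated analytical precision) added in quadrature to a biological
within-group s.d. of 0.3 per-mil (a free scenario parameter — field surveys
rarely report within-group variances, so the default is chosen to make
recovery experiments informative rather than to match the field data).
Five individuals per taxon and area are drawn by default (such surveys
typically require at least three). The *erosion switch* of `default_scenario()`
lowers every trawled-area true TP by a configurable amount (default 0.5,
the headline effect size), so power and recovery experiments know the
injected truth exactly.

What the generator does **not** emulate — and therefore what passing
recovery tests do not establish about field data: spatial or seasonal
isotope gradients within a gulf, species-specific or area-specific
TDFs, non-normal or skewed within-group variation, unbalanced sampling,
and any dependence of signatures on body length (lengths are stored as
metadata only, matching a design that fixed size at collection).

## Numerical choices and degenerate inputs

* Quantiles: linear interpolation (type 7) everywhere.
* Identical samples under Bray–Curtis (0/0) are defined to be at
  distance 0; all-identical groups give Kruskal–Wallis H = 0 with p = 1;
  a group tested against an identical copy gives Wilcoxon p = 1;
  constant samples make Shapiro–Wilk W undefined and raise an error.
* Chain initialisation: the closed-form point estimate for TP (clamped
  to the interior of the support), empirical moments for means and
  dispersions (dispersions clamped away from 0 and from the prior's
  upper bound), jittered per chain.
* Seeds: every chain and pipeline stage derives its seed from the
  single master seed (kept below 2^31); identical seed, configuration
  and data give bit-identical pooled draws and CSV outputs.
* Test problem sizes are the package's own choices: full-length chains
  (5 × 3·10^4 steps) where a single fit is asserted tightly, two or
  three shorter chains for the 100-fit recovery and comparison suites.

## Known limitations

* Each species-area fit is independent; there is no hierarchical
  pooling across species or areas (as in the adopted method).
* No Hamiltonian/NUTS sampling; the random-walk sampler is adequate for
  these low-dimensional posteriors but would scale poorly.
* The PERMANOVA supports exactly the term structures needed here (one
  factor, or the nested three-factor design); it is not a general
  distance-based ANOVA framework.
* The quantile test compares a single quantile; differences confined to
  other parts of the tail are invisible to it.
* Absolute TP levels depend on the (unverifiable) truncation bounds and
  prior centre; only relative differences between areas are robust to
  those choices.

## A minimal session

```{r}
library(tperosion)

scn <- default_scenario(erosion = 0.5, seed = 1)
sim <- generate_survey(scn)
validate_dataset(sim$dataset)

screen_baselines(sim$dataset, "GC")

parts <- split_consumers_baselines(sim$dataset, "GC")
fit <- fit_one_baseline(parts$consumers$MUT$d15N, parts$benthic$d15N,
                        model_config(seed = 1), species = "MUT", area = "GC")
fit

out <- run_pipeline(run_config(input = scn, out_dir = "erosion_run",
                               seed = 1))
out$comparisons$MUT
```
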