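# tperosion

Detecting **trophic position erosion** — the reduction of a consumer's
trophic position (TP) at a fixed body size caused indirectly by fishing —
from nitrogen stable isotopes.

Bottom trawling does more than remove fish: it reworks the benthic prey
field that demersal predators feed on. A predator of a given size in a
trawled gulf may therefore feed lower in the food web than the same-sized
predator in a fishery-restricted area (FRA), a shift invisible to
catch-based indicators. `tperosion` quantifies this shift for
individual-level stable-isotope surveys: consumers and baseline
invertebrates sampled per area, δ¹³C and δ¹⁵N per individual.

The package is aimed at trophic ecologists comparing TP across areas,
protection regimes, or time, and at methodologists who want a fully
testable re-implementation of the standard Bayesian TP workflow.

## What it computes

**Bayesian trophic position.** For each species and area, TP is estimated
from the one-baseline nitrogen model built on

    TP = (δ¹⁵N_c − δ¹⁵N_b) / Δ¹⁵N + λ

with baseline observations `~ N(μ_b, σ_b)`, consumer observations
`~ N(μ_b + Δ¹⁵N·(TP − λ), σ_c)`, a `N(4, 0.5)` prior on TP truncated to
(1, 10), λ = 2 (primary-consumer baseline), and the trophic
discrimination factor Δ¹⁵N informed by the classic aquatic compilation
(3.4 ± 0.98 ‰, n = 56) entered as data. Sampling is by an adaptive
random-walk Metropolis-within-Gibbs sampler (5 chains × 10⁴
adaptation/burn-in/sampling steps), pooled by even per-chain thinning to
exactly 5000 posterior draws, with split-R̂ and effective-sample-size
diagnostics. Two-baseline and full (carbon) variants support model
screening via DIC and the posterior of the pelagic mixing weight.

**Baseline selection.** A distance-based permutational MANOVA
(shifted Bray–Curtis or Euclidean; one-way or the nested
trawl / area(trawl) / taxon design; exhaustive enumeration for small
samples) plus an explicit formalization of the biplot screen: a candidate
baseline ≥ 5 ‰ away from the consumers in δ¹³C, with the consumers not
positioned between the sources, is excluded.

**Cross-area comparison.** The nonparametric battery applied to the
pooled posterior draws: Shapiro–Wilk pre-checks, Kruskal–Wallis,
pairwise Wilcoxon, a Mood-type two-sample test at the 95th percentile,
maxima ranking, table-style ordering strings (`GC=GP>GS>GT`), a
none / intermediate / strong response classification, and the
median-scale erosion effect (mean FRA median − mean trawled median).

**Synthetic surveys.** `generate_survey()` emulates the 4-area ×
12-species design (3 benthic baseline taxa + zooplankton per area,
±0.2 ‰ instrument precision, −5 ‰ pelagic carbon offset) with known true
TPs and an *erosion switch*, so every stage has a parameter-recovery
test surface.

## Worked example

```r
library(tperosion)

scn <- default_scenario(erosion = 0.5, seed = 1)   # trawled areas feed 0.5 TP lower
sim <- generate_survey(scn)
validate_dataset(sim$dataset)
#> dataset accepted for fitting (no errors)

screen_baselines(sim$dataset, "GC")
#> Baseline screen for area GC (d13C gap threshold 5.0 permil)
#>  baseline mean_d13C  n        gap include
#>   benthic -17.97012 15 0.02270333    TRUE
#>   pelagic -22.98466  5 4.99183955    TRUE

parts <- split_consumers_baselines(sim$dataset, "GC")
fit_one_baseline(parts$consumers$MUT$d15N, parts$benthic$d15N,
                 model_config(seed = 1), species = "MUT", area = "GC")
#> one_baseline fit MUT @GC: 5000 pooled TP draws
#>   posterior TP median 3.507, 95% CrI [3.315, 3.743]
#>   converged: TRUE (max split-Rhat 1.002)
```

The true TP of red mullet (MUT) in GC in this scenario is 3.5; the
posterior median lands on it within Monte-Carlo and sampling error.
Fitting all four areas and running the comparison battery:

```r
draws <- list(); k <- 0
for (a in c("GC", "GP", "GS", "GT")) {
  k <- k + 1
  p <- split_consumers_baselines(sim$dataset, a)
  f <- fit_one_baseline(p$consumers$MUT$d15N, p$benthic$d15N,
                        model_config(seed = k), species = "MUT", area = a)
  draws[[a]] <- f$draws
}
compare_areas(area_posteriors(draws, attr(sim$dataset, "areas"), species = "MUT"))
#> Species MUT: KW chi2 = 14300.6 (df 3, p = 0)
#>   median ordering: GP>GC>GT>GS (FRAs > trawled)
#>   q95 ordering:    GP=GC>GT>GS
#>   maxima ranking:  GT>GS>GC>GP
#>   response class: intermediate; median-scale erosion 0.486
```

Both FRAs sit significantly above both trawled areas in median and 95th
percentile (response class `intermediate`; the posterior *maxima* do not
separate with five individuals per group, which is what would upgrade
the class to `strong`). The recovered erosion effect, 0.486 TP, matches
the injected 0.5. The huge Kruskal–Wallis χ² is expected: the battery
treats 5000 autocorrelated posterior draws as observations, and every
result object carries an advisory saying so.

`run_pipeline(run_config(input = scn, out_dir = "run", seed = 1))` runs
screening, fitting and comparison end to end and writes per-stage CSV/JSON
artifacts (posteriors, PERMANOVA, a table-style summary, box-plot data,
diagnostics, config and log); reruns with the same seed are bit-identical.

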