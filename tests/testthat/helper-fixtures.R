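# Shared fixtures: a pocket-sized scenario (2 areas, 2 species) for fast
# structural tests, and a reduced-length model configuration for fits whose
# correctness does not depend on long chains.

tiny_scenario <- function(seed = 1, erosion = 0.5, n_per_group = 5L) {
  areas <- c(GC = "fra", GT = "trawled")
  tp <- rbind(MUT = c(3.5, 3.5 - erosion), HAK = c(3.6, 3.6 - erosion))
  colnames(tp) <- names(areas)
  scenario_config(
    areas = areas, species_tp = tp,
    baseline_d15N = c(GC = 5.0, GT = 5.1),
    baseline_d13C = c(GC = -18.0, GT = -18.2),
    n_per_group = n_per_group, seed = seed)
}

fast_config <- function(seed = 1, ...) {
  model_config(n_adapt = 500, n_burn = 500, n_iter = 1500, n_chains = 2,
               pooled_draws = 1000, seed = seed, ...)
}

# mid-length settings: enough iterations that posterior-median Monte-Carlo
# error is well below the tolerances asserted on it
mid_config <- function(seed = 1, ...) {
  model_config(n_adapt = 2000, n_burn = 2000, n_iter = 4000, n_chains = 3,
               pooled_draws = 3000, seed = seed, ...)
}
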