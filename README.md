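# geoshift

Where have the lineages of a clade lived, when did they move between
regions, and is movement associated with differences in speciation and
extinction? `geoshift` answers these questions from two widely available
data types — geo-referenced occurrence records and a dated (ultrametric)
phylogeny — and is aimed at biogeographers and macroevolution researchers
working at continental scale (for example, comparing the world's tropical
regions with the non-tropical rest).

The pipeline, end to end:

1. **Occurrence cleaning and region coding.** `clean_occurrences()` removes
   the standard archive pathologies (source-flagged rows, blank names,
   non-numeric/out-of-range coordinates, latitude = longitude, zero
   coordinates, per-location duplicates) with an auditable per-rule report;
   `assign_points_to_regions()` codes points into named polygons
   (closed-polygon rule); `apply_filter()` implements tiered presence
   criteria — level 1: ≥ 3 records in a region; level 2: additionally
   ≥ 10% of the species' records; level 3: additionally only the single
   region with the most records. `compute_sampling_fractions()` reports,
   per region, the fraction of coded species present in the tree.
2. **Range shifts through time.** A continuous-time Markov (Mk) model of
   region evolution with rate matrix Q is fitted by maximum likelihood
   (Felsenstein pruning); `relative_shift_rates()` draws stochastic
   character maps (node states from their joint conditional distribution,
   branch histories by uniformization) and reports, per 5-Myr age bin and
   direction, the number of mapped transitions divided by the number of
   available lineages, with an empirical 95% band over (by default) 100
   replicate maps.
3. **State-dependent diversification.** `musse_loglik()`/`fit_musse()`
   implement the MuSSE birth–death model: per-state speciation λ_i and
   extinction μ_i with Markov transitions q_ij, integrating the coupled
   E/D equations along every branch (adaptive Runge–Kutta in C++) with
   state-specific sampling fractions ρ_i entering the tip conditions
   (D_i = ρ_i·1[state = i], E_i = 1 − ρ_i). `normalize_rates()` divides
   each clade's rates by their across-region sum and `compare_regions()`
   runs one-way ANOVA plus Tukey HSD across regions with clades as
   observations.
4. **Phylogenetic clustering of regions.** Parsimony score, association
   index and maximum exclusive single-state clade, with tip-permutation
   null distributions and add-one p-values (`permutation_test()`,
   one-vs-rest per region via `clustering_by_region()`).
5. **Synthetic data.** A Gillespie simulator of state-dependent
   birth–death trees that records the true transition history on every
   surviving branch (`simulate_musse_tree()`), tip subsampling with
   state-specific retention (`subsample_tips()`), toy region polygons, and
   an occurrence generator with controlled contamination
   (`generate_occurrences()`) — so the whole pipeline is testable offline
   against known truth.

`run_pipeline()` ties the stages together under one config with derived
per-stage seeds, machine-parseable logs and a hash manifest;
`run_demo()` builds a synthetic four-region data set and runs everything.
A thin CLI over the same functions lives at `inst/scripts/geoshift.R`
(subcommands `simulate`, `geocode`, `signal`, `shift-rates`, `fit-musse`,
`run`, `demo`).

## A worked example

Simulate a two-region history with faster tropical speciation, then ask the
three questions back:

```r
library(geoshift)

cfg <- sim_config(lambda = c(0.2, 0.12), mu = c(0.03, 0.03), q = 0.02,
                  max_taxa = 150, states = c("tropical", "temperate"),
                  seed = 42)
sim <- simulate_surviving(cfg)

fit_musse(sim$tree, sim$tip_states, q_constraint = "equal")
#> musse_fit: log-likelihood -460.51
#> musse_params, 2 states
#>       state    lambda         mu rho
#> 1 temperate 0.1977974 0.19455676   1
#> 2  tropical 0.2357928 0.08341217   1

permutation_test(sim$tree, sim$tip_states, n_reps = 100, seed = 1)
#> PS: observed 17, null mean 26.19, p = 0.009901
#> AI: observed 1.8984, null mean 5.0551, p = 0.009901
#> MC[temperate]: observed 4, null mean 1.91, p = 0.009901
#> MC[tropical]: observed 16, null mean 10.93, p = 0.09901

mk <- fit_mk(sim$tree, sim$tip_states, "ARD")
shifts <- relative_shift_rates(sim$tree, sim$tip_states, mk,
                               n_maps = 100, bin_width = 5, seed = 1)
head(as.data.frame(shifts), 3)
#>             direction bin_start bin_end   mean   lo95   hi95 denominator
#> 1 temperate->tropical         0     5.0 0.0369 0.0167 0.0672         239
#> 2 temperate->tropical         5    10.0 0.0316 0.0000 0.0753          93
#> 3 temperate->tropical        10    15.0 0.0617 0.0000 0.1667          36
```

Reading the output: the fitted tropical speciation rate (0.24/Myr) exceeds
the temperate one (0.20/Myr), in the direction of the generating values
(0.2 vs 0.12); both regions are significantly clustered on the tree by the
parsimony score and association index (p ≈ 0.0099 is the smallest value
the add-one rule allows at 100 permutations); and the binned series gives
the per-lineage rate of temperate→tropical shifts through time with its
95% band — for instance, in the youngest 5-Myr bin, 239 lineage segments
were available and about 0.037 shifts per available lineage were mapped.

The full synthetic demo writes every stage output (cleaning report,
region counts, sampling fractions, clustering JSON, shift-rate table,
per-clade MuSSE rates, ANOVA/Tukey comparison, manifest):

```r
run_demo("demo_run", seed = 1)
```

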