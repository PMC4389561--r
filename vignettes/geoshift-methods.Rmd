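---
title: "Models and methods behind geoshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind geoshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

geoshift estimates where lineages of a clade have been, when they moved, and
how movement relates to speciation and extinction, starting from two widely
available data types: geo-referenced occurrence records and a dated
(ultrametric) phylogeny. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic-data tests do and
do not establish.

## From occurrence records to region states

Occurrence archives aggregated from heterogeneous sources carry recurring
pathologies: records flagged at source for coordinate problems, blank
species names, unparseable or out-of-range coordinates, latitude equal to
longitude (a classic column-swap/data-entry signature), zero latitude or
longitude (fields left blank and read as 0), and bulk duplicates of the same
collection locality. `clean_occurrences()` removes rows by the first rule
they match, in a fixed documented order, so the removal counts in the
`cleaning_report` always add up to the input row count and re-cleaning a
cleaned table removes nothing. Deduplication keeps one record per species
per location, with locations compared after rounding coordinates to 4
decimal places (about 11 m at the equator) — archives mix precisions, and
finer-than-11-m distinctions are noise at continental scale.

Cleaned points are assigned to named regions by point-in-polygon tests
(closed polygons: boundary points count as inside; regions must be
interior-disjoint, and contacts along shared boundaries are resolved by a
declared precedence order). Species-by-region record counts then pass
through tiered presence filters:

* level 0 — present with at least 1 record;
* level 1 — at least 3 records in the region;
* level 2 — additionally, the region holds at least 10% of the species'
  assigned records;
* level 3 — additionally, presence is kept only in the single region with
  the most records.

Both thresholds are inclusive (≥ 3, ≥ 10%), the percentage base is the
species' records assigned to any named region (unassigned points are
excluded), and level-3 ties are broken by the precedence order — three
points on which printed filter tables are typically silent and which are
fixed here for reproducibility. If the top-count region fails level 2
(possible only when the species has fewer than 3 records there), the
species is coded absent everywhere at level 3.

Range-shift analyses default to level-2 presences reduced to a single state
per species by the level-3 highest-count rule (a widespread species has no
single Markov state otherwise); diversification analyses use level 3
directly. Sampling fractions are reported per region (and per clade) as the
number of region-coded species matched to a tree tip over the number of
region-coded species, both raw and rounded to 2 decimals as such tables are
conventionally printed. Name matching canonicalizes to the first two name
tokens, case-folded, underscores as spaces; canonical collisions are
reported and excluded rather than silently merged.

## Range shifts through time

Region evolution along the tree is modelled as a continuous-time Markov
(Mk) chain with instantaneous rate matrix Q. The default model class is
all-rates-different, because the asymmetry between immigration into and
emigration out of a region is the quantity of interest; equal-rates and
symmetric classes are available. The likelihood is computed by Felsenstein
pruning with per-branch transition probabilities `expm(Q t)` and per-node
rescaling against underflow. Rates are fitted by bounded maximum likelihood
(log scale, rates in [1e-8, 100] per Myr, three deterministic starts scaled
around a parsimony-informed rate).

Stochastic character maps are drawn exactly: node states root-to-tips from
their joint conditional distribution given the tip states, then branch
histories conditional on endpoint states by uniformization with dominating
rate Λ = max |Q_ii|. Uniformization has bounded expected cost even when
endpoints differ on short branches, which is where rejection sampling
stalls. The root state is drawn from the model's root prior (default:
stationary distribution of the fitted Q; uniform and FitzJohn-style
conditional weighting available).

`relative_shift_rates()` summarizes `n_maps` (default 100) replicate
histories as per-bin transition counts divided by a lineage-availability
denominator, in bins of `bin_width` (default 5 Myr) anchored at the
present; the oldest bin is truncated at the root age and its actual width
recorded in the metadata. Because "the number of lineages in a bin" is
ambiguous, two denominators are implemented: the default counts branches
whose age span intersects the bin interior (lineages available during the
bin — this can never be zero for a bin inside the tree's span), the
alternative counts branching events inside the bin (which can be zero and
then yields a missing, not zero, rate). The reported 95% band is the
empirical 2.5–97.5 percentile interval across replicate maps. Event times
are taken at their sampled ages, not at branch midpoints.

## State-dependent diversification

Speciation and extinction rates per region state follow the multiple-state
speciation–extinction (MuSSE) model: lineages in state i speciate at λ_i,
go extinct at μ_i, and switch states at q_ij. The likelihood integrates,
along every branch, the coupled equations for E_i(t) (probability that a
lineage in state i leaves no sampled descendant) and D_i(t) (density of the
observed subtending data),

    dE_i/dt = μ_i − (λ_i + μ_i + Σ_{j≠i} q_ij) E_i + λ_i E_i² + Σ_{j≠i} q_ij E_j
    dD_i/dt = −(λ_i + μ_i + Σ_{j≠i} q_ij) D_i + Σ_{j≠i} q_ij D_j + 2 λ_i E_i D_i

with tip conditions D_i = ρ_i·1[state = i] and E_i = 1 − ρ_i, where ρ_i is
the state-specific sampling fraction, and node combination
D_i ← D_left,i · D_right,i · λ_i. Integration uses an adaptive Cash–Karp
Runge–Kutta 4(5) core (C++), relative/absolute tolerances 1e-8/1e-10,
with D renormalized after every branch into a running log-compensation.
The tolerances are exposed on `musse_loglik()` and can be tightened (e.g.
1e-10/1e-12) when comparing against closed forms. The default root
treatment is FitzJohn weighting (w_i ∝ D_root,i) without survival
conditioning; a flat prior and an equilibrium prior are selectable and the
mode is recorded in every fit.

Two exact identities anchor the implementation: with one state, μ = 0 and
ρ = 1 the log-likelihood equals the pure-birth closed form
(n−1)·log λ − λ·(total branch length); and adding a second state with
identical rates, q = 0 and no observed tips in it leaves the likelihood
unchanged (its D is identically zero). Note that the collapse requires
q = 0: with q > 0 the two-state likelihood factorizes into a
state-independent birth–death part times the Mk likelihood of the tip
states, which is strictly smaller.

`fit_musse()` maximizes over rates in [1e-6, 10] per Myr (log scale,
L-BFGS-B) from three deterministic starts derived from a birth–death moment
estimate (net diversification from tip count and root age at assumed
relative extinction 0, 0.5 and 0.8). Equality constraints are available for
λ, μ and q; per-clade pipeline fits constrain q to a single shared rate
because order-sized subtrees cannot identify k(k−1) transition rates on top
of 2k diversification rates.

Per-clade rates are made comparable across clades by normalizing within
each clade: every rate is divided by the clade's sum over regions,
separately for speciation and extinction, so each clade contributes a
composition rather than an absolute level. Regions are then compared by
one-way ANOVA with clades as observations, followed by Tukey HSD pairwise
tests; mean normalized rates are the point summaries. Normalized values are
used for all comparisons, including any tropical-vs-non-tropical contrast.

## Phylogenetic clustering of region states

Three statistics quantify whether species of a region clump on the tree:
the parsimony score PS (minimum number of state changes; implemented as
unit-cost Sankoff dynamic programming, which equals the Fitch count on
binary trees and handles polytomies); the association index
AI = Σ_nodes (1 − f_node)/2^(n_node − 1), where f_node is the frequency of
the most common state among the node's n_node descendant tips; and MC, the
size of the largest clade whose tips all share a state. The literature
names these statistics without printing formulas, so the exact definitions
used are emitted in the output metadata.

Significance comes from permuting tip states uniformly (default 100
permutations) on the single fixed tree, with add-one p-values
p = (1 + m)/(1 + n), m counting null replicates at least as clustered as
the observation (≤ for PS and AI, ≥ for MC). Operating on one tree rather
than a posterior sample is a stated limitation: the null captures tip-label
randomness only, not phylogenetic uncertainty. The default reporting mode
is one-vs-rest per region; joint multi-state coding is also available since
published analyses rarely say which was used. Null-calibration checks use
AI rather than PS because PS is integer-valued and heavily tied on small
trees, which makes its add-one p conservative by construction rather than
uniform.

## The synthetic-data generator

All tests run on data from the package's own forward simulator, so every
downstream claim can be checked against a known truth. Trees are grown by
Gillespie simulation under the same MuSSE process the estimators assume
(per-state λ, μ; CTMC transitions; root state drawn from the stationary
distribution of q unless fixed), stopped at a time horizon or a taxon cap,
pruned of extinct lineages, with every state change on a surviving branch
retained with its age (the `TrueHistory`). Replicates that leave fewer than
two survivors signal a classed condition and are retried with
deterministically advanced seeds. Occurrence tables place points uniformly
inside each species' home polygon and inject, at configured rates, exactly
the pathologies the cleaner targets plus "stray" points in the wrong
region; ground-truth labels ride along for round-trip tests.

Study conditions used by the validation suite: rate recovery uses 50 trees
of ≥ 200 surviving tips simulated at λ = (0.2, 0.1), μ = (0.05, 0.05),
q = 0.02/Myr — a 2:1 true speciation ratio at plausible angiosperm-order
magnitudes; mapping calibration uses 100–120-tip trees, 2000 maps for
conditional checks and 30 replicates for the mapped-versus-true regression,
with maps drawn under the generating Q so that the check isolates mapping
calibration from rate-estimation noise. The end-to-end demo simulates a
four-region tree capped at 150 taxa, 12 clean points per species, ~13%
total contamination, 100 maps, 100 permutations, and derives four clades by
slicing the tree at the earliest age with at least four coexisting
lineages. These sizes keep a full validation run on one CPU in minutes
while leaving Monte-Carlo error well inside the asserted bands.

What the synthetic data does not emulate: spatial autocorrelation and
sampling bias of real occurrence records, taxonomic synonymy, polygon
complexity of real ecoregions (fixtures are rectangles), phylogenetic
uncertainty, and diversification heterogeneity beyond the fitted model
class. Passing tests therefore demonstrate correctness of the machinery
under its own assumptions, not robustness to violations of them.

## Numerical choices and degenerate inputs

* Ultrametricity is enforced within 1e-6 Myr; node ages within 1e-6 Myr of
  the present are clamped to 0 so that zero-length tip branches created by
  taxon-cap truncation bin identically before and after Newick round-trips.
* Transition probabilities from `expm(Q t)` have tiny negative entries
  clipped to 0 before sampling.
* Uniformization draws the number of dominated jumps by accumulating the
  endpoint-conditioned Poisson mixture until the target quantile, with an
  explicit failure beyond 1e5 terms.
* Invariant characters cannot be fitted (`fit_mk` errors); ρ = 0 for an
  observed state is an error; bins with zero denominator are reported as
  missing, never as zero rates.
* All Monte-Carlo stages take explicit seeds; pipeline stages derive
  substream seeds from one master seed via a Lehmer-style hash so stages
  can be re-run independently and whole runs are byte-reproducible.

## Known limitations

Sampling fractions enter the likelihood as state-specific tip conditions;
at very low sampling (say below ~10%) state-dependent estimates are known
to be fragile regardless of implementation, and the per-clade fits here
provide point estimates, not calibrated uncertainty. The pipeline's
single-state reduction of widespread species discards real range breadth; a
configuration switch can instead drop widespread species, and either choice
is recorded in the run metadata. DEC-style range models with polymorphic
states, hidden-state extensions, and time-varying rates are out of scope.
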