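---
title: "Analysing canopy frugivory webs: models, nulls and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing canopy frugivory webs: models, nulls and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frugnet)
```

## The system and the data model

frugnet analyses diurnal canopy frugivory as a weighted bipartite network.
The raw observation unit is a *visit record*: a frugivore lands in a focal
fruiting tree, the observer notes its identity, the visit duration in
minutes, and focal feeding-rate samples — the number of fruits manipulated
per focal interval (30 s intervals are the convention for primates, 10 s
for birds). `fruits_handled()` turns a visit log into the community
consumption matrix, whose cell $X_{ij}$ estimates the number of fruits of
plant $i$ handled by frugivore $j$:

$$X_{ij} = \Big(\sum_v \mathrm{duration}_v\Big) \times \bar r_{ij}
  \times \frac{60}{\mathrm{interval}},$$

total feeding time multiplied by the average feeding rate converted to
fruits per minute. Two conventions exist for $\bar r_{ij}$; by default all
focal counts of a pair are pooled before averaging (which makes the matrix
additive over arbitrary splits of the log), with a per-visit alternative
behind the `pooling` argument. When external long-term studies provide
better estimates of how a *group* of frugivores (typically the primates)
divides its feeding time, `reallocate_group()` redistributes the group's
per-plant total by those proportions without changing the total itself.

The matrix travels through the package as a `consumption_matrix`: plants
as rows, frugivores as columns, a `scale` flag recording whether cells are
raw counts or row percentages (`normalize_percent()` converts, and the
presence skeleton from `binarize()` — strictly positive cells, no rounding
threshold — is identical under both scales).

## Species-level indices

`species_indices()` assembles the per-plant (or per-frugivore) index table:

* **D, ND** — number of partners, and the same scaled by the number of
  possible partners.
* **NR** — nested rank: position in the degree-ordered matrix, normalized
  to $[0,1]$ with 0 the most generalist species. Ties are broken by total
  interaction weight, then label, so output is deterministic.
* **WB, WC** — weighted betweenness and closeness on the one-mode
  projection. The projection weight between two plants is
  $w_{ik} = \sum_j X_{ij}X_{kj}$ (a `min`-overlap alternative is exposed,
  since the projection rule is a genuine modelling choice); shortest paths
  run on distances $1/w$; both indices are rescaled to sum to one across
  the level, so in a web of $S$ plants the mean is $1/S$ by construction.
  Unreachable pairs contribute ten times the largest finite distance and
  isolated species score zero closeness.
* **SS** — species strength, the sum over partners of the focal species'
  share of each partner's interactions. Summed over all plants this equals
  the number of non-empty frugivore columns, a useful exact invariant.
* **EP, SSP** — effective partners $e^{H}$ (Shannon numbers equivalent)
  and species specificity, the population coefficient of variation of the
  weight vector (zeros included) divided by its maximum $\sqrt{m-1}$.
* **d, d'** — Kullback–Leibler specialization: how far a species' partner
  use diverges from partner availability $q_j = A_j/M$, raw and rescaled
  between extremes achievable given its total. $d_{\min}$ is computed
  *exactly* for count matrices (integer allocation minimizing a separable
  convex objective: floor of the continuous optimum plus greedy
  remainder), and is 0 on proportion data. $d_{\max}$ is a multi-start
  greedy over the vertices of the capped allocation simplex — the obvious
  "fill the scarcest partner first" rule can be beaten by concentrating
  everything on a single high-capacity partner, which the multi-start
  covers; an exhaustive enumeration oracle over all integer matrices with
  matched marginals backs this in the test suite.
* **Gc / core flag** — standardized degree $(k_i-\bar k)/\mathrm{SD}(k)$;
  species at least one SD above the level mean are "core".

Because several of these indices point in opposite directions, the
conventional $1-x$ conversions of `d`, `d'`, `NR` and `SSP` are carried
alongside the raw values, and `correlate_indices()` reproduces the
redundancy analysis (pairwise Pearson, $|r|>0.6$ flagged). One published
index row — a "generality" with mean 0.810 and variance exactly 1.000 —
cannot be reconstructed from its one-line description ("mean number of
manipulating animals per plant" is incompatible with the same table's mean
degree); the per-species `G` column here is therefore the effective-partner
count, with the discrepancy documented rather than imitated.

## Network-level structure and null models

`nodf()` implements NODF (nestedness by overlap and decreasing fill): for
each ordered pair within rows and within columns, the paired score is
$100\,|\mathrm{shared}|/\mathrm{fill(poorer)}$ if the richer member has
strictly larger fill and 0 otherwise, averaged over all pairs. The
implementation is cross-checked against an independent one
(`vegan::nestednodf`) over the complete set of $3\times3$ binary matrices
and random larger webs.

Significance comes from `null_test()` with three ensembles:

* **ER** — every cell Bernoulli with the observed connectance;
* **CE** — cell $(i,j)$ Bernoulli with the average of row-$i$ and
  column-$j$ fill proportions;
* **vaznull** — a weighted null that conserves the grand total $M$ and
  fill $F$ exactly while drawing the skeleton with probability
  proportional to the product of weighted marginals (every row and column
  forced non-empty), then spreading the remaining $M-F$ interaction units
  multinomially. Binary ER/CE nulls are refused for the weighted
  specialization statistic because they destroy the weights.

Empirical $p$-values use the $+1$ correction, $p=(1+\#\{null \ge
obs\})/(R+1)$, so "p = 0" is reported as $p < 1/(R+1)$.

Network specialization `h2_prime()` standardizes the two-dimensional
Shannon entropy between marginal-constrained extremes: $H_{2\max}$ from
the entropy-maximizing proportional fill (the outer product of marginals,
which is the continuous maximum-entropy table) and $H_{2\min}$ from greedy
concentration — repeatedly pouring $\min$(remaining row, remaining column)
into the cell pairing the largest remaining marginals. The greedy extreme
is validated against exhaustive enumeration of every integer table with
matched marginals at small totals; a uniform web scores 0, any diagonal
web scores 1.

## Robustness to secondary extinction

`extinction_sequence()` removes one trophic level in a given order and
counts species at the other level that lose their last partner;
`robustness_area()` integrates the survivors-vs-removed curve by
trapezoids, giving $R \in [0,1]$. `random_robustness()` averages over
random removal orders (default 100, each with a counter-derived seed), and
`single_removal_experiment()` replicates the web, deletes one focal plant
at a time (frugivores left partnerless stay as structural zero columns and
count as immediate losses), and recomputes both directions. The naming
convention follows the ecological reading: "plant-level robustness" is the
persistence of plants as frugivores are removed, and vice versa; the
convention is documented here because the two are easy to swap. Exhaustive
oracles (every removal order on every small web) pin the curve logic in
the tests.

## Phylogenetic structure of visitor assemblages

For each plant, the set of frugivores visiting it is an assemblage whose
phylogenetic structure is measured by MPD (mean pairwise cophenetic
distance) and MNTD (mean nearest-taxon distance), both presence-based.
`ensemble_indices()` compares observed values against nulls obtained by
checkerboard-swap randomization of the whole plant × frugivore presence
matrix — the *independent swap*, which conditions on both species
frequencies and assemblage richness, deliberately chosen over uniform tip
draws so that common visitors stay common under the null. NRI and NTI are
the sign-flipped standardized effect sizes (positive = aggregation);
classification uses two-tailed null quantiles at $\alpha$ (default 0.05)
rather than a fixed $\pm1.96$ cutoff, which is robust to skewed nulls.

The swap chain is implemented in C and run by *successful* swaps: burn-in
of $10\times$fill swaps, thinning of fill swaps between samples (capped in
attempts so a checkerboard-free matrix cannot hang the sampler). Counting
raw proposal attempts instead would leave the chain autocorrelated enough
to collapse the null variance — the package's calibration simulations
(clustered assemblages detected as aggregated ≥ 80% of the time, random
assemblages flagged at roughly the nominal 5%) guard exactly this failure
mode, alongside an exhaustive-enumeration check that the sampled null MPD
matches the fixed-marginal average on small matrices.

## Keystone candidates: topology vs energy flow

`pulp_flow()` scores each plant by the dry pulp biomass its population
moves to the frugivore level:

$$\mathrm{flow} = \underbrace{\mathrm{consumption\ rate}}_{\text{fruits
h}^{-1}\text{tree}^{-1}} \times \mathrm{active\ hours} \times
\underbrace{\mathrm{pulp\ mass}}_{\text{g fruit}^{-1}} \times
\underbrace{\mathrm{density}}_{\text{trees ha}^{-1}}$$

in g ha⁻¹ day⁻¹. The published account lists the ingredients but not the
combining formula; this product is the dimensionally consistent choice,
with two documented knobs: `active_hours` (default 12 daylight hours — the
hourly rate is observed in morning activity peaks and extrapolated) and an
optional `annualize` factor crop duration/12 that averages the daily flow
over the year. Because the daily extrapolation is a modelling choice,
absolute flow magnitudes should not be over-interpreted; rankings and
list overlaps (`rank_keystones()`, `keystone_overlap()`) are the robust
outputs. `abundance_r2()` and `prediction_battery()` supply the two
regression batteries: per-plant OLS of visiting time on frugivore
abundance, and the seven trait regressions of pulp lipid content against
crop duration, seed size, frugivore size, crop size, visitation rate,
visitor richness and recruitment below parents (expected signs
+, +, +, −, −, −, −).

## The synthetic-data generator

Every stage above is exercised without any field data by the `gen_*`
family, all driven by a single integer seed (one isolated RNG stream per
call; identical seeds give byte-identical output):

* `gen_matrix()` draws a web whose binary skeleton mixes, cell-wise, a
  strict-threshold (triangular) nested archetype, a diagonal matching, and
  Bernoulli noise, with mixing weights `nestedness_level` and
  `specialization_level` (their sum at most 1). At the extremes the
  archetypes are exact: NODF = 100 at full nesting, H2' = 1 at a full
  matching. Weights are rounded log-normals with a floor of 1 so count
  indices stay well defined, and every row and column is kept non-empty.
  Defaults emulate the study conditions the package targets: 73 plants ×
  82 frugivores, noise connectance 0.08 (the observed mean normalized
  degree of such webs), nestedness 0.5, specialization 0.25, median weight
  25 fruits. Calibration is monotone: mean NODF rises with
  `nestedness_level` and mean H2' with `specialization_level` (checked by
  Spearman tests over five levels × 50 webs).
* `gen_visit_log()` inverts `fruits_handled()` in expectation: visits per
  positive pair are $1+\mathrm{Pois}(\mu-1)$, durations exponential,
  focal counts Poisson with rate chosen so that expected feeding time ×
  true rate equals the latent cell. Single-log estimates are noisy (that
  is what small focal samples look like); unbiasedness is the designed
  property and is verified over 200 replicate logs.
* `gen_phylogeny()` simulates Yule trees (`ape::rphylo`, death rate 0);
  `gen_assemblage()` draws tip sets that are clustered (a focal tip plus
  nearest neighbours by cophenetic distance), dispersed (greedy maximin)
  or uniform — the ground truth for the NRI/NTI recovery simulations.

What the generator does *not* emulate: taxonomic identity (no
primate/bird composition beyond the focal-interval split), observation
effort heterogeneity across plants, within-species variation in feeding
rates, and phylogenetic signal linking the interaction matrix to the tree.
Passing recovery tests therefore demonstrate that the estimators detect
the structure they claim to detect under known truth — not that any
particular field system has that structure.

## Numerical choices and limitations

* Percent rows are validated to sum to 100 within $10^{-6}$; `d'` and H2'
  are clamped to $[0,1]$ after standardization; degenerate cases (single
  partner, single row/column, zero null SD) return `NA` or the `random`
  class with a warning rather than failing.
* Problem sizes in the shipped tests and in `scripts/acceptance.R` are
  chosen to keep the whole suite in the tens of seconds on one core:
  study-scale webs (73 × 82) for the headline quantities, 1000/500 null
  replicates matching the published protocol, 999 swap runs × 100
  assemblages for the recovery rates, exhaustive enumerations only at
  sizes where they are exact oracles (≤ 4 × 4 matrices, totals ≤ 12).
* The package deliberately omits: alternative nestedness metrics
  (temperature, WNODF), modularity/eigenvector keystone scores,
  interaction rewiring after extinctions, and any tree inference —
  phylogenies are consumed as newick inputs.
* No command-line wrapper is shipped: the package is an analysis library
  in the style of the ecology packages it leans on, and the exported
  functions compose in a few lines of R for any of the workflows above.
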