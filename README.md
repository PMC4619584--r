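# frugnet

Analysis of plant–frugivore interaction networks: who eats whose fruit,
how the web is structured, how fragile it is, and which plants matter
most.

Community frugivory studies watch fruiting trees, record every visiting
frugivore, its feeding time and focal feeding rates, and want answers at
the community scale: is the web nested or compartmentalized? How
specialized is it relative to what its marginal totals force? Which plants
are topological hubs, and do those coincide with the plants that actually
move the most energy (fruit pulp biomass) into the frugivore community?
Are the visitor assemblages of single plants phylogenetically structured,
hinting at fruit-trait filters, or random? frugnet implements this whole
pipeline for R, with a synthetic-data module so every stage can be tested
against known ground truth.

## What it computes

Starting from a visit-record table, `fruits_handled()` builds the weighted
consumption matrix $X_{ij}$ (fruits of plant $i$ handled by frugivore
$j$ = feeding time × mean focal rate), optionally redistributing a
primate group's totals by externally estimated proportions
(`reallocate_group()`). On that matrix:

* **Species indices** (`species_indices()`): degree D and normalized
  degree ND, nested rank NR, weighted betweenness/closeness WB/WC on the
  one-mode projection, species strength SS, effective partners
  EP = $e^H$, species specificity SSP, Kullback–Leibler specialization
  $d_i = \sum_j p'_{ij}\ln(p'_{ij}/q_j)$ with its standardized $d'$, and
  the core/periphery flag $G_c = (k_i - \bar k)/\mathrm{SD}(k) \ge 1$.
* **Network structure**: `nodf()` (nestedness by overlap and decreasing
  fill, 0–100) and `h2_prime()` (two-dimensional Shannon entropy
  standardized between marginal-constrained extremes, 0–1), each with
  null-model significance via `null_test()` — ER and CE binary nulls and
  the total- and connectance-conserving weighted `vaznull_matrix()`.
* **Robustness** (`random_robustness()`, `single_removal_experiment()`):
  area R under the secondary-extinction curve, averaged over random
  removal orders, plus one-plant ablation experiments.
* **Phylogenetics** (`ensemble_indices()`): MPD/MNTD of each plant's
  visitor assemblage, NRI/NTI against an independent-swap (checkerboard)
  null, classification into aggregated / random / dispersed.
* **Keystone scores** (`pulp_flow()`): g of dry fruit pulp transferred to
  frugivores per hectare per day (consumption rate × active hours × pulp
  mass × tree density), ranked and compared against the topological
  indices with `correlate_indices()`; regression batteries
  (`abundance_r2()`, `prediction_battery()`) test whether frugivore
  abundance explains visitation and whether "specialized dispersal
  syndrome" trait correlations exist.
* **Synthetic data** (`gen_matrix()`, `gen_visit_log()`,
  `gen_phylogeny()`, `gen_assemblage()`): webs with tunable nestedness
  and specialization, visit logs that invert `fruits_handled()` in
  expectation, Yule trees, and assemblages with controlled phylogenetic
  clustering.

Results are tibbles or small S3 objects with `tidy()`, `glance()` and
`autoplot()` methods, so everything drops into a dplyr/ggplot2 workflow.

## Worked example

```r
library(frugnet)

web <- gen_matrix(n_plants = 30, n_frugivores = 40, seed = 42)
glance(web)
#>   n_plants n_frugivores scale  total  fill connectance
#> 1       30           40 counts 10348   363       0.302

nodf(binarize(web))
#> [1] 46.68619
null_test(web, "NODF", model = "ER", replicates = 1000, seed = 42)
#> <null_test> NODF vs ER null (1000 replicates)
#>   observed = 46.69; null mean = 31.56 (SD 1.702); z = 8.89; p < 0.001

h2_prime(web)
#> [1] 0.3262089

head(species_indices(web, "plants")[, c("species", "D", "ND", "NR",
                                        "SS", "EP", "d_prime",
                                        "core_flag")], 3)
#>   species  D    ND     NR    SS    EP d_prime core_flag
#> 1 P01     20 0.5   0.0690  4.21  17.6   0.358 core
#> 2 P02     18 0.45  0.207   2.63  15.6   0.385 periphery
#> 3 P03     26 0.65  0       3.89  21.3   0.270 core

random_robustness(web, "frugivores", n_orders = 100, seed = 42)
#> <robustness> removing frugivores: R = 0.909 (SD 0.024 over 100 random orders)
```

Read: this synthetic web is significantly more nested than its
equiprobable null (z ≈ 8.9), moderately specialized (H2′ ≈ 0.33 on the
0–1 scale), and highly robust to random frugivore loss (R ≈ 0.91, where 1
means no plant ever loses its last disperser until the end). The
species table identifies core plants (degree at least one SD above the
level mean) and their specialization relative to partner availability.

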