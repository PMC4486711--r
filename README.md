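# sympatry

Infer the geography of speciation — how often new species arise within the
range of their ancestor rather than in isolation — from the present-day
range overlap of sister species. The package was built around the
comparative biology of heliconiine butterflies (*Heliconius* and allies),
whose mimicry shifts and host-plant fidelity make them strong candidates
for sympatric speciation, but every component takes plain tables and works
for any clade with sister-pair ranges and divergence times.

## What it computes

For each sister pair, overlap is the area of sympatry divided by the area
of the smaller range, an index in [0, 1]; indices < 0.05 count as complete
allopatry and > 0.95 as complete sympatry. A dataset of *n* pairs is
summarised by the counts *z* (completely sympatric) and *c* (completely
allopatric) and their bimodality

> B = (z · c) / ((n/2) · (n/2)),

which is 0 when either extreme is empty and 1 when the data split evenly
between the extremes. Three inference routes are implemented:

* **Simulation-based inference.** A stochastic simulator places two
  daughter ranges on a 100 × 100 domain according to the speciation
  geometry (sympatric, vicariant, parapatric, peripatric) and then adds
  independent normal deviates to the four range edges each time step, ten
  steps per million years of branch length, restarting any pair in which a
  daughter dwindles to nothing. Observed (z, c, B) are compared with the
  simulated distributions by a two-tailed percentile test (consistent when
  inside the 2.5–97.5 percentile band); the answer is the range of
  sympatric-speciation fractions not rejected by all three indices in some
  parameter combination.
* **Age-range correlation.** OLS of arcsin √overlap on branch length; the
  intercept, back-transformed through sin², estimates the sympatric
  fraction at speciation.
* **Trait divergence.** Mimicry-ring and host-plant similarity
  (shared traits over the smaller repertoire) modelled as binomial GLMs of
  sharing on branch length with a quasi-GLM √φ standard-error correction
  under overdispersion; climatic niche overlap as intersection volumes of
  minimum convex polyhedra in a 3-component correlation-matrix PCA space,
  regressed on the angular scale; and a multiple regression of range
  overlap on all ecological similarities.

Seed-deterministic generators (`gen_pair_table()`, `gen_trait_profiles()`,
`gen_raster_stack()`, `gen_synthetic_study()`) produce study-shaped inputs
with known truth, so the whole pipeline is testable offline.

## Worked example

```r
library(sympatry)

cfg   <- sim_config(movement_sd = 0.5, ancestral_fraction = 0.16)
pairs <- gen_pair_table(22, sympatric_fraction = 0.5, cfg, seed = 7)
(obs  <- summarize_overlaps(pairs))
#> # A tibble: 1 × 4
#>       n     z     c bimodality
#>   <int> <int> <int>      <dbl>
#> 1    22     7    10      0.579

sweep <- run_sweep(gen_branch_lengths(22, seed = 7),
                   movement_sd = c(0.5, 1), ancestral_fraction = 0.16,
                   geometry = "vicariant", n_replicates = 200, seed = 8)
consistent_sympatric_range(obs, sweep)
#> <sympatry_inference>
#>   observed: n = 22  z = 7  c = 10  bimodality = 0.579
#>   jointly consistent sympatric fraction: 32% - 59%

arc_regression(pairs)
#> <arc_fit> age-range correlation (angular scale), n = 22 pairs
#>   intercept 0.69 +/- 0.27  (back-transformed 0.40)
#>   slope     0.02 +/- 0.05  (P = 0.76)
```

Of the 22 synthetic pairs (generated with a true sympatric fraction of
0.5), 7 ended completely sympatric and 10 completely allopatric; the
percentile inference brackets the truth at 32–59%, and the age-range
intercept back-transforms to an estimated 0.40 sympatric fraction. Fitted
objects have `tidy()` / `glance()` methods, and `autoplot()` draws the
overlap histogram, the fitted correlation, the sweep medians and the
consistency map.

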