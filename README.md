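# florsel

Quantifying herbivore-mediated phenotypic selection on floral traits across
plant populations.

Floral herbivores consume flowers, fruits and seeds, and in doing so can act
as agents of natural selection on floral display and phenology. `florsel`
implements the full inference chain for paired herbivore-present (HP) /
herbivore-exclusion (HE) field experiments replicated across populations:

1. **Selection gradients** (Lande–Arnold): within each population ×
   treatment slice, relative fitness *w* = seeds / mean(seeds) is regressed
   by OLS on variance-standardized traits *z* (flowering start date, flower
   number, corolla size). The partial regression coefficients β are the
   directional selection gradients; optional squared terms give quadratic
   gradients γ = 2 × the fitted coefficient. Variance inflation factors
   diagnose collinearity.
2. **Opportunity for selection**: *I* = Var(*w*) per slice, the upper bound
   on the strength of selection.
3. **Herbivore-mediated selection**: the treatment contrast
   Δβ_herb = β_HP − β_HE with propagated standard error
   √(SE²_HP + SE²_HE), and its per-population significance from the
   trait × treatment ANCOVA interaction.
4. **Two-way ANOVAs** of traits, herbivory intensity and fitness components
   on population × treatment (log₁₀ / √ transforms, sequential or marginal
   sums of squares), and pooled ANCOVAs testing spatial variation in net
   (trait × population) and herbivore-mediated
   (trait × population × treatment) selection.
5. **Across-population meta-regression** on herbivory intensity *x* (the
   population mean proportion of flowers damaged, HP plants):
   - opportunity for selection on *x*, linear vs quadratic OLS compared by
     AIC ("models A/B");
   - |Δβ_herb| on *x*, linear vs quadratic Bayesian measurement-error
     regression compared by DIC ("models C/D"). Because |Δβ| is an absolute
     value of a noisy estimate, its sampling variance is taken from the
     **folded normal distribution**; the hierarchical model
     y_j ~ N(θ_j, se²_j), θ_j ~ N(c₀ + c₁x_j + c₂x²_j, σ²) with known se_j
     is fitted by a conjugate Gibbs sampler (compiled), with
     vertex −c₁/(2c₂) locating the intensity at which selection peaks.
6. **A synthetic-data generator** (`simulate_study()`) that emulates the
   paired multi-population design — 11 populations, 60–125 pairs each,
   population mean herbivory intensities spanning ~0.15–0.56, herbivore
   preference linked to flower number and flowering start, seed loss
   proportional to damage — so every stage is testable end to end without
   field data.

All user-facing functions take a data frame first and return tibbles;
results have `tidy()` / `glance()` and `autoplot()` methods.

## Input format

`read_plant_table()` / `write_plant_table()` handle delimited text (CSV
default, TSV via `delim = "\t"`, UTF-8, header required) with exactly these
columns, one row per plant:

| column | meaning |
|---|---|
| `population_id` | population label |
| `pair_id` | plant-pair label within the population |
| `treatment` | `HP` (herbivores present) or `HE` (herbivores excluded) |
| `flowering_start` | day of year the first flower opened |
| `n_flowers` | total flowers produced |
| `corolla_size` | mean corolla diameter of the first three flowers, mm |
| `n_fruits` | fruits at maturation |
| `seeds_per_fruit` | mean seeds per fruit |
| `seeds_total` | total seeds per plant (female fitness) |
| `n_damaged_flowers` | flowers showing herbivory |

Per-plant herbivory intensity is `n_damaged_flowers / n_flowers`; validation
enforces `n_damaged_flowers ≤ n_flowers`, `n_fruits ≤ n_flowers`, one record
per (population, pair, treatment), and both treatments in every population.

## Worked example

```r
library(florsel)

plants <- simulate_study(sim_config(n_populations = 5,
                                    pairs_per_population = 60, seed = 2024))
population_intensity(plants, "HP")
#>   population_id treatment  mean    sd     n
#> 1 pop01         HP        0.158 0.239    60
#> 2 pop02         HP        0.207 0.277    60
#> 3 pop03         HP        0.346 0.303    60
#> 4 pop04         HP        0.383 0.326    60
#> 5 pop05         HP        0.448 0.345    60
```

Population mean HP intensity rises across populations as configured; HE
intensity is zero under perfect exclusion. Gradients per slice:

```r
selection_gradients(plants) |> dplyr::filter(population_id == "pop03")
#>   population_id treatment trait               beta     se        p   vif     n
#> 1 pop03         HE        flowering_start  0.00157 0.0286 9.56e- 1  1.06    60
#> 2 pop03         HE        n_flowers        0.423   0.0280 2.02e-21  1.01    60
#> 3 pop03         HE        corolla_size    -0.0279  0.0286 3.32e- 1  1.05    60
#> 4 pop03         HP        flowering_start -0.0647  0.0755 3.95e- 1  1.16    60
#> 5 pop03         HP        n_flowers        0.313   0.0753 1.11e- 4  1.16    60
#> 6 pop03         HP        corolla_size     0.0245  0.0705 7.30e- 1  1.01    60
```

Both treatments show strong positive selection on flower number (more
flowers → more fruits → more seeds); the HP gradient is weaker because
herbivores preferentially attack many-flowered plants and remove part of
their fitness advantage. The treatment contrast isolates that effect:

```r
med <- mediated_selection(plants)
dplyr::filter(med, trait == "n_flowers")
#>   population_id trait     delta_beta     se p_interaction     p_z
#> 1 pop01         n_flowers    -0.0605 0.0614       0.292   0.324
#> 2 pop02         n_flowers    -0.161  0.0666       0.0162  0.0158
#> 4 pop04         n_flowers    -0.204  0.0680       0.00344 0.00276
#> ...
```

`delta_beta` is β_HP − β_HE, `se` its propagated error, `p_interaction` the
trait × treatment ANCOVA test. Folding the contrasts and regressing their
magnitude on herbivory intensity with known sampling error:

```r
pts <- fold_points(med, population_intensity(plants, "HP"))
bayes_meta(dplyr::filter(pts, trait == "n_flowers"), degree = 2, seed = 11)
#> Bayesian quadratic meta-regression (n = 5)
#>    estimate       se      2.5%    97.5%
#> c0 -0.21319  1.01380  -1.49374  1.33076
#> c1  2.45797  7.31596  -8.83162 12.64258
#> c2 -3.91106 12.01362 -20.42236 14.56614
#> DIC = -11.467, vertex at x = 0.3142
```

With only five populations the curvature is uncertain, but the point
estimate peaks at intermediate intensity (vertex ≈ 0.31). `run_pipeline()`
chains all stages and writes `gradients.csv`, `mediated.csv`,
`opportunity.csv`, `intensity.csv`, `meta_fits.json` and a `summary.txt`,
reproducibly for a given seed.

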