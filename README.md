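# stockmix

Connectivity analysis for sea-turtle mixed stocks. Immature turtles sampled
at a feeding ground are a mixture of animals from many nesting populations
(rookeries); `stockmix` estimates where they came from, using two
independent data streams, and measures how well the two agree:

* **Genetics** — mitochondrial control-region haplotype frequency tables,
  analysed with Nei diversity estimators, TN93 distances, pairwise
  F<sub>ST</sub>/Φ<sub>ST</sub> and hierarchical AMOVA with permutation
  inference, and a **many-to-many Bayesian mixed stock analysis**: every
  rookery *r* has a destination simplex φ<sub>r</sub> over all feeding
  grounds plus an UNKNOWN sink, and the mixture sampled at feeding ground
  *m* is

  θ<sub>m,r</sub> = S<sub>r</sub> φ<sub>r,m</sub> / Σ<sub>r′</sub> S<sub>r′</sub> φ<sub>r′,m</sub>,

  where S<sub>r</sub> (nesting females per season) enters as an ecological
  covariate. Fitting is by Gibbs sampling over latent natal-rookery
  assignments with Metropolis updates for φ, one chain per rookery, and
  Gelman–Rubin convergence diagnostics.
* **Oceanography** — surface drifter trajectories (Global Drifter Program
  style CSV). Drifters passing a 4°×4° box around each rookery and later
  reaching a target feeding region are counted (k<sub>rt</sub> of
  n<sub>r</sub>, after excluding drifters transmitting < 90 days), and the
  natal-origin probability is the Beta(1,1)-smoothed, size-weighted

  P(r | t) ∝ (k<sub>rt</sub> + 1)/(n<sub>r</sub> + 2) · S<sub>r</sub>.

* **Concordance** — a permutation (Mantel-type) correlation between the
  genetic and drifter origin-profile matrices, and ordinary least squares
  on log-transformed paired proportions.

A synthetic-data module generates haplotype tables, aligned sequences and
drifter tracks with *known* ground truth, so the entire pipeline is
testable offline; a packaged haplotype-frequency table for five Brazilian
feeding aggregations (157 samples, ten 740-bp haplotypes) serves as the
real-data fixture.

## Worked example

```r
library(stockmix)

tab <- read_haplotype_table(system.file("extdata", "table1_740bp.csv", package = "stockmix"))
diversity_summary(tab)
#> # A tibble: 5 × 5
#>   pop             n n_hap     h   se_h
#>   <chr>       <int> <int> <dbl>  <dbl>
#> 1 SPSP           12     4 0.636 0.128
#> 2 Ceara          23     4 0.249 0.116
#> 3 Bahia          32     5 0.433 0.105
#> 4 Abrolhos       65     5 0.203 0.0662
#> 5 SouthBrazil    25     3 0.503 0.0979
```

The offshore archipelago (SPSP) is the most diverse aggregation (h = 0.64):
it sits where several current systems meet and receives settlers from many
sources, while the coastal park (Abrolhos) is dominated by one haplotype
(h = 0.20). Collapsing the ten long-fragment haplotypes onto their legacy
short-fragment equivalents leaves eight:

```r
short <- collapse_haplotypes(tab, read_collapse_map(
  system.file("extdata", "collapse_382bp.csv", package = "stockmix")))
nrow(short)
#> [1] 8
```

A full mixed-stock run on synthetic data with known mixing (chain length
shortened here for speed; analyses use 20,000):

```r
cfg <- sim_scenario("benchmark", seed = 711)
rk  <- gen_rookery_tables(cfg)
fg  <- gen_feeding_tables(cfg, rk$freqs)
msa <- filter_orphans(fg, rk$table, sizes = cfg$sizes)  # warns about unsampled haplotypes
fit <- fit_many_to_many(msa$input, chain_length = 2000, seed = 711)
fit
#> # many-to-many mixed stock fit: 4 rookeries -> 5 feeding grounds
#> # 4 chains x 2000 sweeps (burn-in 1000, thin 1), seed 711
#> # Gelman-Rubin: max 1.113, mean 1.027
#> # feeding-ground-centric posterior means (theta):
#>        R01   R02   R03   R04
#> FG01 0.516 0.147 0.233 0.103
#> FG02 0.121 0.667 0.117 0.095
#> FG03 0.111 0.179 0.609 0.100
#> FG04 0.144 0.114 0.159 0.583
#> FG05 0.320 0.327 0.193 0.160
```

Each feeding ground's row estimates the proportion of its animals
originating from each rookery; the generator's true dominant source (0.6 on
the diagonal for FG01–FG04, uniform for FG05) is recovered. `tidy(fit)`
returns the long table with 95% credible intervals,
`tidy(fit, view = "rookery")` the rookery-centric destination shares, and
`autoplot(fit)` the stacked contribution chart. Drifter counting and the
origin estimator work the same way from `gen_drifter_tracks()` /
`read_drifter_tracks()` through `count_passages()` and
`origin_posterior()`; `mantel_test()` and `log_profile_regression()`
compare the two origin profiles.

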