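---
title: "Estimating natal origins of mixed feeding aggregations: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating natal origins of mixed feeding aggregations: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stockmix)
```

Sea turtles hatch on a nesting beach (a *rookery*), disperse with surface
currents, and recruit as immatures to coastal feeding grounds far from home.
A feeding aggregation is therefore a *mixed stock*: a blend of animals from
many rookeries. `stockmix` estimates that blend from two independent data
streams — mitochondrial control-region haplotype frequencies, and satellite-
tracked surface drifter trajectories — and quantifies how well the two
agree. This vignette documents the models, the tunable parameters, the
synthetic-data generator used for validation, and the numerical choices a
user should know about.

## Data model

A haplotype table (`hap_table`) is a haplotypes-by-populations integer count
matrix with a role per population (`rookery` or `feeding`), optional group
labels, and a locus tag. Two locus conventions coexist in this field:
long-fragment haplotypes (here tagged `740bp`) resolve more variants, while
the legacy short fragment (`382bp`) is what most Atlantic populations were
scored on. `collapse_haplotypes()` maps long haplotypes onto their short
equivalents by summing rows; it is a pure relabeling, so per-population
sample sizes are conserved by construction. Haplotypes observed at a feeding
ground but at no characterized rookery ("orphans") cannot be attributed to
any source and are removed by `filter_orphans()` before mixture estimation;
haplotypes that do occur at a rookery are always retained, including
introgressed (hybrid-lineage) sequences, because their rookery presence makes
them informative about origin.

## Diversity estimators

Gene (haplotype) diversity is Nei's unbiased estimator
$\hat h = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$,
with Nei's (1987) sampling variance for the standard error. Nucleotide
diversity is
$\hat\pi = \frac{n}{n-1} \sum_{ij} p_i p_j d_{ij}$
with $d_{ij}$ the per-site distance between haplotypes $i$ and $j$; its
standard error uses Tajima's total variance and therefore needs the
alignment length. With exactly two haplotypes, $\hat\pi$ reduces to
$\frac{n}{n-1} 2 p_1 p_2 d$ — the identity the test suite asserts.
Published diversity values for these data could not be reproduced from the
published count table under any standard estimator we evaluated (e.g. counts
7/1/3/1 give $\hat h = 0.636$, not the printed 0.644, though the printed
standard error 0.128 matches Nei's formula exactly); the tests therefore
use the formula itself as the oracle rather than printed values.

## Distances and population structure

`tn93_distance()` implements the Tamura–Nei (TN93) closed form, which
separates the two transition types (A↔G, C↔T) from transversions and allows
unequal base frequencies. Frequencies are pooled over the two sequences of
each pair; sites with a gap in either member are excluded pairwise (rather
than deleting the site across the whole alignment), which maximizes usable
sites on short fragments. Saturation (a logarithm argument reaching zero)
raises an error naming the pair instead of returning `NaN`. With equal base
frequencies and balanced transition types the formula reduces exactly to
Kimura's K80, and further to Jukes–Cantor when all six substitution types
are equally represented; those reductions are asserted to `1e-9`.

Structure statistics use the Excoffier–Smouse–Quattro analysis of molecular
variance. Supplied haplotype distances play the role of squared
inter-individual distances (the convention of the standard desktop
software): the identity matrix yields the classical frequency $F_{ST}$, a
TN93 matrix yields $\Phi_{ST}$. The three-level design partitions variance
among groups ($\Phi_{CT}$), among populations within groups ($\Phi_{SC}$),
and within populations ($\Phi_{ST}$), with the unequal-sample-size moment
coefficients. Permutation inference matches each statistic's null:
individuals among all populations for $\Phi_{ST}$, individuals within
groups for $\Phi_{SC}$, whole populations among groups for $\Phi_{CT}$.
The p-value counts permuted statistics at least as large as the observed
one with the observed configuration included, so the smallest attainable
value is $1/(n_{\mathrm{perm}}+1)$; the default is 10,000 permutations
(the permutation count is a display convention, not stated by the data
sources this design follows). Negative indices are reported raw and
truncated to zero only for display.

## The many-to-many mixed stock model

The estimator treats rookeries as sources with known relative output.
Each rookery $r$ has:

* a haplotype pool $f_r$ (Dirichlet(1) prior, updated by the rookery
  sample — conjugate);
* a destination simplex $\phi_r$ over all feeding grounds plus an UNKNOWN
  sink (Dirichlet(1) prior), answering "where do hatchlings of $r$ end up";
* a size $S_r$ (nesting females per season), the ecological covariate.

The mixture sampled at feeding ground $m$ is
$$\theta_{m,r} = \frac{S_r\,\phi_{r,m}}{\sum_{r'} S_{r'}\,\phi_{r',m}},$$
so a large rookery is a priori a likelier source of any given immature
turtle. Each sampled individual carries a latent natal rookery $z$ with
$\Pr(z = r) \propto \theta_{m,r} f_{r,h}$ given its haplotype $h$.

Sampling is Gibbs over $z$ (per-haplotype multinomial blocks) and $f_r$
(conjugate Dirichlet), with Metropolis-within-Gibbs for each $\phi_r$,
whose full conditional
$\prod_m \phi_{r,m}^{N_{rm}} \big/ \prod_m D_m^{n_m}$
(with $D_m$ the size-weighted normalizer) is non-conjugate because all
rookeries compete through $D_m$. Three moves are combined per sweep: an
independence proposal from the Dirichlet that would be exact if $D_m$ were
constant; an adaptive random-walk Dirichlet proposal (concentration tuned
toward a 20–45% acceptance rate during burn-in only, then frozen, keeping
the post-burn-in kernel valid); and a log-odds random walk on the UNKNOWN
share, which is the weakly identified direction — data constrain $\phi$
mostly through ratios, so the split between observed feeding grounds and
the UNKNOWN sink mixes slowly under generic proposals.

Defaults follow the field's survey practice: chain length 20,000 with half
discarded as burn-in, one chain per rookery initialized with every
individual assigned to that rookery (overdispersed starts), and the
Gelman–Rubin potential scale reduction factor computed across chains for
every stored $\theta$ and $\phi$ component. The feeding-ground-centric
$\theta$ is derived from $\phi$ at every sweep, so both views come from the
same posterior; every stored simplex sums to one to $10^{-9}$.

Two analytic limits pin the covariate's role and are asserted in tests:
with a single rookery $\theta \equiv 1$; and with two rookeries fixed for
disjoint haplotypes and a 50/50 feeding sample, the posterior mean of
$\theta$ stays at (0.5, 0.5) even under 9:1 sizes — the data dominate the
mixture while the rookery-centric $\phi$ absorbs the size imbalance.

## Drifter-based origins

Rookeries get 4°×4° boxes centered on their coordinates; feeding grounds
with similar current exposure are grouped into target regions configured as
box sets (2° half-width by default — an artifact convention, since arrival
geometry is not standardized). Drifters transmitting less than 90 days are
excluded (boundary inclusive). A drifter counts once toward $n_r$ at its
first fix inside box $r$ and once toward $k_{rt}$ if any fix at or after
that entry lies in target $t$; arrival must follow passage, and one drifter
may count for several rookeries. The origin probability combines a
Beta(1,1)-smoothed arrival rate with rookery size:
$$\Pr(r \mid t) \propto \frac{k_{rt}+1}{n_r+2}\, S_r ,$$
normalized over rookeries. The smoothing keeps every rookery's probability
strictly positive — a finite drifter sample cannot rule a source out — and
in the limit of no arrivals and equal passage counts the posterior is
exactly proportional to rookery size. The full Bayesian machinery behind
the published drifter estimates lives in a prior publication; the smoothed
estimator above is this package's explicit, documented model, chosen to
reproduce the published estimator's qualitative behavior (zero-count
sources keep mass; columns normalize).

## Concordance

`mantel_test()` correlates two target-by-rookery profile matrices by the
Pearson correlation of their paired entries and builds the null by
permuting the rows and columns of one matrix (9,999 permutations by
default). This generalizes the classical square-matrix test to the
rectangular profile matrices the comparison actually produces; whether the
original comparison operated on raw profiles or a dissimilarity transform
is not stated in the sources this design follows, so the profile-matrix
form is the documented contract. `log_profile_regression()` regresses
log drifter proportions on log genetic proportions; zero proportions are
replaced by half the smallest nonzero value of their own profile before
logging (configurable to dropping the pair instead).

## The synthetic-data generator

Every stage of the pipeline is exercised without downloads by
`sim_config()` and the `gen_*()` generators, which are pure functions of
`(configuration, seed)`: each generator draws from a substream derived by
hashing its name with the root seed, so adding a generator never perturbs
another's output.

* **Rookery pools** are symmetric Dirichlet draws (concentration 0.2 by
  default — sparse, realistic for control-region haplotype frequency
  vectors, which are typically dominated by one or two variants).
* **Feeding samples** draw each individual's source from a known mixing row
  and then a haplotype from that source's pool — exactly the mixture the
  estimator inverts, so recovery can be measured against known truth. The
  realized source counts are attached to the table, because at 100 samples
  per feeding ground the realized composition itself deviates from the
  mixing matrix by up to ~0.1 (binomial noise), and that is the quantity
  the data can identify.
* **Sequences** sprinkle substitutions on a random root with a controlled
  transition probability, one dedicated site per haplotype guaranteeing
  distinctness.
* **Drifter tracks** are daily-fix piecewise-linear paths released inside
  each rookery's box, reaching each target with a configured probability by
  waypoint insertion, with lognormal lifespans (median 300 days, log-sd 0.8
  — matching typical reported drifter longevities of roughly 290–450 days
  and leaving a realistic ~10% under the 90-day cutoff).

The benchmark scenario (`sim_scenario("benchmark")`) has 4 rookeries, 5
feeding grounds of 100 samples each, 60 samples per rookery, 12 haplotypes,
and equal rookery sizes. Two design choices deserve emphasis. First,
"well-separated pools" is *enforced*: pools are redrawn until every pair
overlaps by less than 0.3 (overlap $=\sum_h \min(f_r, f_s)$), because a
single confusable pair of rookeries makes their contributions mutually
unidentifiable at these sample sizes regardless of the estimator. Second,
the benchmark uses equal rookery sizes so that it measures the sampler, not
the covariate: with strongly unequal sizes the size term acts as an
informative prior that deliberately shrinks small rookeries' contributions,
which is desired behavior but a confound in a recovery check; the
covariate's effect is pinned separately by the analytic disjoint-haplotype
cases. The `"paperlike"` scenario (13 rookeries / 875 samples, 6 feeding
grounds / 1,361 samples, sizes spanning two orders of magnitude) mirrors a
full Atlantic survey's scale for workflow demonstrations.

What passing these synthetic benchmarks does *not* show: real control-region
data violate the generator's assumptions in known ways — rookery pools are
phylogenetically correlated rather than independent Dirichlet draws, real
feeding aggregations mix age classes with different dispersal histories, and
real drifter tracks follow currents rather than waypoints. The benchmarks
validate the estimators' correctness and calibration, not the field
realism of any particular dataset.

## Problem sizes and runtimes

The shipped validation uses the 4×5 benchmark at chain length 20,000 with
4 chains (about 1.5–2 minutes on one core), 200 seeded two-population
instances for the fixation-index oracle comparison, and 500 replicates at
199 permutations for the permutation-test calibration — sizes chosen so the
whole suite documents the method at desk scale while remaining quick to
re-run.

## Known limitations

* Fixation indices and AMOVA assume the supplied distances behave like
  squared distances; no check enforces metricity.
* The Metropolis step for $\phi$ is adequate for tens of rookeries but has
  not been profiled beyond that; very large metapopulations may need longer
  chains.
* The UNKNOWN destination share is weakly identified by design — credible
  intervals for $\phi_{r,\mathrm{UNKNOWN}}$ are honest but wide.
* IUPAC ambiguity codes are rejected, not resolved; upstream consensus
  calling must produce unambiguous states.
* Antimeridian-crossing boxes are supported, but polar geometry is not
  (boxes are lat/lon rectangles).
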