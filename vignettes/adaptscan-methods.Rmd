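---
title: "Models and methods behind adaptscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind adaptscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(adaptscan)
```

adaptscan studies local adaptation in structured diploid plant panels —
the motivating system is a collection of fruit-tree landraces and wild
relatives spread across strong climatic gradients, divided into seven
ecotype-like groups.  The package covers three questions end to end:
where has selection reshaped the genome (selective-sweep scans and a
consensus region caller), which variants track climate (environmental
association under correction for relatedness and structure), and how do
adaptive phenology traits behave over decades of observation (bloom-date
decomposition, cold hardiness, chilling requirement).  A forward-time
simulator generates benchmark panels with known truth so every stage can be
validated quantitatively.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the limits of what the simulator-based
validation can show.

## The benchmark generator

`simulate_population()` runs a discrete-generation Wright–Fisher model of
`n_demes` diploid demes joined by a symmetric island model: each gamete's
parent is drawn from another deme with probability `migration_rate`
(default 0.02) and from its own deme otherwise.  Mutation is infinite-sites
on integer base pairs at `mut_rate` per bp per generation; recombination is
a single crossover per gamete placed uniformly, occurring with probability
`min(1, rec_rate * seq_length)`.  A forward simulator (not a coalescent)
was chosen so that hard sweeps, migration and phasing are explicit rather
than approximated; the per-generation loop is compiled code driven by R's
RNG, so a scenario plus seed reproduces its output byte for byte.

A sweep is a designated allele injected on one haplotype of its deme at a
start generation; fitness within that deme (only) is multiplied by
`1 + s * dosage`.  Selection local to the deme is the local-adaptation
reading of a group-specific sweep: the allele is beneficial where its
climate applies and neutral elsewhere.  Establishment is enforced by
rejection: a lost sweep allele is re-injected (up to 100 retries, then
`"sweep not establishable"`), and the per-generation frequency trajectory
is recorded in the ground truth.

The default panel emulates a seven-group landrace collection.  Group sizes
with published counts are fixed (NE 19, ST 14, TB 45) and the remaining
four groups were chosen once so the six landrace groups sum to 211
accessions (YG 60, NW 38, NP 46, YT 34).  Default rates
(`mut_rate = rec_rate = 2.5e-7` per bp, 1-Mb region, `4 * mean(deme_size)`
generations) put nucleotide diversity near `1e-4`–`1e-3` per bp at a
desk-scale population size — mutation and recombination are rescaled
upward as population size is scaled down, the standard practice in
forward simulation, preserving the population-scaled compounds
`4 N mu` and `4 N r` that the statistics actually see.

`simulate_environment()` draws each environmental variable (EV) as a deme
mean plus Gaussian noise (`noise_sd`, default 0.3 on a standardized
gradient).  A fraction `shared_frac` (default 0.7) of the 51 EVs load with
random sign on a single shared latitudinal gradient, making them strongly
collinear — the situation that motivates summarizing EVs by their first
principal component, which then carries well over half the variance.  The
remaining EVs get independent deme means.

`simulate_phenotypes()` produces three panels with known truth: bloom
dates `BD[i, y] = mu + sum_k beta_k g[ik] + gamma_bd * dT[y] + eps`, where
`dT` is a linear warming series (`warming_rate`, default 0.05 °C/yr over
1983–2011) and `gamma_bd` defaults to `-10 / (0.05 * 28)` days/°C so the
population-true advance in bloom date over the 28-year span is exactly ten
days; relative-conductance curves from the logistic freezing-damage model
at the six standard treatment temperatures (−10 … −35 °C) with
per-accession true LT50 ~ Normal(−22.5, 3) and slope `k = 0.4`; and an
hourly winter temperature series (90 days, seasonal dip plus diurnal
cycle) for chilling-hour counting.

What the generator does *not* emulate: genome-scale heterogeneity
(recombination and mutation-rate maps, repeats, callability), genotyping
error, soft sweeps and polygenic selection, range expansion or admixture
history, and multi-chromosome layouts.  Passing the recovery tests
therefore shows that the statistics are implemented correctly and behave
as designed under clean hard-sweep and island-model conditions — not that
they would attain the same power on a real resequencing panel.

## Windowed diversity and differentiation

All windowed statistics use sliding windows (default 10 kb, 1-kb step, the
standard scan resolution) on 0-based half-open coordinates internally;
VCF/GFF input is 1-based, BED output 0-based.  Windows with fewer sites
than a metric's minimum (1 for diversity and FST, 3 for Tajima's D) carry
`NaN` and never enter outlier ranking.

* `windowed_pi()`: per site `2 c (n - c) / (n (n - 1))` on called alleles,
  summed and divided by the full window span (no callability mask — the
  simulator has none, and diversity scans on real data conventionally use
  the nominal span).
* `tajimas_d()`: the classical standardized difference between pairwise
  diversity and Watterson's estimator; when missingness makes the
  called-allele number vary, the constants use the window's modal value.
* `weir_cockerham_fst()`: the 1984 variance components from genotype
  counts, `a/(a+b+c)` per SNP and ratio-of-sums per window; per-SNP
  estimates may be slightly negative (meaningful evidence of no
  differentiation), window values are clamped to [0, 1] on report.
* `rod()`: `1 - pi_target / pi_reference`, with the reference conventionally
  the pooled samples of the other groups rather than a mean of per-group
  values.

## Sweep-model scans

`background_sfs()` tabulates the genome-wide derived-allele frequency
spectrum (ALT is the derived state, which the simulator guarantees;
`folded = TRUE` collapses it when ancestral states are unknown).

`clr_scan()` contrasts, at each grid position, a hitchhiking-distorted
spectrum against the background.  A lineage at distance `d` escapes the
sweep with probability `1 - exp(-alpha d)`; the escaped lineages plus one
extra lineage — the sweeping haplotype that every non-escaped lineage
coalesces into — form a hypergeometric draw from the background
configuration, and the extra lineage's allele is copied to all non-escaped
lineages.  At full escape this returns the background exactly.  Two
numerical points matter.  First, the composite likelihood includes an
invariant-position term: using the chromosome's per-bp polymorphism rate
as background, positions without a SNP lend strong support inside the
diversity trough a sweep predicts; without this term the scan is blind to
the trough itself, which after a completed sweep is most of the signal.
Second, spectrum probabilities are floored at `1e-12` so a single
post-sweep recovery mutation inside the predicted trough cannot veto the
model with an infinite penalty.  `alpha` is maximized per grid point over
a log grid plus golden-section refinement within `alpha_range`
(default `1e-7`–`1e-2` per bp; `1/alpha` is roughly the footprint
described).  Grid points are restricted to positions with `max_dist` of
flanking sequence on both sides, because a truncated flank makes the
invariant term incomparable across positions.

`mu_scan()` slides windows of `snps_per_window` consecutive SNPs (so low
SNP density stretches a window's physical span) and multiplies three
signals: relative span (`mu_var`), pseudo-counted share of singletons plus
highest-frequency sites normalized by its genome-wide mean (`mu_sfs`), and
the ratio of within-half to cross-half mean r² with `epsilon = 0.01`
(`mu_ld`).  The three-signal design follows the composite-statistic idea
from the sweep-scan literature; the exact normalizations are this
package's own and are validated by recovery tests rather than by
equivalence to any external tool.  r² uses haplotypes when phased (capped
at `ld_max_haps = 200` rows — the estimate is stable far below typical
panel sizes and the correlation matrices dominate the scan's cost), else
dosages.

`ihs_scan()` computes extended haplotype homozygosity outward from each
core SNP with derived frequency in [0.05, 0.95], integrating by trapezoid
in physical bp (no genetic map) until EHH falls below 0.05, and
standardizes `ln(iHH_A / iHH_D)` within derived-frequency bins of width
0.05.  Bins with fewer than 10 scores are set `NaN` with a warning.  The
score is reported signed; a two-sided threshold such as `|iHS| > 2.5`
flags either tail.

`consensus_regions()` implements the outlier-consensus rule: per metric,
windows at or beyond the empirical top-`tail_fraction` quantile (ties
included, matching "top 5 % (>= threshold)" semantics; lower tail for
diversity and, by default, Tajima's D), merged when overlapping or
touching; merged spans of the union over metrics are candidate selection
regions when at least `min_metrics` metrics contribute >= 1 bp.  For a
wild-group style upper-tail D scan pass `tail_side = c(tajd = "high")`.

## Environmental and trait association

`kinship_matrix()` is mean identity-by-state, `(2 - |d_i - d_j|)/2` over
jointly called sites, bent to positive semidefiniteness by flooring
eigenvalues at `1e-6` and rescaling to a unit diagonal (the bend can move
an entry by ~1e-6, which is why duplicate samples read 1 only to that
tolerance).

`emmax_scan()` fits the null mixed model `y = X beta + u + e`,
`cov(u) = sigma_g^2 K`, once by REML — a 100-point grid on
`ln(delta) in [-10, 10]` for the variance ratio `delta =
sigma_e^2/sigma_g^2`, then golden-section refinement — and reuses the null
variance components for every marker (the population-parameters-
previously-determined approximation; `per_marker_reml = TRUE` re-maximizes
per marker).  Fixed effects are an intercept plus `n_pcs = 3` genotype
principal components.  Markers are tested by generalized least squares in
the eigenrotated, whitened space with a two-sided t test.  Missing
dosages are mean-imputed per variant for association only, never for the
diversity statistics.  Bonferroni thresholds are always computed as
`alpha / n_tests` from the post-filter variant count rather than quoted as
constants.

`lfmm_scan()` is a ridge-penalized alternating least-squares latent-factor
model (`K = 3` factors by default): `Y = x b' + U V' + E` with `U`
initialized from the top left singular vectors of `Y` residualized on `x`,
alternating `(V|U)`, `(U|V)`, `(b|U,V)` until the relative objective
change is below `tol`.  A deterministic ridge solver was preferred over
MCMC: same estimand, reproducible, desk-scale.  Per-locus z-scores are
calibrated by genomic control — `z^2` divided by `median(z^2)/0.456` — and
referred to chi-square(1); the reported `lambda_gif` is the pre-calibration
inflation.  Under a null predictor it concentrates near 1, though any
single scan's median over correlated loci is noisy; calibration checks
use the median over several null predictors.

`hotspot_loci()` merges significant SNPs within `cluster_bp = 10 kb` into
loci and reports those associated with strictly more than `min_evs = 5`
distinct EVs, the "more than five" reading of the hotspot rule.

## Trait analytics

`ammi_decompose()` works on accession-by-year cell means (replicates
averaged first): two-way main effects, then SVD of the doubly centered
interaction.  IPCA degrees of freedom follow Gollob,
`(g-1) + (e-1) - 2k + 1`, each term F-tested against the pooled remaining
interaction, and the main effects against the full interaction mean
square — with cell means there is no independent replicate error term, a
declared simplification.  Missing cells are imputed as row mean + column
mean − grand mean and flagged.  The share of bloom-date variation
explained by a warming driver is operationalized as the squared
correlation between the year main effects and the yearly temperature
anomaly (`driver = "ipca1"` switches to the first IPCA year scores): the
driver claim concerns the year-to-year shift of the whole panel, which
lives in the year main effects.

`abd_slopes()` regresses bloom day-of-year on calendar year per accession
(minimum 5 years) and reports the advance as `-slope * span`, so positive
values mean earlier bloom — ten days of advance over 1983–2011
corresponds to a slope of −0.357 d/yr.

`fit_lt50()` fits `RC(T) = 1/(1 + exp(k (T - LT50)))`, `k > 0`, by
Levenberg–Marquardt least squares, multi-started over
`k in {0.1, 0.3, 1.0}` with LT50 initialized at the temperature whose
conductance is nearest 0.5 and bounded to the tested range ± 10 °C to
prevent divergence on flat curves.

`chilling_hours()` counts hours in `(0, 7.2]` °C: an hour at exactly 0 °C
is excluded, one at exactly 7.2 °C counts.  `classify_yearly_associations()`
partitions multiyear association SNPs into temporary (1 year), recurrent
(2–5) and stable (> 5).

## Cross-stage synthesis

`genes_in_regions()` reports genes overlapping candidate regions by >= 1 bp
(half-open intervals, strand ignored).  `mantel_test()` correlates the
upper triangles of a genetic distance (default `1 - IBS`) and an
environmental distance (Euclidean on standardized EVs, altitude included
as an EV), with a one-sided permutation p-value
`(1 + #{r_perm >= r_obs}) / (1 + n_perm)` — one-sided because the claim
under test is a positive association between genetic and environmental
divergence.

## Validation design and problem sizes

The acceptance suite (`tests/testthat/test-acceptance.R`) runs entirely on
simulated data.  The sizes were chosen once as the smallest scenarios in
which each property is statistically decidable:

* *Neutral calibration*: one deme of 100 diploids, 1 Mb, ~5 000 SNPs;
  mean windowed Tajima's D in [−0.7, 0.7], random-split FST below 0.02,
  segregating sites within 3 SD of Watterson's expectation.  The
  site-frequency GOF test pools the sites of 6 000 small, fully
  equilibrated replicates tuned to ~1 segregating site each: sites within
  one simulated chromosome share a genealogy, so their class counts are
  far over-dispersed relative to the multinomial a chi-square test
  assumes — a property of linked data, not of any particular simulator —
  and one site per independent replicate restores near-independence
  without biasing the spectrum.  (Burn-in matters at this precision: a
  population sampled before mutation–drift equilibrium shows a singleton
  excess the test detects.)
* *Sweep recovery*: a 1 000-diploid target deme against a 60-diploid
  reference, isolated (no migration, so fixation is absorbing and the
  sampled trough is clean), 1 Mb, `s = 0.05` (`2Ns = 100`) swept for 300
  generations after a 2 000-generation burn-in, 20 seeds.  Consensus
  calling uses ROD + Tajima's D + FST at the 10-kb/1-kb grid; mu uses
  200-SNP windows; CLR a 100-diploid subpanel.  Desk-scale sweeps with
  `s = 0.05` take ~200 generations to fix, so recombination erodes the
  swept haplotype during the sweep itself; the scenario's recombination
  rate (1.1e-7) was set so the expected hitchhiking footprint (tens of kb
  per flank) matches the ±50-kb localization question being asked.
* *Association calibration*: four demes of 50 (island migration 0.02) for
  the permuted-phenotype null (averaged over 10 permutations of ~1 000
  MAF-filtered markers) and the LFMM null; a single panmictic deme of 200
  for the power test, because in a strongly structured panel a
  structure-aligned causal variant is *correctly* absorbed by the kinship
  term — power against structure-confounded effects is exactly what a
  mixed model trades away.  Ties with perfect-LD proxies of the causal
  SNP count as successes: no statistic can order identical genotype
  columns.
* *iHS standardization*: ~2 700 cores from the neutral scenario; per-bin
  means within 0.05 of 0 and SDs within 0.05 of 1.

## Known limitations

The CLR scan models an instantaneous hard sweep; on slow (`2Ns` ~ tens)
sweeps its best-fitting `alpha` describes the eroded core rather than the
full original footprint, and its localization is noisier than the mu
statistic's.  The simulator's single-crossover-per-gamete recombination
caps the per-generation map length at one Morgan regardless of
`rec_rate`.  Tajima's D windows use a single called-allele number (the
mode), an approximation under heavy missingness.  The AMMI F tests use
Gollob degrees of freedom, which are anti-conservative for late IPCA
terms; treat them as descriptive.  `mu_scan` normalizations are this
package's own calibration of the three-signal composite and are not
numerically interchangeable with external implementations.
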