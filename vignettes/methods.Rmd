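---
title: "Models and methods behind soilNweb"
author: "soilNweb maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind soilNweb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

soilNweb implements the computational chain of a cotton-field study of
green-manure incorporation combined with reduced nitrogen fertilization:
chamber gas fluxes and their seasonal integration, bacterial community
diversity, null-model community-assembly partitioning, co-occurrence
network topology with keystone detection, and soil-property driver
statistics. This vignette explains the models, the tunable parameters, the
synthetic-data generators used for validation, and the numerical choices a
maintainer would want to know about.

## The study design

The emulated experiment is a split-plot factorial: three green-manure
patterns (NG none, OVG *Orychophragmus violaceus*, VVG *Vicia villosa*) as
main plots, four nitrogen levels (N3 the conventional 225 kg N ha^-1; N2,
N1, N0 at 75, 50 and 0% of it) as subplots, three replicates — 36 plots.
Nine soil properties (pH, NH4+-N, NO3--N, MBN, MBC, SOC, TN, AP, AK) are
measured per plot; the package ships the study's published treatment means
and standard deviations as a plain-text grid (`soil_field_means()`), which
is both the anchor of the soil simulator and the deterministic input of the
factorial effect statistics.

## Gas fluxes and cumulative emissions

NH3 volatilization uses the ventilation-chamber (sponge) method: one
extract concentration `C` (mg/L) per deployment gives the daily flux
`F = C V / (A D) x 10^-2` in kg NH4+-N hm^-2 d^-1, with extract volume `V`
(L), chamber cross-section `A` (m^2) and sponge coverage `D` (days). N2O
uses closed static chambers: concentrations at 15/30/45/60 minutes after
sealing; the flux is `rho (P/P0) (V/A) 273/(273+T) dc/dt` with the OLS
slope `dc/dt` per hour, `rho = 1.964` kg m^-3 (44 g/mol over 22.414 L/mol),
and the chamber temperature `T` in deg C. The slope regression R^2 is kept
with each record; closures with R^2 below 0.90 (a common chamber QC level)
are flagged but not dropped unless strict mode is requested.

Cumulative seasonal emissions are trapezoidal integrals over sampling
dates. For N2O the printed prefactor combines 1/2 (trapezoid), 24 (hourly
to daily) and 10^-5 (microgram m^-2 to kg hm^-2). Whether the published
hourly flux is on the gas-mass or N-mass basis is genuinely ambiguous, so
the integrator exposes `n_basis`: the default `"N"` applies the 28/44
N2O-to-N conversion, `"gas"` disables it. All worked examples in the test
suite state their basis explicitly.

## Synthetic data: what it emulates and what it does not

Every downstream stage is validated on generated data with known ground
truth; nothing is downloaded. The generators emulate:

- **Gas series.** NH3 flux decays exponentially after each of two
  fertilization events (sampling days 1-7, 10, 13, 20, 27, 34 after each),
  with amplitude scaled by the N rate (plus a small zero-N baseline, since
  unfertilized soil still emits) and a green-manure multiplier (defaults:
  OVG 0.6, VVG 1.1, matching the field direction that the high-C:N manure
  suppresses emissions). N2O follows a seedling-stage-peaked seasonal curve
  (peak near day 30, width 18 days) across 22 closures. Measurement noise
  is additive Gaussian with standard deviation proportional to each
  reading's signal (constant relative error, truncated at zero) — the
  realistic metrology for colorimetric and GC readings, and the regime in
  which the integrator recovers the stored noise-free cumulative emission
  within 2% on treatment means of three replicates at 5% noise.
- **Neutral communities.** A log-series source pool (Fisher's alpha and
  pool size set `x = J/(J + alpha)`) and per-plot local communities built
  by sequential replacement sampling: each of the `depth` individuals is,
  with probability `m`, a migrant drawn from the pool, otherwise a copy of
  a uniformly chosen earlier resident. At `m = 1` this is exactly i.i.d.
  multinomial pool sampling. The Sloan neutral-model fit recovers `m = 0.3`
  within +-0.1 (median over 20 panels of 36 samples at depth 5000).
- **Selection-structured communities.** Each ASV has a niche optimum on a
  one-dimensional gradient in [0, 1]; expected abundance is the pool
  abundance weighted by a Gaussian kernel with precision
  `gradient_strength` (0 = neutral limit). Optional Dirichlet `drift`
  overdispersion adds sample-level dominance shifts without changing
  expected abundances.
- **Phylogenies.** Pure-birth (Yule) trees over the ASV pool with niche
  optima evolved by Brownian motion, min-max rescaled to [0, 1]. The
  `clade_BM` trait model places the Brownian increments on internal
  branches only, so optima are conserved within terminal clades — the
  maximal-phylogenetic-signal end member.
- **Soil tables.** Replicates as treatment mean + Gaussian error, anchored
  on the published grid; `sd_scale = 0` gives the deterministic grid
  itself.

What the generators do **not** emulate: sequencing error and chimeras,
compositional coupling between gas fluxes and the community tables, soil
property/community covariance, weather, or between-year variation. Passing
tests therefore demonstrate that the estimators are correct and calibrated
under their own assumptions — not that field conclusions are recoverable
from sequence data.

## Community assembly inference

**Sloan neutral model.** For each ASV the observed occurrence frequency is
compared to `1 - pbeta(d; N m p, N m (1 - p))` at detection limit
`d = 1/N`, `N` the mean sample depth. `m` is estimated by bounded
least squares on frequencies; the 95% envelope is a Wilson binomial
interval at the sample count, and ASVs are classed above/within/below it.

**betaNTI.** Abundance-weighted beta mean nearest-taxon distance per
sample pair, standardized against 999 (default; 99 in the scaled test
panels) tip-label shuffles of the regional tree. The standard sign
convention applies: above +2 heterogeneous (variable) selection, below -2
homogeneous selection. Two numerical details matter. First, taxa shared by
both samples contribute zero nearest-taxon distance under *every* tip
permutation, so a pair of nearly identical communities has an almost
constant null; such pairs are flagged `NA` (a self-pair is the extreme
case) rather than given a meaningless z-score, and a fully degenerate null
(e.g. a star tree with all equal distances) is an error. Second, the
degeneracy cut is scale-aware (relative to the null mean) because a
constant null differs from zero only by floating-point noise.

**RC_bray.** Null communities preserve each sample's richness and total
abundance; taxa enter with probability proportional to occurrence
frequency and individuals fill multinomially by regional relative
abundance. `RC = 2[P(null < obs) + P(null = obs)/2] - 1`, with the
half-weight tie rule keeping RC centred at the null median. The
implementation is Monte-Carlo; an exhaustive-enumeration oracle on tiny
toys pins it down in the tests.

**Process classification.** betaNTI > 2 heterogeneous selection; < -2
homogeneous selection; otherwise RC_bray > 0.95 dispersal limitation,
< -0.95 homogenizing dispersal, else undominated. Fractions always sum to
100% over classifiable pairs.

**Niche breadth.** Levins `B = 1 / sum P^2` per taxon (the effective
number of occupied samples). Published community-level values exceed any
sample count, implying an aggregate over taxa whose exact form is not
stated; both conventions (abundance-weighted mean and sum over taxa) are
reported rather than resolving the ambiguity.

### Why the directional-assembly panels look the way they do

The selection regimes used to validate the classifier are deliberately
constructed so that the betaNTI machinery *can* see them, and their design
is the one place where naive choices fail silently. With plain tip-level
Brownian optima and no drift, strong filtering under one environment
drives every sample to nearly the same members; shared taxa contribute
zero to observed and null betaMNTD alike, and the z-score degenerates
toward zero. The panels therefore use: a 400-taxon near-even pool
(Fisher's alpha 10^4) at depth 200 (samples are sparse subsets, high
turnover), clade-conserved optima (`clade_BM`, so the filter selects whole
clades), kernel precision 120, within-group environment jitter comparable
to the kernel width (sd 0.08), and Dirichlet drift (concentration 50).
Heterogeneous panels put the two groups at gradient positions 0.1 and 0.9;
homogeneous panels put all samples at 0.1 (a trait-tail clade — mid-trait
values are reachable by many unrelated clades and give no clade-level
filter). Under these conditions the modal classified process matches the
planted regime in at least 8 of 10 seeds (heterogeneous: 10 of 10), with
the +-2 and +-0.95 thresholds untouched. Field-scale fractions (e.g. the
published 44-83% homogeneous selection band) are *not* reproduction
targets; they depend on the real data.

## Co-occurrence networks

Construction: prevalence filter (default 1/3 of samples), Spearman
correlations on relative abundances, edges kept at |rho| >= 0.6 with
Benjamini-Hochberg FDR < 0.05 (p-values from the t approximation to the
Spearman statistic), isolated nodes dropped, modules by seeded greedy
modularity maximization. The source study names none of these thresholds,
so all are exposed and logged; its published topology panel is treated as
a non-reproducible field result. The topology panel defines every metric
on fragmented graphs: average path distance over connected pairs only,
geodesic efficiency with zero contribution from disconnected pairs,
Krackhardt connectedness as the fraction of reachable pairs. Zi-Pi roles
use the quoted thresholds (2.5 and 0.62 — 0.62 verbatim even though 0.625
is the more common literature value): within-module degree z-score (zero
for singleton or zero-variance modules) and among-module connectivity
`1 - sum (k_it/k_i)^2` (zero for isolated nodes).

## Driver statistics

Factorial effects are computed on cell means first, then marginalized, so
unbalanced replication cannot tilt the marginals; the nitrogen-reduction
headline is the mean of the reduced levels' percentage changes versus N3
computed on green-manure-marginal means — the only reading that reproduces
the published percentages from the published grid. ANOVA comes in two
error structures: a simple fixed-effects two-way table, and a split-plot
mode in which the main-plot factor is tested against the pattern x
replicate stratum. LSD letters use pooled within-group variance at alpha =
0.05, assigned by descending mean with an insert-and-absorb algorithm;
exact ties (zero variance) fall back to mean equality. Random-forest
importance is permutation %IncMSE with significance from refits on
permuted responses. PLS path modeling uses mode A outer estimation with
the centroid inner scheme, standardized indicators, convergence tolerance
1e-6 on normalized outer weights (cap 300 iterations, non-convergence is
an error), OLS inner paths, GoF = sqrt(mean communality x mean inner R^2)
with the > 0.60 acceptability rule, and a seeded bootstrap for path
significance. One caveat stated plainly: on pure-noise multi-indicator
blocks, mode A weights capitalize on chance (they converge toward the top
singular pair of the noise cross-covariance), so orthogonal blocks yield
|path| around 0.14 at two indicators and n = 200; with single-indicator
blocks the path collapses to a plain Pearson r and is unbiased.

## Problem sizes and determinism

All stochastic stages take explicit seeds, and each simulated artifact
draws from its own stream derived from the master seed, so adding an
output never perturbs existing ones; a fixed configuration yields
byte-identical tables, trees, series and pipeline manifests. The validation
suite runs at deliberately scaled-down sizes chosen to exercise the
estimators' operating regimes: 36-sample, 60-taxon panels at depth 5000
for neutral-model recovery; 12-sample, 400-taxon panels with 99 null
draws for the directional assembly checks; graphs of at most 30 nodes for
the brute-force network oracles. These sizes are the package's validation
design, not statements about field data.

## Known limitations

- The gas and community generators are statistically independent, so
  cross-domain analyses (correlations, random forest, PLS-PM) are
  validated on separately constructed latent-variable data, not on the
  full synthetic bundle.
- The betaNTI null flags fully-overlapping sample pairs as NA rather than
  inventing a z-score; analyses of near-duplicate communities should use
  RC_bray, which remains informative there.
- Chao1 uses the classic form (bias-corrected only when doubletons are
  absent); estimates differ from implementations that always
  bias-correct.
- The NMDS stress surface is multimodal; the reported stress is the best
  of 20 seeded restarts (plus a metric start), which is a heuristic, not
  a global optimum.
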