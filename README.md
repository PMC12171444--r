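# soilNweb

Gaseous nitrogen emissions and soil bacterial community ecology for
green-manure field trials.

Intensive cotton cultivation loses fertilizer nitrogen as ammonia (NH3)
volatilization and nitrous oxide (N2O) emission. Field trials that combine
green-manure incorporation (none / *Orychophragmus violaceus* /
*Vicia villosa*) with reduced N fertilization (0–100% of the conventional
225 kg N ha⁻¹) generate three intertwined data streams: chamber gas
measurements, soil physicochemical properties, and 16S amplicon (ASV)
community tables. soilNweb is the analysis pipeline for such trials,
aimed at soil scientists and microbial ecologists who want every
computational step — from raw chamber readings to path models — reusable,
seeded, and tested against oracles.

## What it computes

**Gas fluxes and seasonal emissions.** Ventilation-chamber NH3 flux
`F = C·V/(A·D)·10⁻²` (kg NH4⁺-N hm⁻² d⁻¹) and static-chamber N2O flux
`F = ρ·(P/P₀)·(V/A)·273/(273+T)·Δc/Δt` with slope-regression QC, then
trapezoidal cumulative emissions `CF = ½·Σ(Fᵢ+Fᵢ₋₁)(Tᵢ−Tᵢ₋₁)` (×24×10⁻⁵
and optionally ×28/44 for N2O), and treatment-level percentage effects.

**Community ecology.** Shannon/Chao1/ACE alpha diversity, Bray–Curtis
distances with NMDS (Kruskal stress-1, multi-restart) and PERMANOVA,
ternary enrichment of top ASVs across the three manure patterns.

**Assembly processes.** The Sloan neutral community model (occurrence
frequency vs mean relative abundance; migration rate `m` by bounded least
squares), abundance-weighted βMNTD/βNTI against a tip-shuffling null,
Raup–Crick on Bray–Curtis (RC_bray), the five-way classification
(heterogeneous/homogeneous selection, dispersal limitation, homogenizing
dispersal, undominated; |βNTI| = 2 and |RC| = 0.95 thresholds), and Levins
niche breadth `B = 1/Σp²`.

**Co-occurrence networks.** Spearman edges with BH-FDR control, module
detection, a topology panel defined on fragmented graphs (clustering,
path distance, modularity, geodesic efficiency, Krackhardt
connectedness), Zi–Pi node roles (hubs at Zi > 2.5, connectors at
Pi > 0.62) and keystone reports.

**Drivers.** Factorial percentage effects on the published soil grid,
one-way/split-plot ANOVA with LSD letters and Levene tests, correlation
matrices with significance stars, permutation random-forest importance,
and PLS path modeling (mode A / centroid, GoF with the 0.60 acceptability
rule, bootstrap path significance).

**Synthetic data.** Every stage has a generator with stored ground truth
(neutral and selection-structured communities on simulated phylogenies,
gas series with known cumulative emissions, soil tables anchored on the
published treatment means), so the whole pipeline is testable offline.

## Worked example

```r
library(soilNweb)

# the published 12-treatment soil grid ships with the package
grid <- soil_field_means()
eff <- factorial_effects(grid, "MBC", "pattern", reference = "NG")
eff$levels
#>   level   mean pct_change
#> 1    NG  65.70    0.00000
#> 2   OVG 117.75   79.22374
#> 3   VVG 118.50   80.36530

# a neutral community panel and its Sloan-model fit
cfg <- synth_config(seed = 42, n_asvs = 60, depth = 5000,
                    migration_m = 0.3)
fit <- fit_ncm(simulate_neutral_community(cfg))
fit
#> Sloan neutral community model: m = 0.2835, R2 = 0.973, N = 5000
#>  above within  below
#>      6     51      3
```

The first block says OVG incorporation raised microbial biomass carbon by
79.2% over the no-manure control (marginal means over the four N levels);
the second shows the neutral-model fit recovering a migration rate near
the generator's true `m = 0.3` with a high fit R², and classifying each
ASV against the 95% neutral envelope.

An end-to-end run on synthetic inputs, with a checksum manifest:

```r
res <- run_pipeline(pipeline_config(seed = 1))
res$assembly$partition    # process fractions summing to 100%
res$network$topology      # the co-occurrence topology panel
```

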