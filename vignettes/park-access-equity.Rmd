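---
title: "Methods: supply-demand adjusted park accessibility and equity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supply-demand adjusted park accessibility and equity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenreach)
```

## The problem and the model

Plain catchment counts and nearest-park distances ignore two things that
shape real park use: parks differ in how attractive they are, and several
populations compete for the same park. The pipeline in this package
addresses both with a two-step floating catchment area (2SFCA) estimator
augmented by a Huff choice model.

The chain, per travel mode, is:

1. **Travel times.** Cell centroids and park entrances are snapped to
   their nearest road-network node and Dijkstra shortest paths give
   t_ij in minutes at the mode speed; a park's time is the minimum over
   its entrances (people enter at gates, not centroids). Unreachable
   pairs (disconnected components) are excluded everywhere downstream.
2. **Attractiveness.** S_j combines park area, the mean street green-view
   index in the park's network service area, and the Shannon diversity of
   surrounding service-function POIs. Components are divided by their
   maximum over parks before weighting, so S_j ∈ [0, 1] and area units
   cancel.
3. **Choice.** Prob_ij ∝ S_j G(t_ij, t₀) over the parks reachable within
   the threshold; rows normalise to 1.
4. **Step one.** R_j = S_j / Σ_i Prob_ij P_i G(t_ij, t₀) — supply divided
   by decay- and choice-weighted demand.
5. **Step two.** A_i = Σ_j Prob_ij R_j G(t_ij, t₀).
6. **Equity.** Equality index E_i = a_i·max(R_j)/max(a_i) with a six-class
   scheme; LISA clusters of E_i; Lorenz/Gini of per-capita access; zonal
   min/max/mean/SD/underserved tables.

A useful internal check falls out of the algebra: Σ_i P_i A_i equals the
summed effective supply of all parks with positive weighted demand. The
package verifies this identity (`conservation_error()`) to floating-point
precision on every fit, which guards against silent index-alignment and
filtering bugs.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| mode speeds | 5 / 15 / 40 | km/h | walking / cycling / driving averages |
| thresholds t₀ | 30 / 25 / 30 | min | psychological limits; derivable from survey bins via `threshold_from_survey()` (bin midpoint × share, max over park categories, half-up rounding; the open top bin is fixed at a 60-minute midpoint) |
| service radius | 300 or 500 | m | 500 m for comprehensive parks and special parks above 5000 m²; 300 m otherwise |
| attractiveness weights γ | ⅓, ⅓, ⅓ | — | must sum to 1 |
| grid cell | 100 | m | fine enough for block-level planning diagnostics |
| off-road dilation | 20 | m | POIs and green-view points sit beside, not on, the street line |
| Huff variant | `gaussian` | — | see below |
| supply scale | `dimensionless` | — | `"area"` gives R_j in m²/person |
| LISA | queen, 999 perms, α = 0.05 | — | fully seedable |

## Decisions taken where the design was open

**Huff weight variant.** The weight could be read as S_j·G, S_j·t_ij·G or
S_j/t_ij·G. The default is S_j·G: multiplying by raw travel time would
reward *farther* parks, which contradicts the decay's purpose, and the
Gaussian kernel already encodes impedance. The literal
(`gaussian_times_time`) and inverse (`gaussian_over_time`) forms remain
selectable for sensitivity analysis; the supply-conservation identity
holds for all three.

**Decay endpoints.** G is defined piecewise with the second branch taken
at t > t₀, the only reading under which the pieces partition the domain;
G is then continuous at the threshold (both sides → 0).

**Gini formula.** The rectangle form 1 − Σ ΔP·ΔQ evaluates to 1 − 1/n on a
perfectly uniform allocation, so it cannot serve as an inequality measure
anchored at zero. The standard trapezoid form
G = 1 − Σ (P_k − P_{k−1})(Q_k + Q_{k−1}) is used; the rectangle value is
available behind `lorenz_gini(..., literal = TRUE)` as a debug attribute.
Units are sorted ascending by resource per capita, which keeps the Lorenz
curve convex and below the diagonal. The default resource is P_i·A_i
(population-weighted access), pairing cumulative population share with
cumulative park-resource share; raw A_i is selectable.

**Local Moran.** The standard Anselin decomposition
I_i = (x_i − x̄)/m₂ · Σ_j w_ij (x_j − x̄) with m₂ = Σ(x_k − x̄)²/n is used
(a transcription that repeats the focal deviation in the lag term would
make I_i a scaled square, never negative, and could not produce HL/LH
categories). Inference is by conditional permutation: x_i is held fixed
and its k neighbour values are drawn from the other n − 1 observations.
Draws are with replacement — for k ≤ 8 neighbours out of thousands of
candidates the difference from without-replacement sampling is
negligible, and it vectorises cleanly. The p-value is one-sided in the
direction of the observed statistic, (count + 1)/(nsim + 1); labels
require p ≤ α and are set by the quadrant of (value, lag) around the
mean. The weight scheme (queen default), permutation count and α are
explicit arguments because no single convention dominates practice.

**Classification boundaries.** The six equality classes follow the printed
inequalities exactly (0.25 belongs to class III, 1.0 to class V); class VI
("oversupply") is labelled a form of inequality by convention, however
counterintuitive, and is kept as printed. Gini bands assign boundary
values to the lower band. The special-park area tie at exactly 5000 m²
resolves upward to 500 m (`tie_up = FALSE` to flip).

**Supply scale.** S_j is dimensionless in [0, 1] by default, which makes
R_j a per-person share. With realistic urban populations max(R_j) is then
far below 0.25, so the six-class equality scheme — whose thresholds are
absolute — degenerates into classes I/II only. Zonal reporting practice
prints ratios in m²/person, and on that scale the classes spread; the
`supply_scale = "area"` switch (S_j × park area) therefore exists and is
what the scenario-recovery analyses use. This is a units decision, not a
model change: Prob, the Lorenz/Gini and LISA are all invariant to it.

**Geometry conventions.** One planar metric frame; 0-based row-major cell
ids; partial edge cells are kept with their true area but population
redistribution uses residential-POI counts only; zone membership is by
centroid. Snapping is to the nearest node (not nearest edge point) with
the snap distance charged at mode speed — at a 100 m grid and 100 m
network spacing the snap error is bounded by ~71 m, small against
kilometre-scale catchments. Service-area membership, by contrast, does
use exact edge-interior coverage (per-edge covered sub-segments plus the
20 m off-road dilation), because 300 m radii are comparable to edge
lengths.

## What the synthetic generator emulates — and what it does not

`make_scenario()` builds cities with the structure the estimator assumes:
concentric ring zones, population intensity decaying log-normally from
the centre and redistributed onto cells proportionally to residential
POIs (conserving zone totals exactly via largest-remainder rounding),
parks in four categories with field-realistic size ranges and 1–4
entrances on the network, a 100 m lattice street network with diagonal
shortcuts and an optional river crossed by five bridges, POIs clustered
around parks and ring roads, and a smooth harmonic green-view field in
[0, 1], elevated along greenway edges.

Defaults: 50 × 50 cells (5 × 5 km), 125,000 residents (5,000/km², a
mid-density urban core), 20 parks (2 comprehensive, 3 special, 7
community, 8 street), ~2,600 nodes and ~5,200 edges, 1,500 service POIs,
3,000 residential POIs, green-view samples at every edge midpoint. These
sizes run the full three-mode pipeline in well under a minute while
leaving enough spatial texture for cluster and equity statistics to be
meaningful.

What it does *not* emulate: real street topologies (one-way systems,
grade separation, mode-restricted links), transit, land-use correlation
between POI categories, park shapes (parks are square), or empirically
calibrated population and green-view magnitudes. Passing tests on these
cities therefore demonstrate the *mechanics* of the estimator —
normalisation, conservation, monotonicity, cluster recovery, the
qualitative walking-vs-driving equity ordering — not calibrated estimates
for any real city.

Named scenarios encode qualitative expectations used in testing:
`park_desert_quadrant` keeps one quadrant park-free (low-access classes
should concentrate there under walking); `uniform_everything` is the
symmetric analytic limit (identical parks on a regular layout, uniform
population) in which accessibility is near-constant and the Gini is close
to zero; `riverside_greenway` severs the lattice along a river except at
bridges.

## Numerical choices and degenerate inputs

- Huff rows with no reachable park are all-zero (not NaN); rows whose
  reachable parks all have zero attractiveness are zeroed with a warning.
- R_j = 0 when a park attracts no weighted demand, which is what makes
  the conservation identity exact rather than approximate.
- A component maximum of 0 in the attractiveness normalisation
  contributes 0 for every park (0/0 guard).
- `gaussian_over_time` floors travel time at 0.1 min to avoid division
  blow-ups at co-located origin/entrance pairs.
- Shannon diversity of an empty service area is 0; a park with no
  green-view samples in range scores 0 with a warning.
- Constant fields raise an explicit zero-variance error in `local_moran`;
  an all-zero resource vector raises an explicit error in `lorenz_gini`.
- Zones with no populated cells produce NA summary rows with a warning
  rather than silently disappearing.

## Problem sizes used in the shipped checks

Unit and property tests run on hand-built toy fixtures (line and detour
networks, 3×3–10×10 grids) plus 12–15-cell-wide generated cities; the
end-to-end checks use the default 50 × 50 baseline, five seeds for the
stochastic scenario-recovery properties, 999 permutations for the LISA
oracle comparisons and 100 small random cities for Huff normalisation.
The whole suite completes in about a minute on one core.

## Known limitations

- Single planar frame; no CRS transforms — inputs must arrive projected.
- No transit or multimodal chains; driving ignores parking and access
  walking.
- Nearest-node snapping (not nearest edge point) for OD times.
- The Huff threshold is shared between the choice and catchment steps.
- "Underserved" is defined as exactly zero accessibility; cells barely
  above zero are not flagged.
- Permutation p-values are pseudo p-values; no multiple-testing
  correction is applied across cells, matching common LISA practice.
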