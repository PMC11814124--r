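---
title: "Methods: coupled ecological-economic simulation of protecting dive sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled ecological-economic simulation of protecting dive sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mpadive asks a policy question: if every pixel of ocean that currently hosts
recreational scuba diving were upgraded to a fully or highly protected marine
protected area (MPA), what would happen to fish biomass, to a global
biodiversity score, and to the dive-tourism economy — and how much of the
resulting willingness-to-pay gain could a per-dive user fee capture? This
vignette documents the model, its assumptions, the tunable parameters, and
the choices made where the design was genuinely open.

## The world

The spatial unit is a 50 km x 50 km pixel identified by a 0-based integer
id, carrying centroid coordinates, an area (2,500 km^2 nominal; exposed as
data rather than recomputed geodesically), ocean and diving flags, region
and country labels, and a five-level protection status:
`fully_highly > less_unknown > designated_unimplemented > proposed_committed
> unprotected`. All distances are great-circle (haversine on a 6,371 km
mean-radius sphere); there is no projection machinery because the dynamics
only consume centroid distances and areas.

A pixel is classified `fully_highly` when at least 50% of its area (the
threshold is an argument) lies in fully/highly protected MPAs. Below the
threshold the best remaining designation wins, with sub-threshold
fully/highly coverage counting as MPA membership at the `less_unknown`
tier — the classification rank never lets partial full protection outrank
the threshold rule. When one dive site carries several designations, the
highest status wins and ties go to the oldest designation year.

Dive prices can be allocated to ocean pixels under three schemes: one
global median (the reference case), per-country medians with a global
fallback for countries lacking observations (the data are silent on the
fallback; the global median is the least informative choice), and
inverse-distance interpolation of per-pixel medians.

## Synthetic worlds

Real inputs for this analysis (protected-area boundaries, logged dives,
operator prices, stock assessments, species ranges) are large external
databases. The generators in `generate_world()`, `generate_stocks()` and
`generate_species()` emulate their statistical structure so the entire
pipeline is testable from a single seed:

* **Geography.** A land mass with a sinusoidal coastline occupies
  `1 - ocean_fraction` of the grid; dive pixels (1.2% of ocean pixels by
  default, matching the observed global prevalence of diving) are sampled
  with weights decaying away from the coast and boosted near cluster
  seeds, reproducing the coast-hugging, clustered geography of dive sites.
* **Protection.** Exact counts of dive pixels receive fully/highly
  coverage (target 15.48% of dive sites) and lesser designations (67.35%
  in any MPA), the two observed global shares; a lower background density
  of MPAs covers non-dive ocean.
* **Dive effort.** Annual dives default to 33.1 million scaled by the
  world's dive-pixel count relative to the ~1,816 dive pixels a global
  50 km grid implies; the allocation across pixels is lognormal
  (`sdlog = 1.5`, a heavy tail: the within-world distribution is not
  observed, so we chose a shape that makes a few sites dominate, as real
  logbooks do) and is rounded to integers by largest remainder so the
  total is exact.
* **Prices.** Operator price observations are lognormal around the
  US$58.75 median with `sdlog = 0.25` (prices per dive are empirically
  near-constant across regions); sampling is stratified on the quantile
  scale so the sample median honours the configured median even at
  moderate n.
* **Stocks.** Each stock has life-history features (growth rate r,
  carrying capacity K, length, trophic level, an ordered movement keyword,
  range size), a contiguous 4-connected range blob seeded at a dive pixel,
  and a business-as-usual depletion drawn Uniform(0.1, 0.9) — the
  stand-in for externally estimated current biomass, config-exposed.
  Ground-truth home range and pelagic larval duration (PLD) are log-linear
  in the features plus lognormal noise, so trait imputation has a
  recoverable truth. A configurable fraction of stocks is flagged
  "empirical" (their traits may train the imputation models); elasmobranch
  stocks carry no PLD.
* **Species.** Biodiversity-scored species are allotted to taxa by
  largest-remainder rounding of the taxon aggregate weight table, so
  realized aggregates match the table; ranges are contiguous blobs biased
  toward dive pixels, and each species carries an abatable-impact fraction
  Uniform(0.2, 0.9).

One master seed drives everything; per-generator streams use fixed offsets
(world +0, stocks +1000, species +2000, Monte-Carlo draws +3000), so
adding stocks does not perturb the world.

What the generators do **not** emulate: realistic coastlines and
bathymetry (dive suitability is a generated flag, not a depth model),
spatial covariance between prices and effort, anisotropic larval drift,
and country-level idiosyncrasies. Passing tests on synthetic worlds
therefore demonstrate the correctness and internal consistency of the
machinery, not calibration to any real coastline.

## Dispersal traits

Home range (km^2) is treated as the area of a circle, giving the adult
movement radius `zeta = sqrt(homerange / pi)` km. Larvae disperse by an
isotropic Gaussian kernel whose spread follows the empirical relationship
`sigma = 1.33 * sqrt(pi/2) * PLD^1.3` (km, PLD in days); drift is
neglected.

Both traits are imputed, where unobserved, by a random-forest regression
of the log trait on the six life-history features (500 trees; all
features tried at each split and a minimum node size of 3, which measurably
improves held-out accuracy on this small, strongly informative feature
set; fixed seed). Empirical values take priority when available, and
species with multiple empirical observations are aggregated by geometric
mean before training. Elasmobranchs have no pelagic larval stage: their
PLD is removed and — a choice the source material leaves open — their
larvae settle in the natal pixel only (identity larval row). Stocks whose
traits can be neither observed nor predicted are dropped with a warning.

Discretisation choices for the matrices:

* **Adult movement** redistributes biomass uniformly over the range
  pixels whose centroids lie within `zeta` of the source (always
  including the source), making every row sum to exactly 1. Uniformity is
  our choice — only the radius constraint is given; a distance-weighted
  alternative would slot into the same constructor.
* **Larval settlement** evaluates the kernel at centroid distance times
  the destination pixel area, restricted to the range, then renormalises
  each source row to 1 (default). At 50 km resolution the raw
  discretisation misbehaves for small sigma — the d = 0 cell alone can
  exceed 1 (e.g. 2500/(2 pi 100) ≈ 3.98 at sigma = 10 km) — so
  renormalisation is the default and the raw behaviour remains available
  (`renormalize = FALSE`), under which rows may sum below 1 (larvae lost
  offshore).

## Biomass dynamics

Stock biomass follows a synchronous logistic metapopulation update on the
stock's range. For a protected pixel i:

B_i(t+1) = s_ii B_i(t) + sum_{j != i} s_ji B_j(t)
         + [rho_ii + sum_{j != i} rho_ji] r B_i(t) (1 - B_i(t) / K_i)

The carrying capacity K is spread homogeneously over the range
(K_i = K / |range|). Fished pixels are reset to their business-as-usual
density every step: fishers are assumed to capture all adult spillover
and larval subsidy, so biomass only accrues inside MPAs — this also
pins fished densities bit-identically through equilibration, which the
tests assert.

Note the recruitment term: immigrant larval settlement weights
*local* production at the destination pixel (the settlement weights
multiply `r B_i (1 - B_i/K_i)`, not production at the source). We
implement the update exactly in this printed form rather than
"correcting" the asymmetry; with row-renormalised kernels the incoming
settlement weights sum near 1 and the term behaves as a recruitment
multiplier on local production.

Equilibria use a fixed 100 iterations (matching the source procedure) so
equal-length runs are bit-reproducible; an optional tolerance-based early
stop exists but is off by default. The business-as-usual state starts all
pixels at `depletion x K` and equilibrates under the existing MPA network;
the protect-all state re-equilibrates from there with every dive pixel
closed. The percent change per dive pixel aggregates per-stock changes
weighted by each stock's total carrying capacity.

## Biodiversity score

The score is a weighted sum over species of a persistence term,
`sum_s w_s (1 - q_s (1 - p_s) - u_s)^z`, where `p_s` is the fraction of
the species' range in fully/highly protected pixels (only full/high
protection counts, consistent with the benefits being unique to that
tier), `q_s` the abatable-impact fraction, `u_s` an optional unabatable
share (default 0), and `z = 0.25` a concavity exponent. A score of 1
means every species is free of threats. **This functional form is a
reconstruction**: the source defines the score verbally (a weighted sum
of marginal persistence gains from removing abatable impacts) and defers
the formula to earlier work we cannot reproduce here; the power form is
concave and monotone in protection, satisfies the stated endpoints
(full protection with fully abatable impact gives persistence 1), and
both `z` and the persistence function are config-exposed so an alternative
can be plugged in. Species weights divide printed taxon aggregate weights
(Elasmobranchii 34.0%, Actinopterygii 27.3%, Anthozoa 16.5%, birds 5.2%,
mammals 5.0%, Malacostraca 3.8%, cephalopods 2.1%, other 6.1%) uniformly
within each taxon.

## Economics

Each dive pixel is a linear demand market observed in equilibrium:
`Q(P) = a - b P` with `b = Q*/(C - P*)` and `a = Q* + b P*`, where the
choke price C is the 99th percentile (nearest rank) of observed prices.
The slope is forced by the choke-price construction; the source never
writes b explicitly. Supply is horizontal (prices near-constant in the
data), so producer surplus is identically zero and is asserted, not
modelled.

Protection shifts willingness to pay (WTP) per dive by
`P* [0.04 x 1(MPA) + f_bio(dB) + f_div(dS)]`: a 4% MPA "name effect" plus
saturating responses to the relative biomass change (cap 0.84) and the
biodiversity-score gain (cap 0.82). The response shape is Michaelis-Menten
`cap * x / (k + x)`; the half-saturation constants are a reconstruction of
an unavailable supplementary parameterisation and were fixed once:
`k_bio = 1.0` (half the biomass cap at a +100% biomass change, the scale
of change the analysis itself produces) and `k_div = 0.05` (half the
biodiversity cap at a 0.05 score gain, the scale of the observed global
gain). Both are config-exposed in `wtp_params()`.

With a fee F, the dive change is `dQ = Q*(WTP - F)/(C - P*)`; industry
revenue changes by `P* dQ`; fee revenue is `F (Q* + dQ)`; and the
consumer-surplus change is
`0.5 (Q* + dQ)^2 (C - P*)/Q* - 0.5 Q* (C - P*)`, which the tests verify
against an independent geometric triangle computation. Dives are clamped
at zero (with a warning) when a fee exceeds the choke margin. The
*neutral fee* F = WTP holds dives, industry revenue and consumer surplus
exactly at their pre-MPA values while collecting `WTP x Q*`.

The global dive extrapolation multiplies active divers by a casual/core
mix (4 and 10 dives per year). The casual share is not printed in the
source; the default 0.728 solves the printed mix (9 million divers making
50.7 million dives) and is config-exposed.

Only pixels whose status actually upgrades receive the WTP shift —
pre-existing fully/highly pixels are already in the baseline. Fees apply
to all dive pixels in both branches, which is what makes the no-MPA
branch a pure price increase. The economic gain is attributed to the
three WTP components linearly through the demand shift, weighting each
pixel by its demand slope. The biodiversity input to WTP is the global
score gain applied uniformly to upgraded pixels: the score is global by
construction and the source does not describe a per-pixel attribution;
a per-pixel decomposition would change only the spatial pattern, not the
totals, of the biodiversity component.

## Scenario engine

`run_scenario()` composes the stages; `fee_sweep()` evaluates both policy
branches on a fee grid (default US$1 steps to twice the median choke
margin, covering the full revenue dome) with the biology equilibrated
once; `neutral_fee()` verifies the fixed point; `monte_carlo()` draws
dive totals uniformly between bounds (default 17.1/33.1 and 54.0/33.1
times the baseline, the global lower/upper bounds relative to the central
estimate) and rescales pixel dive counts proportionally — reallocation
under uncertainty is unspecified in the source, and proportional scaling
preserves the spatial pattern; `sensitivity_suite()` crosses dive-total,
price-scheme and biodiversity-weight axes, sharing the biomass equilibria
across rows since none of those axes touches the biology.

## Problem sizes and numerical notes

The package's own reference configuration is a 40 x 40 grid (880 ocean
pixels), 50 stocks and 200 species, which the full pipeline traverses in
a few seconds; tests use 16-30 pixel grids with 8-15 stocks, and the
trait-recovery checks use 200-600 stocks. Degenerate inputs are handled
explicitly: zero dive pixels give empty economics; `Q* = 0` pixels have
zero demand slope and zero surplus; equal observed prices make the choke
price equal the market price, which the demand constructor rejects;
`sigma = 0` and elasmobranch stocks settle natally; stocks without
resolvable traits are dropped with a warning, and fewer than 10 empirical
training stocks makes the bundle constructor fall back to treating all
generated traits as observed rather than fitting an under-determined
forest.

Known limitations: no age/size structure or species interactions, no
fishing-effort reallocation, no cross-site substitution in demand, no
tourism multiplier effects, and the biodiversity persistence form is a
documented reconstruction. Results on synthetic worlds are
internal-consistency demonstrations, not forecasts for real coastlines.

## A worked example

```{r, eval = FALSE}
library(mpadive)

bundle <- generate_world_bundle(
  world_gen_config(nrow = 40, ncol = 40, seed = 1),
  stock_gen_config(n_stocks = 50, seed = 1),
  n_species = 200
)

result <- run_scenario(bundle, policy = "protect_all", fee = 0)
glance(result)

nf <- neutral_fee(bundle)
nf$mean_fee_usd

fs <- fee_sweep(bundle)
autoplot(fs)
```
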