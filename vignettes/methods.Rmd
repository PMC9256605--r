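---
title: "Methods: community-scale potential climate impacts on fisheries and agriculture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community-scale potential climate impacts on fisheries and agriculture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Tropical coastal communities draw food and income from two climate-exposed
sectors at once: small-scale fisheries and small-scale agriculture. A
community-scale assessment of potential climate impact needs three
ingredients: how strongly each community *depends* on each sector
(sensitivity), how much each sector's productive base is *projected to
change* at that community's location (exposure), and a way to combine the
two. `coastimpact` implements that pipeline — household-survey sensitivity
indices, multi-model ensemble exposure extraction, a Euclidean
potential-impact score, and the comparative statistics used to summarize
them across communities and countries — together with a synthetic-data
generator so the whole chain is testable without any external data.

# Sensitivity from ranked occupation surveys

Each surveyed household lists every livelihood activity that brings in food
or income and ranks the activities by importance (rank 1 = most important).
Activities fall into ten categories; fishing, mariculture, gleaning and fish
trading form the *fisheries* sector, farming and cash cropping the
*agriculture* sector, and salaried, informal, tourism and other work the
*off* sector.

For a focal sector with engaged-household count $X$, counterpart count
$NX$, community size $N$, and ranking-direction counts $r_x$, $r_{nx}$, the
community's sensitivity is

$$S = \frac{X}{X + NX} \times \frac{N}{X + NX} \times
      \frac{r_x/2 + 1}{r_x + r_{nx} + 1}.$$

The first factor measures engagement, the second how exclusively engaged
households sit inside the focal sector (it is 1 when no household holds a
counterpart occupation), and the third whether, in households engaged on
both sides, the focal sector tends to hold the more important rank. When
every household lists at least one occupation, each factor lies in $[0,1]$,
so $S \in [0,1]$, and $S = 0$ exactly when no household engages the focal
sector. Three scores are produced per community: $S_A$ (agriculture), $S_F$
(fisheries), and $S_{AF}$ (the two natural-resource sectors jointly, with
the off sector as counterpart).

Three choices here were genuinely open and are worth recording:

* **"Relying on" a sector** means holding at least one occupation mapped to
  it; no minimum rank is required.
* **Ranking-direction counts are per household, not per occupation pair**:
  among households engaged on both sides, the best (lowest) rank on each
  side is compared and the winner's counter incremented once. Ranks are
  distinct within a household, so ties cannot occur. A per-pair variant is
  available via `sector_counts(per_pair = TRUE)`; it counts every ordered
  focal-counterpart pair and yields larger $r$ values but the same
  direction of effect.
* **The joint index's counterpart is the off sector only** — the joint
  focal set already absorbs both natural-resource sectors, so its linkage
  factor measures dependence relative to wage-type alternatives.

Households that list no occupations are dropped with a warning rather than
failing the community.

# Material style of life

Wealth is scored from 16 presence/absence material items per household. The
first principal axis of the *centered, unstandardized* (covariance-form)
binary item matrix is kept as the household score — the standard choice for
asset indices, where item prevalences carry information that correlation
scaling would discard. The axis sign is not identified by the
decomposition, so it is oriented to correlate positively with the
raw item count (wealthier = higher score). Community means of the household
scores are min-max rescaled to $[0,1]$ across the community set; the
rescaling is affine, hence order-preserving. Temporal trajectories for
repeatedly surveyed communities fit one pooled PCA across all waves and
project wave centroids into that common plane, so displacement between
waves is comparable across waves.

# Exposure from gridded ensembles

Exposure is the mid-century percent change in a sector's productive base,
relative to a historical reference:

* **Fisheries** (`E_F`): total consumer biomass on a 1° ocean grid, 16
  model runs (9 marine ecosystem models, 7 of them under two Earth-system
  forcings). For each site the 20 nearest ocean cells are selected by
  haversine distance (sphere radius 6371 km), with distance ties broken by
  (latitude, longitude) for determinism.
* **Agriculture** (`E_A`): rain-fed rice, maize and cassava yield on a 0.5°
  grid, 20 model runs (4 crop models × 5 forcings); cassava is simulated by
  a single crop model, so only 5 runs carry it. For each site, land cells
  within an 11×11 window centered on the containing cell are used (the
  window is clipped at grid edges; the containing cell is the one with the
  nearest center).

Per run, the field is averaged over the selected cells and over the years of
each window — historical 1983–2013 and future 2046–2056, both inclusive —
and the change is $100 \times (\bar{v}_{fut} - \bar{v}_{hist}) /
\bar{v}_{hist}$. Cells-and-years first, runs second: each run yields one
change value, and ensemble statistics are computed across runs. (Averaging
per-cell changes across runs first is a defensible alternative; with a
common cell set and a positive baseline the two orderings differ only
through baseline weighting, and the per-run-first form keeps run agreement
well defined.) The generator emits annual fields; a monthly source would be
annualized by unweighted month means at load time. Runs with a
non-positive historical baseline are flagged missing and drop out of both
the ensemble mean and the agreement denominator.

Ensemble statistics per site and sector: the arithmetic mean, the 25th and
75th percentiles (linear interpolation, the `quantile()` type-7 default —
the convention is not fixed by the method), and *model-run agreement*: the
fraction of available runs whose sign of change matches the sign of the
ensemble mean. Zero-change runs are counted as agreeing with either
direction; if the ensemble mean is exactly zero, agreement is the larger of
the non-positive and non-negative fractions.

Per-crop changes combine into `E_A` *per run*, keyed by run identity, so a
run that simulates only some crops (cassava's single model) still
contributes exactly once to agreement; the default crop average is
unweighted, with optional production weights renormalized over the crops a
run provides. The composite exposure is the sector average
$E_{AF} = (E_A + E_F)/2$. A cell-count sensitivity helper recomputes the
fisheries statistics for 1, 3, 5, 10, 20, 50, 100 nearest cells.

# Potential impact

Potential impact is the Euclidean distance from the origin in the
(sensitivity, exposure) plane. The two axes have incommensurate units (a
unitless index vs a percent change), so each is placed on $[0,1]$ first:
exposure is converted to a *loss* ($\max(0, -E)$, projected gains
contribute no harm) and both components are min-max scaled across the
community set being compared. The score is then
$\sqrt{s^2 + e^2} \in [0, \sqrt{2}]$, weakly monotone in each component.
Because the scaling is set-relative, single-community calls require
explicit bounds (`bounds = list(sensitivity = ..., loss = ...)`), which
also provide a raw-units variant (`scale = "none"` skips rescaling
entirely). A community bears a *double burden* when both sector exposures
are strictly negative.

# Comparative statistics

Communities cluster within countries, so every reported average is the
fixed intercept of a Gaussian random-intercept model
`value ~ 1 + (1 | country)` (REML, with Satterthwaite degrees of freedom
for the test of the intercept against zero — which is why the reported df
are fractional and close to the number of countries). Singular or failed
fits fall back to the mean of country means with a $k-1$ df t-test and a
warning. Sector comparisons keep the paired structure by modelling the
per-community difference `E_F - E_A` as the response. Cohen's D (pooled,
df-weighted SD) quantifies surveyed-vs-random-site differences, with the
random reference sites drawn without replacement from coastal population
cells above 25 people/km² (strict inequality), 10% of the eligible set,
reproducibly by seed.

The wealth-impact regression `impact ~ msl + (1 | country)` reports a
slope with a nonparametric bootstrap SE: communities are resampled with
replacement *within* country (stratified, 1000 replications by default), so
every resample retains all countries; the p-value is a normal approximation
on slope/SE. Marginal and conditional $R^2$ use the standard
variance-decomposition definitions for mixed models (fixed-effect variance
over total, and fixed-plus-random over total).

# The synthetic-data generator

The generator produces the full study under one master seed: a household
survey, site coordinates, gridded ensembles for each scenario, and a
population raster. Sub-seeds are derived from the master seed in a fixed
documented order (survey, sites, grids, population, spare), so adding a
generator does not shift the streams of existing ones, and every object is
byte-identical under a repeated seed.

Defaults are the study conditions: five countries contributing
25/6/10/25/6 communities (72 sites), 13–150 households per community,
16 fisheries runs and 20 crop runs (cassava from one model), historical
window 1983–2013, future window 2046–2056, and two scenarios — a harsher
one with true mean changes of −14.7% (fisheries) and +1.2% (agriculture),
matching the reported high-emissions ensemble means, and a milder one set
at −6% and +2.5%, since low-emissions sector means for these sites are not
reported and mitigation should shrink losses. Between-run SD is 5% and
cell-level spatial noise 8%; both are fractional changes. Households draw a
sector membership (agriculture only / fisheries only / both / neither) from
per-country probabilities with a Dirichlet-style community-level jitter
(concentration 60; `Inf` disables it); in dual households the best
fisheries rank beats the best agriculture rank with probability 0.6 —
coastal settlements tend to rank fishing first, but not uniformly. Item
flags follow a logistic model on a per-country latent wealth. The
population raster is generated at 0.05°, much finer than the climate grids,
mirroring km-scale gridded population products.

Construction of the grids: a positive log-normal base field per sector
(biomass on ocean cells, yield on land cells, one shared sinusoidal
coastline), historical years equal to the base (times optional 2%
interannual noise), and future years equal to the base times
$(1 + \Delta + \delta_r + \eta_c)$ with $\delta_r$ the run offset and
$\eta_c$ cell-level spatial noise. Spatial noise is i.i.d. per cell by
default; an optional smoothing radius introduces autocorrelation (the
smoothed field is rescaled so the configured SD keeps its meaning), because
nothing fixes the sub-grid structure of real projection fields. With all
noise SDs at zero, extracted exposure equals the configured change exactly,
which the tests exploit as an oracle.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: spatially autocorrelated, trended climate
fields (the default noise is white and the future is a level shift, not a
trajectory); correlated errors between runs sharing a forcing; seasonality
and monthly resolution; survey nonresponse and sampling weights;
within-household rank instability; and any coupling between wealth and
sector membership. The double-burden rate is particularly
construction-dependent: with white spatial noise, site-level agriculture
exposure varies mostly through the shared run-ensemble draw, so per-seed
rates are lumpy even though the mild-vs-harsh ordering holds in
expectation.

# Numerical choices and degenerate inputs

Distance ties in cell selection break lexicographically; percentiles use
linear interpolation; year windows are inclusive; the agreement rule for
zero changes and zero means is as above; runs with baseline mean ≤ 1e-12
are excluded per site. The sensitivity index refuses communities with no
occupations at all ($X + NX = 0$); the PCA refuses all-constant item
matrices and fewer than two households; min-max scaling refuses degenerate
(single-community or zero-range) sets unless bounds are supplied; the
coastal sampler refuses an empty eligible set. Grid containers validate
monotone coordinates, matching mask and array shapes, and disjoint
historical/future windows at construction.

# Problem sizes used by the test suite

The oracle-equivalence test runs 1000 random communities against a
brute-force household enumeration at 1e-12. Monte-Carlo checks of exposure
recovery and double-burden ordering use 50 seeded replicates of a
72-site, two-scenario study on a 16°×16° box (a quarter of the default
domain area, chosen to keep ensemble arrays small while leaving >100 ocean
cells for the cell-count sweep); recovery is asserted within 3 Monte-Carlo
SE and the sector-gap sign in at least 95% of seeds. Mixed-model coverage
uses 100 simulated cohorts at the real design's country sizes. Bootstrap
tests use 20–60 replications; the default of 1000 is exercised by the
acceptance script.

# Limitations

Sensitivity captures the economic dimension of dependence only; adaptive
capacity is out of scope, as are regridding between resolutions,
bias-correction of forcings, and habitat types absent from global marine
ensembles (reefs, seagrass). Exposure at a site inherits the coarse grid of
the ensembles; the 20-cell / 11×11 neighbourhoods smooth over sub-grid
heterogeneity. The Euclidean combination weights the two scaled axes
equally; the scaling that preceded the published distance is not uniquely
determined, which is why both the min-max and raw-units variants are
exposed.
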