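# coastimpact

Community-scale assessment of potential climate-change impacts on the two
food-producing sectors tropical coastal communities depend on: small-scale
**fisheries** and small-scale **agriculture**.

Who this is for: researchers working at the interface of household
socioeconomic surveys and gridded climate-impact projections who need to
(1) score how strongly each community depends on each sector, (2) extract
mid-century productivity changes at survey sites from multi-model ensembles,
and (3) combine and compare the two across communities and countries.

## The model

**Sensitivity.** Each household ranks all livelihood activities that bring
in food or income. For a focal sector with engaged-household count *X*,
counterpart count *NX*, community size *N*, and household-level
ranking-direction counts *r_x*, *r_nx*,

```
S = X/(X+NX) × N/(X+NX) × (r_x/2 + 1)/(r_x + r_nx + 1)
```

giving S_A (agriculture), S_F (fisheries) and S_AF (both sectors jointly,
against the off-sector counterpart), each in [0, 1]. Household wealth
("material style of life") is the first principal axis of 16 binary material
items, community means rescaled to [0, 1].

**Exposure.** Percent change between a historical window (1983–2013) and
mid-century (2046–2056) in: total consumer biomass over the 20 nearest ocean
cells (haversine distance, 1° grid, 16 model runs) for E_F; and rain-fed
rice/maize/cassava yield over the land cells of an 11×11 window (0.5° grid,
20 runs, cassava single-model) for E_A, with per-run crop averaging. The
composite is E_AF = (E_A + E_F)/2. Each site also gets 25th/75th ensemble
percentiles and model-run agreement (the fraction of runs matching the
ensemble-mean direction).

**Potential impact.** Sensitivity and exposure *loss* (gains floor at zero)
are min-max scaled across the community set and combined as the Euclidean
distance from the origin, √(s² + e²) ∈ [0, √2]. A community with
simultaneous projected losses in both sectors bears a **double burden**.

**Statistics.** Every reported average is the intercept of a country
random-effect model (Satterthwaite df); sector comparisons model the paired
per-community difference; the wealth-impact regression reports bootstrap SEs
(communities resampled within country) and marginal/conditional R².

A synthetic-data generator emulates household surveys, gridded ensembles,
site coordinates and a fine coastal population raster, so the entire
pipeline runs and is tested without external downloads.

## Worked example

```r
library(coastimpact)

cfg <- synthetic_config(seed = 1)          # 72 communities, 5 countries
res <- run_pipeline(cfg, n_boot = 200)
print(res)
#> <impact_pipeline> 72 communities, scenarios: ssp126, ssp585
#>   ssp126: E_F -2.0%, E_A 2.9%, gap -5.0 (p=0.00892), double burden 0%
#>   ssp585: E_F -13.4%, E_A 2.3%, gap -15.7 (p=3.84e-05), double burden 0%

res$analysis$ssp585$mean_E_F
#> mixed mean: -13.42 +/- 0.6608 (SE); t = -20.3, df = 3.87, p = 4.5e-05 [lmm]
res$analysis$ssp585$sector_difference
#> mixed mean: -15.68 +/- 0.7622 (SE); t = -20.6, df = 3.92, p = 3.84e-05 [lmm]
res$analysis$ssp585$msl_regression
#> slope 0.3222 +/- 0.1275 (bootstrap SE, n = 200); p = 0.0115; R2 m = 0.061, c = 0.456

head(res$impact[res$impact$scenario == "ssp585",
     c("community_id", "S_AF", "E_F", "E_A", "potential_impact")], 3)
#>    community_id      S_AF       E_F      E_A potential_impact
#> 73          C01 0.1621466  -9.83517 3.007984        0.2512612
#> 74          C02 0.1064477 -12.11125 2.476729        0.4438565
#> 75          C03 0.1982855 -12.56694 2.688895        0.6358488
```

Reading this: under the high-emissions scenario the synthetic communities
face a mean fisheries loss of 13.4% (the generating truth is −14.7%, and
the estimate sits within ensemble noise of it) against a small agriculture
gain, a paired sector gap of −15.7 points with the fractional
country-level degrees of freedom characteristic of the random-effect
design, and per-community potential-impact scores that blend each
community's dependence (S_AF) with its local projected loss.

The same functions work piecewise: `community_sensitivity()`,
`msl_scores()`, `site_exposure()`, `ensemble_stats()`, `potential_impact()`,
`mixed_mean()`, `cohens_d()`, `random_coastal_sample()`. A thin CLI wrapper
is provided in `scripts/pipeline.R`.

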