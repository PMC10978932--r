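# pm25burden

Scenario-based projection of deaths attributable to ambient fine
particulate matter (PM2.5), with a four-factor decomposition of the change
in the burden and an SDG3.9 attainment analysis. The package is aimed at
environmental-health and exposure modellers who want a tested, reusable
implementation of the standard attributable-mortality pipeline —
exposure–response curves, multi-model concentration ensembles, death-rate
projection, Shapley-type decomposition, and policy scoring — exercised
end-to-end on a self-contained synthetic world with known ground truth.

## The model

Attributable deaths are computed per grid cell and summed over 15 adult
age groups *a* and 6 causes *d*:

    DAPP = Σ_{a,d} PAF_{a,d}(c) · POP · Rate_{a,d} · AgeP_a,
    PAF  = (RR(c) − 1) / RR(c)

with relative risk RR taken from tabulated exposure–response curves
(piecewise-linear, RR = 1 below a counterfactual concentration, flat
beyond the last knot). Concentrations are composed from aerosol
components, `PM2.5 = BC + OA + SO4 + NH4 + 0.25·SS + 0.1·dust` (ammonium
derived as `36·SO4/96` when absent), calibrated per model to the observed
base-year grid by a trend-preserving ratio rule, and averaged across
models. Cause-specific death rates follow
`ln m ~ N(β1·min(SDI,0.8) + β2·max(SDI−0.8,0) + θ_a·t + α_la + ln R + ε̂, σ)`
with per-series ARIMA residual forecasts. The change in DAPP between two
years is attributed to population, age structure, death rates and
concentration by sequential substitution averaged over all 24 factor
orderings (the Shapley value), and SDG3.9 attainment is scored at 10/20/30 %
reduction thresholds, including ±20 % intervention sensitivity analyses.
See `vignettes/methods.Rmd` for assumptions, parameters and limitations.

## Worked example

```r
library(pm25burden)

world <- generate_world(world_config(seed = 1))
proj  <- run_projection(world, years = c(2000, 2015, 2030, 2050),
                        band_years = integer(0))

tot <- subset(proj$totals, band == "mid" & scenario == "SSP1-2.6")
relative_change(setNames(tot$deaths, tot$year), 2015, 2030)
#> [1] -18.87289

decompose_projection(proj, "SSP1-2.6", year0 = 2015, year1 = 2030)
#> <decomposition_result> DAPP 4193841 -> 3402342 (-18.9%), 24 orderings
#>   population            +228233 deaths  (+5.4%)
#>   age_structure        +1595221 deaths  (+38.0%)
#>   death_rate           -1640358 deaths  (-39.1%)
#>   concentration         -974595 deaths  (-23.2%)

intervention_analysis(proj, "SSP1-2.6", year = 2030)[, c("cell", "change_pct")]
#>        cell change_pct
#> 1      none  -18.87289
#> 2   pm_only  -32.08969
#> 3 rate_only  -35.09831
#> 4      both  -45.67175

historical_target(proj)$target
#> [1] 30.24889
```

Under the sustainability-like scenario the burden falls 18.9 % by 2030 —
just short of the moderate (20 %) SDG3.9 target — because a large aging
effect (+38 %) nearly cancels the healthcare-driven rate decline (−39 %),
leaving the concentration decline (−23 %) and population growth (+5 %) to
set the net change. An additional 20 % cut in either concentrations or
death rates pushes the scenario past the moderate target. The data-driven
reduction target derived from the best-performing tail of historical
national reductions is ≈ 30 %.

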