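---
title: "Projecting and decomposing PM2.5-attributable mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting and decomposing PM2.5-attributable mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pm25burden)
```

## The burden identity

The quantity at the centre of the package is the number of deaths
attributable to ambient fine particulate matter (DAPP), evaluated per grid
cell and summed over fifteen adult age groups $a$ (25--30 through 95+) and
six causes of death $d$ (lung cancer, COPD, lower respiratory infection,
ischaemic heart disease, stroke, type-2 diabetes):

$$\mathrm{DAPP} = \sum_{a,d} \mathrm{PAF}_{a,d}(c) \times \mathrm{POP}
  \times \mathrm{Rate}_{a,d} \times \mathrm{AgeP}_a,$$

where $c$ is the cell's annual-mean PM2.5 concentration, POP the cell
population (adults 25+), $\mathrm{Rate}_{a,d}$ the national cause- and
age-specific death rate, $\mathrm{AgeP}_a$ the national age fraction, and

$$\mathrm{PAF}_{a,d} = \frac{RR_{a,d}(c) - 1}{RR_{a,d}(c)}$$

the population attributable fraction. Relative risks come from tabulated
exposure--response curves: piecewise-linear in concentration between knots,
$RR = 1$ at and below a configurable counterfactual (theoretical
minimum-risk) concentration, and flat above the last knot. Linear
interpolation with flat extrapolation preserves monotonicity and the
saturating shape of the tabulated values without inventing curvature.
Ischaemic heart disease and stroke carry age-specific curves; the other
four causes use one all-ages curve. Curves failing the monotone, $RR \ge 1$
contract are rejected on load; an explicit isotonic-repair flag exists
because silent repair would hide data errors.

Death rates and age fractions are applied uniformly to all cells of a
country (rate and age-structure projections are national-level);
concentrations enter per cell. An open modelling choice is whether the PAF
should be evaluated at cell-level or at population-weighted national
concentrations; we evaluate per cell, which preserves the spatial
nonlinearity of the response.

## PM2.5 from aerosol components

Simulated PM2.5 is composed offline from surface concentrations of the
aerosol components each pseudo-model reports:

$$\mathrm{PM}_{2.5} = BC + OA + SO_4 + NH_4 + 0.25\,SS + 0.1\,dust,$$

with ammonium derived as $NH_4 = 36 \times SO_4 / 96$ (ammonium present
only as ammonium sulfate) when a model does not report it. Nitrate is
deliberately omitted from the composition for cross-model consistency.
The 0.25 and 0.1 factors approximate the sea-salt and dust mass fractions
in the PM2.5 size range.

Simulated trajectories are not directly comparable with observations, so
each model is calibrated to the observed base-year (2015) grid by the
multiplicative ratio rule
$\mathrm{cal}(t) = \mathrm{obs} \times \mathrm{sim}(t)/\mathrm{sim}(2015)$,
which preserves the simulated relative trend and reproduces the
observations exactly in the base year. This is the module's most
consequential choice; an additive-offset dialect is exposed as a
configuration switch for sensitivity analysis. Cells whose base-year
simulation falls below a floor of 0.01 µg/m³ have no meaningful trend
ratio; they are flagged and held at the observed value. Ensemble statistics
(cell-wise mean and empirical 2.5th/97.5th percentiles, linear
interpolation) are computed across models after averaging ensemble members
within each model, so member count never dilutes across-model spread. The
headline burden series follows the ensemble-mean concentration; per-model
burdens are kept for the uncertainty envelope. Because the attributable
fraction is nonlinear in concentration, the burden of the mean
concentration differs from the mean of per-model burdens (a Jensen gap);
both paths are computed and stored.

## Projecting death rates

Cause-specific death rates follow a log-linear model driven by the
Socio-Demographic Index (SDI), a $[0,1]$ geometric mean of min-max-rescaled
log income per person, educational attainment, and total fertility under
age 25 (fertility inverted):

$$\ln m \sim N(\hat y + \hat\epsilon,\ \sigma), \qquad
  \hat y = \beta_1\,\min(S, 0.8) + \beta_2\,\max(S - 0.8, 0)
         + \theta_{a}\,t + \alpha_{la} + \ln R .$$

The two SDI segments are parameterised as a hinge so that $\hat y$ is
continuous at the knot by construction (a two-segment notation leaves the
join ambiguous). $\theta$ is an age-specific secular trend (estimated per
age--cause block), $\alpha$ a region-by-age(-by-cause) intercept, and
$\ln R$ a user-supplied risk-factor offset (default 0) that is absorbed
into the intercepts — shifting it is a pure reparameterisation, which the
tests verify. "Region" may be the country itself or a coarser grouping via
an optional mapping table.

The fit absorbs the intercept block by within-group demeaning
(Frisch--Waugh) and solves the reduced normal equations; the demeaned
design is well-conditioned and the trend block is row-disjoint across
age--cause groups. Identifiability requires within-region SDI variation on
both sides of the knot; degenerate designs (constant SDI, no observations
above the knot) raise errors naming the collinear block rather than
returning silently pivoted estimates.

Residuals $\epsilon$ are forecast per series (country × age × cause) by
ARIMA models selected by AICc over the small grid (0,0,0), (1,0,0),
(0,1,0), (1,0,1); series are mean-free by construction so models are
fitted without a mean and forecasts revert to zero. Forecasts are damped
geometrically (0.95 per step) so that the difference-order model cannot
drift without bound over a 35-year horizon. Projected rates are
$\exp(\hat y + \hat\epsilon)$ with a nominal 95 % band
$\exp(\hat y + \hat\epsilon \pm 1.96\hat\sigma)$; the band describes the
realised rates (Equation above defines a distribution for $\ln m$), and
simulation tests check its coverage stays within 90--99 %.

## Decomposition of change

The change in DAPP between two states is attributed to its four factor
blocks — population, age structure, death rates, concentration — by
sequential substitution: switch factors one at a time from the first to
the second period, record the change at each step, and average over all
$4! = 24$ switching orders. The average equals the Shapley value of the
set function $v(S)$ = DAPP with the factors in $S$ switched, so the
implementation evaluates the 16 subset values once and assembles all
paths from them; tests compare against an independent subset-enumeration
oracle and verify exact telescoping ($\sum_f \phi_f = \Delta$DAPP).
Exposure--response curves are never substituted: they are
scenario-invariant. Contributions are reported in deaths and as percent of
the first-period DAPP; the output is the averaged attribution per factor
(not a cumulative path under one fixed order), and is labelled as such.

## SDG3.9 scoring and interventions

Attainment is scored against weak/moderate/ambitious targets of 10/20/30 %
reduction relative to the 2015 baseline, with a closed boundary (exactly
−20 % meets the moderate target). A data-driven target is derived from the
historical (2000--2015) national reduction distribution as the 10th
percentile of best performance — the 90th percentile of reductions under
linear interpolation; both the tail and the interpolation convention are
arguments because the convention is not standardised. Interventions
multiply concentrations and/or death rates (default 0.8, a 20 % additional
improvement) on the *inputs*, after which DAPP is recomputed — the PAF is
nonlinear in concentration, so scaling outputs would be wrong for the
air-quality lever; the same multipliers are applied to the low/high input
bands when requested. Rate interventions scale the burden exactly
linearly, which the tests assert to machine precision.

## The synthetic world

All analysis code is exercised end-to-end on a generated world whose
statistical structure mirrors the inputs the method expects: a 1°-style
grid (default 20 × 40) with a one-cell ocean border and twelve countries
as contiguous blocks of land cells; national adult populations spread over
fixed within-country Dirichlet weights (ocean cells hold zero population);
national age pyramids $p_a \propto e^{-\lambda a}$ whose slope declines
over time (aging); SDI paths per country and scenario that coincide before
the 2015 base year; ground-truth mortality parameters
($\beta_1 = -3$, $\beta_2 = -1$, Gompertz-type age gradient of 0.43 per
5-year group, lognormal noise $\sigma = 0.05$) from which rate tables are
generated; and per-scenario, per-model aerosol component trajectories
(log-linear trends, a shared AR(1) internal-variability draw per model,
model-specific multiplicative offsets that the base-year calibration
removes, and fixed compositional shares that the composition formula
reassembles exactly).

Scenario drivers are expressed as interpretable anchors relative to 2015
— population ratio, SDI increment, aging factor (the ratio of the
death-weighted age-structure sum), and population-weighted PM2.5 ratio at
2030 and 2050 — and the generator solves for the underlying pyramid slopes
and trend rates. The four default scenarios emulate the published
ScenarioMIP storylines quantitatively: under the sustainability pathway
the population-weighted PM2.5 falls about 31 % by 2030 and the burden
falls just short of 20 %; under regional rivalry PM2.5 rises about 12 %
with high population growth; aging and healthcare improvements are large
and nearly offsetting everywhere. A pollution-control tilt makes PM
trends country-dependent (strong-control scenarios clean up the most
polluted countries fastest; weak control lets them deteriorate fastest)
while an exact renormalisation keeps the population-weighted mean ratio on
its anchor; combined with saturating risk curves this reproduces the
marked asymmetry between the concentration factor's effect under falling
versus rising pollution. The 65+ share of attributable deaths anchors the
2015 pyramid (the solver uses a slightly reduced effective age slope,
0.43 − 0.033, because the age-specific curves attenuate risk at older
ages). Historical heterogeneity in national PM trends and SDI growth is
chosen so that the best-performing tail of 2000--2015 national reductions
puts the derived target near 30 %.

What the generator does *not* emulate: real-world country magnitudes or
shapes, within-country demographic heterogeneity (pyramids and rates are
national), cause-of-death correlation structure, migration, and any
atmospheric chemistry or transport — concentrations are statistical
trajectories, not physics. Passing tests therefore demonstrate the
correctness and calibration behaviour of the *method* on data with the
assumed structure, not the accuracy of any real-world projection.

## Numerical choices and problem sizes

Default problem sizes keep the full analysis desk-scale: the default world
is 20 × 40 cells, 12 countries, 4 scenarios × 5 models, 2000--2050; the
parameter-recovery study uses 50 countries × 30 years × 15 ages × 6 causes
(135 000 rows per fit, about one second via the demeaned normal
equations). Percentiles use linear interpolation (R type 7) everywhere.
The ratio calibration floor is 0.01 µg/m³. ARIMA fits fall back to a
white-noise model when a series is degenerate or a candidate order fails
to converge. Run manifests checksum every output file and deliberately
exclude timestamps so that identical configurations yield identical
manifests. Gridded fields are exchanged as long-format CSV with explicit
units columns; tables are long/tidy CSV; configuration is YAML written at
full precision so a written world regenerates bit-identically from its
seed.

## Known limitations

The hinge knot at SDI 0.8 is fixed, matching the model the projections
are built on, and is not re-estimated. The residual ARIMA grid is small by
design; series with richer dynamics will be under-fitted toward white
noise. The uncertainty envelope crosses model spread with the death-rate
band but treats the two sources as independent and ignores
exposure--response curve uncertainty beyond the supplied low/mid/high
bands. The decomposition attributes interactions by averaging; it does not
report them separately.
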