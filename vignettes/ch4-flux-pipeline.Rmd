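---
title: "From chamber closures to warming statistics: the ch4flux methods"
author: "ch4flux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From chamber closures to warming statistics: the ch4flux methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ch4flux)
```

## The measurement problem

High-latitude soils exchange methane with the atmosphere in both
directions: methanogenic archaea produce CH₄ in anoxic microsites
(P_soil) while methanotrophic bacteria oxidise both that soil-produced
CH₄ (C_soil) and CH₄ diffusing in from the atmosphere (C_atm). A static
chamber only sees the net of the three,

$$F_{net} = P_{soil} - C_{soil} - C_{atm},$$

so a near-zero chamber flux can hide vigorous, opposed microbial
activity. `ch4flux` implements the full analysis chain for paired
warming experiments (open-top chambers, OTC, vs ambient plots): flux
computation with quality control, inhibition-based partitioning of the
identity above, seasonal treatment statistics, and microclimate
processing — plus a synthetic generator that gives every stage a
ground-truth recovery test.

Sign convention throughout: **negative flux = net uptake by the soil**,
in mg C-CH₄ m⁻² d⁻¹.

## Closure curves to fluxes

A chamber deployment yields a 1 Hz CH₄ concentration series over a
4-minute closure. The first 30 s (the *deadband*, `deadband_s`) are
discarded — chamber placement disturbs the headspace — and the slope of
the remainder comes from ordinary least squares (`fit_slope()`). The
slope in ppm s⁻¹ converts to an areal flux through the ideal gas law
(`ppm_slope_to_flux()`):

$$F = s \cdot 10^{-6} \cdot \frac{P}{RT} \cdot h_{eff}
      \cdot 12.011 \cdot 1000 \cdot 86400,$$

where $P/(RT)$ is the molar density of chamber air, $h_{eff}$ the
effective headspace height (chamber height + collar headspace, default
0.20 + 0.05 m — but always an explicit input, since collar insertion
depth varies), 12.011 g mol⁻¹ converts moles of CH₄ to grams of carbon,
and 1000 · 86400 rescale to mg and days. Chamber pressure comes from the
isothermal barometric formula at site elevation
(`elevation_to_pressure()`, with $g$ = 9.80665 m s⁻², $M$ = 0.0289644 kg
mol⁻¹, $R$ = 8.314 J mol⁻¹ K⁻¹), evaluated at chamber temperature; the
chamber vent is assumed to equalise to ambient pressure. Water-vapour
dilution is not corrected (the analyzer is assumed to report dry mole
fraction), and no nonlinear (exponential/HMR-type) closure model is
offered.

A hand-checkable anchor: a slope of −1.0 × 10⁻⁴ ppm s⁻¹ at 10 °C,
90 kPa and $h_{eff}$ = 0.25 m gives −0.992 mg C m⁻² d⁻¹.

### Quality control

Three replicate closures per collar and occasion are averaged
arithmetically (`average_collar()`), flags unioned. Screening
(`qc_filter()`) then works on the plot-level table:

* rows with R² ≥ `r2_include` (default 0.8) are **always** kept;
* rows with 0 ≤ R² < 0.8 are kept *unless* they are gross outliers —
  this keeps valid near-zero fluxes, whose closure fits are inevitably
  poor because there is no trend to fit.

The outlier rule removes a low-R² row whose flux deviates by more than
`outlier_sigma` (default 3) standard deviations from the mean of the
**other** rows of its community × treatment × year group. The
leave-one-out form matters: with pooled statistics a single gross
outlier in a group of five inflates the spread so much that it can never
exceed 1.79σ, and the screen would be vacuous. Groups under 3 rows are
retained unscreened with a warning. The grouping is a configuration key;
community × treatment × year is the narrowest choice with enough rows
(~5 plots × ~6 occasions).

The R² of a zero-variance (flat) closure is *defined* as 0, so the
screening branch is total.

Cells missing one or two of the expected five plots are filled with the
group mean (`impute_missing()`, flag `IMPUTED`) to restore the balanced
structure repeated-measures models need; cells missing three or more are
left alone — a mean from two plots is not data. Non-missing values are
never altered, and the group mean is preserved exactly.

`covariate_accumulate()` adds within-year running sums ∑T_soil and ∑SWC
(cumulative climate exposure up to each occasion) and two response
transforms used by downstream models: the negative square root
$-\sqrt{-x}$ for uptake rows (variance stabilisation; undefined for
emissions) and the signed log $\mathrm{sign}(x)\ln(1+|x|)$.

## Inhibition partitioning

Acetylene is a specific inhibitor of methane monooxygenase. The field
protocol generates it in situ: 1.23 g of calcium carbide hydrolyses to
one mole of C₂H₂ per mole of CaC₂, which in a 10 cm opaque chamber over
a collar (cylinder r = 0.10 m, h = 0.15 m) at 283 K / 90 kPa is a ~10 %
vol headspace fraction (`acetylene_fraction()` computes 10.6 %). After a
2 h incubation all methanotrophy is (assumed) blocked, so the post
closure measures P_soil.

Two measurements cannot identify three unknowns, so the partition
(`partition_fluxes()`) uses the minimal-assumption closure:

* **F_net ≤ 0**: total oxidation = P_soil − F_net ≥ P_soil, so all
  production is consumed: C_soil = P_soil, C_atm = −F_net.
* **0 < F_net ≤ P_soil**: some production escapes: C_soil = P_soil −
  F_net, and C_atm = 0 — atmospheric uptake cannot be resolved when the
  soil is a net source, so it is set to the identified lower bound.
* **F_net > P_soil**: inconsistent (emission exceeding gross
  production); both components zeroed and flagged
  `INCONSISTENT_FNET_GT_P` rather than forced.

Production estimates are guarded two ways (`estimate_production()`): the
post-incubation closure must have R² ≥ 0.8 (otherwise P_soil is
*undefined*, flag `P_UNDEFINED_LOW_R2`, and the plot contributes only
its F_net), and a negative post flux — physically impossible production,
i.e. incomplete inhibition — is clamped to zero with flag
`NEGATIVE_POST_FLUX`. P_soil is throughout a *lower bound*: the field
protocol cannot verify complete inhibition, and acetylene diffusion
through wet soil is not modelled. No R² cutoff is applied to the pre
closures: near-zero net fluxes are legitimate data here.

`partition_campaign()` maps this over matched pre/post pairs, reports
group means ± SE per community × treatment, and tests total oxidation
> 0 per group with the exact signed-rank test. Note the power floor: a
group of three plots cannot go below p = 1/8 one-sided.

## Seasonal statistics

**Normalization.** Fluxes within one occasion × community (both
treatments pooled — pooling is what makes effect sizes comparable across
occasions) are arcsinh-transformed,
$y = \ln(x + \sqrt{x^2+1})$, which is defined for both signs and
log-like in the tails, then z-scored with the sample (n−1) sd
(`arcsinh_standardize()`). The output is exactly mean 0, sd 1; a
zero-variance group is flagged rather than divided by zero.

**Effect sizes.** `hedges_g()` computes Cohen's d of OTC − Ambient on
the pooled-sd scale with Hedges' small-sample correction
$J = 1 - 3/(4\,df - 1)$; the variance uses the standard large-sample SMD
formula $1/n_1 + 1/n_2 + g^2/(2(n_1+n_2))$. On (normalized) fluxes a
*negative* g means increased oxidation capacity under warming — more
uptake, less emission, or both. `effect_size_table()` applies this per
occasion × community.

**Zero-flux tests.** `wilcoxon_signed_rank()` tests symmetry around
zero. Exact zeros are dropped (the standard signed-rank convention) and
|x| ties mid-ranked. For n ≤ 20 the p-value is exact: the distribution
of the positive-rank sum over all 2ⁿ sign assignments is built by
dynamic programming on twice the ranks (integers even under midranks);
above 20 a normal approximation with continuity and tie correction takes
over. The threshold 20 keeps the exact branch both cheap (the DP is
O(n · n²), not O(2ⁿ)) and wide enough for field group sizes.
`stats::wilcox.test` is not used because it abandons exact p-values
under ties; the test suite instead checks the DP against an explicit
2ⁿ enumeration oracle for all n ≤ 12.

**Percent change.** Per occasion,
$\Delta\% = 100\,(\bar F_{Amb} - \bar F_{OTC}) / |\bar F_{Amb}|$, so
positive values always mean increased oxidation capacity; the season
summary is the mean ± SE over occasions. This estimator was chosen —
the field convention of quoting "x % ± y %" does not pin one down —
because it yields both a point estimate and an SE at the season level
and reproduces both canonical cases with one formula (ambient −1.0 vs
OTC −2.4 → +140 % uptake increase; ambient +1.0 vs OTC +0.088 → 91.2 %
emission reduction). Occasions with |ambient mean| below
`percent_change_floor` (default 0.05 mg C m⁻² d⁻¹) are excluded and
reported: the ratio is unstable around a zero denominator, which is
exactly the near-zero wet-meadow situation.

**Q₁₀.** For the uptake subset (F_net < 0 only; the estimator rejects
mixed-sign input), `q10_estimate()` regresses ln(−F_net) on 1000/T_K.
The slope m gives the apparent activation energy $E_a = -1000\,R\,m$ and

$$Q_{10} = \exp\!\left(\frac{10\,E_a}{R\,T_{ref}(T_{ref}+10)}\right),$$

with $T_{ref}$ defaulting to the subset's mean soil temperature (the
reference is otherwise arbitrary, and the subset mean is where the fit
is best constrained). Significance is the regression slope t-test at
0.05. Preconditions: ≥ 5 observations spanning ≥ 2 °C.

**SWC response.** `swc_response()` fits F_net = a·SWC² + b·SWC + c on
the uptake subset; with a > 0 the vertex −b/(2a) is the soil water
content of maximal uptake (diffusion limitation above it, desiccation
below).

**Model tables.** `build_model_table()` assembles the cumulative
covariates and transforms and, under the uptake-only switch, drops the
net-emitting tussock-tundra community and all F_net ≥ 0 rows — isolating
oxidation-driven uptake from concurrent methanogenesis. Mixed-model
fitting itself is deliberately out of scope: the package hands a clean
table to lme4/emmeans rather than wrapping them.

## Microclimate

`daylight_season_mean()` averages each logger channel over June–August
samples with local hour in [9, 17) — half-open so 17:00 is not counted,
and daylight-restricted because the OTC warming signal is strongest
under insolation. `detect_snow_days()` classifies a calendar day as
snow-covered when the 2 cm surface channel shows daily range < 1.5 °C
*and* daily mean within ±1.5 °C of zero: a snowpack both damps the
diurnal swing and pins the sensor near the melting point. The cited
snow-classification literature does not restate its rule, so these
thresholds are configuration keys validated only against the synthetic
generator; a clear-sky deep-freeze day (tiny range, mean −15 °C) is
deliberately snow-free under this rule. `snowmelt_day()` returns the
first day on or after April 1 (by date arithmetic — DOY 91 or 92
depending on leap year) starting ≥ 3 consecutive snow-free days; a
2-day thaw does not count. `treatment_delta()` differences arm means per
community with a between-plot-variance SE.

## The synthetic world

The generator exists so that every stage has a recovery test with known
truth; it is a stated world, not a fit to any dataset.

* **Closures** (`simulate_closure()`): a straight line whose slope is
  the *exact inversion* of the flux conversion (so
  noiseless round trips are identities to 1e−9), plus an exponentially
  decaying placement pulse confined to the deadband (default amplitude
  0.05 ppm), plus AR(1) noise (innovation sd 0.002 ppm, ρ = 0.3 —
  1 Hz analyzer readings are autocorrelated, and white noise would make
  the QC step unrealistically easy). The analyzer noise magnitude is a
  fixture constant: instrument specifications for the field analyzers do
  not state it in these units.
* **Campaigns** (`simulate_campaign()`): per plot × occasion, T_soil and
  SWC are drawn from the community climate; production is
  $p_0\,q_{10,prod}^{(T-10)/10} g(SWC)$ with $g$ logistic in SWC
  (methanogenesis needs saturation), atmospheric uptake capacity is
  $c_{atm,0}\,q_{10,ox}^{(T-10)/10} f(SWC)$ with $f$ a concave-down
  quadratic peaking at SWC 0.2 (aeration vs desiccation), and
  soil-derived oxidation is the smaller of production and an analogous
  demand term $c_{s,0}\,q_{10,ox}^{(T-10)/10} f(SWC)$. The identity
  F_net = P − C_soil − C_atm holds to machine precision by construction.
  Default parameters (`default_community_params()`) are fixture
  constants chosen once so ambient cells show the canonical sign pattern
  — uptake in HD/MD/MM, near-zero MW, emission in TT — and OTC cells
  show scaled-up oxidation capacity (×2.4 in HD, the anchor the
  percent-change recovery test uses). Q₁₀ defaults: 3.0 for production,
  2.0 for oxidation (methanogenesis is the more temperature-sensitive
  process). A per-row proxy R² of $F^2/(F^2+\sigma^2)$ makes near-zero
  true fluxes carry low R², as real near-zero closures do.
* **Inhibition pairs**: the pre closure realizes F_net (transparent
  chamber, h_eff 0.25 m), the post realizes P_soil (opaque 10 cm
  chamber, h_eff 0.15 m) — the complete-inhibition idealisation.
* **Logger years** (`simulate_logger_year()`): 15-minute steps; the
  snow-free surface channel is a seasonal mean plus a diurnal sinusoid
  peaking at 14:00; under snow the signal is a slowly drifting daily
  level near 0 °C (sd `under_snow_sd`) with 0.03 °C jitter — a buffered
  sensor drifts at the day scale rather than flickering sample to
  sample, and at 96 samples/day white noise of sd 0.3 °C would have an
  expected daily range of ~1.5 °C, right at the classification
  threshold. Soil moisture steps up by `melt_swc_pulse` at melt-out and
  relaxes over ~a month.

What the generator does **not** emulate: analyzer drift, chamber leaks,
pressure artefacts, ebullition, plant-mediated (aerenchyma) transport,
incomplete acetylene inhibition, spatial correlation between plots, and
logger gaps. A green recovery test therefore establishes that the
estimators invert the stated model — not that field data satisfy it.

Seeding: one integer seed; every sub-stream (per cell, per closure, per
logger) derives deterministically from it via a Lehmer step, so
generators are bit-reproducible and the full pipeline is byte-identical
across reruns (`run_pipeline()` writes a manifest and all products as
RFC-4180 CSV).

## Numerical conventions and edge cases

* Zero-variance closure → slope 0, R² 0 (not NaN).
* Zero surviving replicates → missing value, not an error.
* All-zero sample in the signed-rank test → error (test undefined).
* Percent change requires ≥ 3 usable occasions; excluded occasions are
  reported, not silently dropped.
* Q₁₀ of temperature-independent rates is exactly 1 (slope 0 ⇒ Eₐ 0).
* Negative R² from floating-point cancellation is clamped at 0.
* The snowmelt run test requires calendar contiguity, so a data gap
  cannot fake three consecutive snow-free days.

## Known limitations

The partition is under-determined on net-emission days (C_atm is then a
lower bound, 0); P_soil is a lower bound everywhere; the 3σ screen's
grouping and residual scale (flux vs slope) are conventions exposed as
configuration, not facts; the snow-day thresholds are validated only
against the synthetic world; and the percent-change estimator is one of
several defensible definitions of a seasonal "% change" (it is the one
that yields an SE). Mixed-effects inference, biomass estimation,
tea-bag-index protocols and plotting beyond QC are out of scope.
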