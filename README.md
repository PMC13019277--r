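# ch4flux

Analysis pipeline for closed-chamber methane (CH₄) flux measurements in
long-term passive-warming experiments — paired open-top chamber (OTC)
and ambient plots across tundra plant communities (dry heath HD, dry
meadow MD, mesic meadow MM, wet meadow MW, tussock tundra TT).

It is written for field ecologists and biogeochemists who have 1 Hz
chamber closure curves, plot-level campaign tables, acetylene-inhibition
closure pairs and sub-daily microclimate logger files, and want the full
chain from raw concentrations to treatment statistics in one tested,
reproducible package.

## What it computes

**Closure curves → areal fluxes.** After a 30 s deadband, the CH₄
concentration slope *s* (ppm s⁻¹) comes from ordinary least squares, and
the areal flux from the ideal gas law,

    F = s · 10⁻⁶ · P/(R·T) · h_eff · 12.011 · 1000 · 86400   [mg C-CH₄ m⁻² d⁻¹]

with chamber pressure *P* from the barometric formula at site elevation,
*T* the chamber temperature, and *h_eff* the effective headspace height.
Negative fluxes are net uptake by the soil. QC: rows with R² ≥ 0.8 are
always kept; low-R² rows are screened at 3 leave-one-out group standard
deviations; triplicates are averaged per collar; cells missing ≤ 2 of 5
plots are mean-imputed.

**Acetylene-inhibition partitioning.** Acetylene blocks methane
monooxygenase, so a post-incubation closure measures gross production
P_soil. The identity F_net = P_soil − C_soil − C_atm then splits the net
flux into oxidation of soil-produced CH₄ (C_soil) and of atmospheric CH₄
(C_atm): when F_net ≤ 0 all production is re-oxidised (C_soil = P_soil,
C_atm = −F_net); when 0 < F_net ≤ P_soil, C_soil = P_soil − F_net and
C_atm = 0.

**Seasonal statistics.** arcsinh transformation + z-scoring per occasion
× community; Hedges'-corrected effect sizes g (negative g = increased
oxidation capacity under warming); exact Wilcoxon signed-rank tests
against zero flux; seasonal percent change of treatment means; Arrhenius
Q₁₀ from ln(uptake) vs 1000/T_K; a quadratic SWC–uptake response; and
assembly of mixed-model-ready tables (∑T_soil, ∑SWC, transformed
responses). Model *fitting* is intentionally out of scope.

**Microclimate.** Daylight (9–17 h) June–August means per logger channel;
snow-day classification from the collapsed diurnal amplitude at 2 cm;
snowmelt day = first of three consecutive snow-free days after April 1;
OTC − Ambient deltas with between-plot SEs.

**Synthetic data.** Seeded generators for closures, campaigns,
inhibition pairs and logger years with known ground truth, so every
stage has a parameter-recovery test and the pipeline runs end to end
with no external data.

## Worked example

```r
library(ch4flux)

## a 4-minute closure realizing a known uptake flux, with analyzer noise
tr <- closure_truth(true_flux = -0.992, noise_sd = 0.002,
                    chamber_temp = 10, elevation = 981, h_eff = 0.25)
s <- simulate_closure(tr, seed = 1)
closure_flux(s)
#>           slope     slope_se        r2      flux n_used qc_flags
#> 1 -0.0001030996 2.293982e-06 0.9070465 -1.022761    209

## seasonal warming effect in the dry heath (OTC uptake capacity x2.4)
sim <- simulate_campaign(scenario_config(seed = 1))
pc <- percent_change(sim$table, community = "HD")
#> HD: 147.3% +/- 7.1% (uptake increase)

## partition a net flux of -5 given a post-inhibition production of ~2
pr <- simulate_inhibition_pair(list(f_net_true = -5, p_soil = 2), seed = 1)
partition_fluxes(closure_flux(pr$pre)$flux,
                 estimate_production(pr$post)$p_soil)
#>       f_net   p_soil   c_soil    c_atm total_oxidation flags
#> 1 -4.995585 2.000449 2.000449 4.995585        6.996034
```

The closure flux −1.02 mg C m⁻² d⁻¹ recovers the stated −0.992 within
the noise of a single 4-minute fit (the estimator is unbiased; see the
tests). The percent change says warmed dry-heath plots took up ~2.5× as
much atmospheric CH₄ as ambient plots that season, and the partition
recovers the generator's (C_soil, C_atm) = (2, 5) split from the two
closures alone.

The chained pipeline (`run_pipeline(pipeline_config(h_eff = 0.25, ...))`)
writes `fluxes.csv`, `partition.csv`, `effect_sizes.csv`,
`percent_change.csv`, `q10.csv`, `model_table.csv`,
`microclimate_means.csv`, `snowmelt.csv` and a manifest; reruns with the
same seed are byte-identical. A thin CLI wrapper lives in
`inst/scripts/ch4flux.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the installed package's full pipeline — synthetic campaign, flux
computation, QC, inhibition partitioning, seasonal statistics and
microclimate processing — from the given seed and writes the JSON
result file.

## Vignette

`vignettes/ch4-flux-pipeline.Rmd` documents the model and its
assumptions, every tunable constant with units and defaults, what the
synthetic generator does and does not emulate, and the package's
numerical conventions and known limitations.
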