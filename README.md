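# oxipheno

Phenotyping of nocturnal pulse-oximetry (SpO2) recordings for sleep-apnea
cohorts, and the statistical protocol relating those phenotypes to incident
cardiovascular disease (CVD).

Obstructive sleep apnea exposes patients to intermittent hypoxia, a key
mechanism linking the disorder to cardiovascular risk — yet the standard
severity measure, the apnea–hypopnea index (AHI), summarizes the night as a
single event count. `oxipheno` extracts **31 oximetry patterns** from an
SpO2 trace across four analytic families and runs the full cohort
association analysis over them:

| Family | Patterns (count) |
|---|---|
| Desaturation characteristics | ODI2–ODI5, hypoxic burden (5) |
| Time-series distribution | mean, SD, skewness, kurtosis, median, nadir, T80–T94 (14) |
| Power spectral density | mean, SD, skewness, kurtosis, spectral entropy for the full band 0–0.1 Hz and the OSA band 0.00417–0.05 Hz (10) |
| Non-linear | sample entropy (m = 1, r = 0.25, at 0.2 Hz), central tendency measure (radius 1%) (2) |

Key definitions: ODI at threshold X is desaturation events of depth ≥ X%
per hour of sleep; hypoxic burden is the respiratory-event-anchored
desaturation area Σ∫max(0, baseline − SpO2)dt / TST in %·min/h with a
patient-specific window from the ensemble-average response; TX is the
percentage of sleep time with SpO2 ≤ X%; spectral entropy is −Σp·log p of
normalized in-band power; sample entropy is −log(A/B) over matching
templates; CTM is the fraction of Poincaré first-difference points inside
a fixed radius.

The association stage applies the cohort inclusion filter (AHI ≥ 5,
predominantly obstructive events, outcome known, no CVD before the 2-year
landmark), z-scores every pattern, and fits one covariate-adjusted Cox
proportional-hazards model per pattern (age, race, smoking, BMI, sex;
Efron ties) for the whole sample and for men and women separately, with
Benjamini–Hochberg FDR control at 0.05 within each analysis family.
Hazard ratios are per 1 SD. A synthetic cohort generator (signals,
respiratory events, hypnograms, covariates, landmark survival outcomes)
makes the whole pipeline testable without access-restricted
polysomnography data; see the methods vignette
(`vignettes/oximetry-phenotyping.Rmd`) for the model and every default.

## Worked example

Extract the patterns from one (here: synthetic) night:

```r
library(oxipheno)
nt <- generate_spo2(signal_config(duration_h = 4, event_rate = 25,
                                  depth_mean = 5, seed = 7))
fv <- extract_all(nt$signal, nt$hypnogram, nt$events)
round(unlist(fv[c("ODI3", "ODI4", "HypoxicBurden", "SpO2Mean", "SpO2SD",
                  "T90", "FFB_SpecEnt", "SampEn", "CTM", "AHI")]), 2)
#>          ODI3          ODI4 HypoxicBurden      SpO2Mean        SpO2SD
#>         30.79         29.47         63.85         95.23          1.47
#>           T90   FFB_SpecEnt        SampEn           CTM           AHI
#>          0.34          4.07          0.14          0.68         32.11
```

A severe synthetic night: ~30 desaturations/h deeper than 4%, a hypoxic
burden of 64 %·min/h, and only 0.3% of sleep below 90% saturation — depth
and frequency, not sustained hypoxemia.

Run the full pipeline on a simulated cohort in which ODI4 truly carries a
hazard ratio of 1.6 per SD:

```r
b <- run_pipeline(pipeline_config(
  mode = "simulate",
  cohort = cohort_config(n = 120, baseline_hazard = 0.03,
                         feature_betas = c(ODI4 = log(1.6))),
  signal = signal_config(duration_h = 1.5),
  features = oximetry_config(psd_min_duration_s = 1800),
  seed = 11))
b$tally
#>     missing outcome              no OSA       central apnea CVD before landmark
#>                   0                   9                   0                   9
head(render_forest_table(b$associations)[, c("feature", "family", "label",
                                             "p_bh", "significant")], 6)
#>         feature       family            label    p_bh significant
#> 1           AHI   comparison 1.33 (0.90-1.96)      NA       FALSE
#> 2          ODI2 desaturation 1.43 (0.97-2.10) 0.07092       FALSE
#> 3          ODI3 desaturation 1.56 (1.07-2.28) 0.02681        TRUE
#> 4          ODI4 desaturation 1.83 (1.23-2.71) 0.00652        TRUE
#> 5          ODI5 desaturation 1.94 (1.30-2.89) 0.00610        TRUE
#> 6         SpO2SD time_series 1.95 (1.27-2.98) 0.00636        TRUE
```

The planted ODI4 effect is recovered (HR 1.83, CI excluding 1) and spills
into its correlated neighbours, while AHI — the comparison predictor,
excluded from the FDR families — is weaker; 18 of 120 simulated
participants are excluded by the inclusion filter, with the tally showing
why. Real CSV inputs run through the same path (`mode = "csv"`; formats
in `?pipeline_config`), and `inst/cli/oxipheno.R` is a thin command-line
wrapper (`simulate | run | extract | associate`).

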