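# p4valid

Analytical method validation for quantitative immunoassays, built around the
validation of an automated chemiluminescent progesterone (P4) assay in cattle
serum and heparinized plasma. The package is aimed at veterinary clinical
pathologists and assay developers who need to characterize an instrument
across its reportable range — here 0.2–40 ng/mL — and decide whether its
random and systematic error are fit for clinical use.

It implements the complete protocol as composable stages:

- **Precision profiling** — within-run (repeatability) CV% per spike level as
  the mean of per-day CVs, between-run (reproducibility) CV% as the CV of the
  daily means, and CV-vs-concentration trendlines
  (`CV% = b0 + b1·log10 c` or quadratic in `c`).
- **Spike and recovery** — `recovery% = 100·(measured − control)/spiked`,
  spiking-recovery bias `SRB% = recovery% − 100`.
- **Detection limits** — `LOB = blank mean + 1.65·SD`,
  `LOD = control mean + 1.65·SD`, `LOQ = level mean + 2·SD`, with SDs taken
  over the between-run series.
- **Reportable-range linearity** — OLS of measured on spiked concentration
  with CI-based constant/proportional bias flags and a paired-t deviation
  check.
- **Interlaboratory comparison** — Passing–Bablok regression (shifted-median
  slope over all pairwise slopes, rank-based CIs), Bland–Altman agreement in
  absolute and percent-difference modes with `LoA = bias ± 1.96·SD`, and
  concentration-binned range-based bias.
- **Observed total error** (Westgard): `TEo% = 2·CV% + |bias%|` in three
  variants according to the bias source — TEo_SR (spiking-recovery),
  TEo_RB (range-based, per concentration bin) and TEo_AB (average
  interlaboratory bias) — plus a QC-panel summary
  (`TEo = 2·between-run CV% + |bias vs nominal|`).
- **Synthetic data** — a generator for replicate spike panels, QC panels and
  paired two-laboratory datasets with multiplicative day effects,
  concentration-dependent CV and recovery, and reporting-limit censoring
  (`"<0.2"`), so the whole pipeline is testable without instrument data.

## Worked example

Simulate a 5-day × 5-replicate plasma spike panel under the default error
model (within-run `CV% = 8.9 − 1.7·log10 c`, `SRB% = −20.7 + 3.3·log10 c`,
0.3 ng/mL endogenous baseline, 5% day-to-day shifts), profile it, and
combine precision with the spiking-recovery bias into TEo:

```r
library(p4valid)
panel   <- resolve_censored(simulate_spike_panel(seed = 42))
profile <- precision_profile(panel)
profile
#> Precision profile (11 levels)
#>  level_id spiked mean_measured within_cv_pct between_cv_pct
#>        P0    0.0     0.2400609          11.5            6.5
#>        L1    0.4     0.5600200           7.8            9.2
#>        L3    1.0     1.0729142           8.4            4.0
#>        L5    5.0     4.4098930           6.0            5.7
#>       L10   30.0    26.0591931           5.9            3.2
#>  ...
#> overall within-run CV%:  6.9
#> overall between-run CV%: 4.7
#> trendline (linlog): CV% = 7.64, -1.16  (R2 = 0.68)

teo_sr_table(profile, recovery_result(panel))
#> Observed total error (SR bias)
#>  level_id spiked cv_pct bias_pct teo_sr
#>        L1    0.4    7.8    -20.0   35.7
#>        L3    1.0    8.4    -16.7   33.4
#>        L5    5.0    6.0    -16.6   28.7
#>       L10   30.0    5.9    -13.9   25.8
#>  ...
#> mean TEo: 30.5%
```

The imprecision and the recovery loss both worsen toward the low end of the
range, and each level's TEo tells you the total deviation (at roughly 95%
coverage of the random component) a single reported concentration may carry.

Interlaboratory agreement on a simulated 40-sample paired set:

```r
pairs <- simulate_paired_comparison(seed = 42)
passing_bablok(pairs)
#> Passing-Bablok regression (n = 40 pairs, 780 slopes, 0 excluded)
#>   slope:     1.116  [1.087, 1.152]  -> proportional bias present
#>   intercept: 0.032  [-0.083, 0.106] ng/mL  -> constant bias absent

bland_altman(pairs, mode = "percent")
#> Bland-Altman (percent differences, n = 40)
#>   mean bias: -12.49%  [-14.74, -10.25]
#>   LoA: -26.26% [-30.15, -22.37]  to  1.28% [-2.62, 5.17]
#>   LoA interval width: 27.54%
#>   proportional error slope: 0.106 (p = 0.425)
```

The slope CI excluding 1 flags the proportional disagreement that was built
into the simulation (laboratory B reads 9% high); the intercept CI containing
0 reports the absence of constant bias.

`run_validation(validation_config(seed = 42, out_dir = "out"))` executes all
stages in order and writes the classic one-row-per-level report
(spiked, mean measured, within-run CV%, SRB%, RB%, AB%, TEo_SR, TEo_RB,
TEo_AB; round-half-to-even to one decimal) plus a JSON bundle of every
fitted object.

The package also bundles the published per-level summary of the plasma
validation this design comes from (`reference_plasma_summary()`), together
with its interlaboratory/QC headline values (`reference_interlab_qc()`), so
the total-error arithmetic can be re-run against printed values.

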