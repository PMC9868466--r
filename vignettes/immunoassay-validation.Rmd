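---
title: "Validating a quantitative immunoassay: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a quantitative immunoassay: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p4valid)
```

# The problem

Progesterone concentration ([P4]) in cattle serum or plasma drives routine
reproductive decisions — luteal activity around 1 ng/mL, pregnancy
maintenance, timing of parturition — so a laboratory adopting an automated
immunoassay must know how wrong a single reported number can be across the
instrument's reportable range (0.2–40 ng/mL for the system this package was
designed around). The validation protocol implemented here combines three
complementary phases:

1. a **spiking-recovery phase**: a pooled low-[P4] matrix is spiked to a
   ladder of known concentrations and measured in five replicates on five
   consecutive days, giving precision, recovery, linearity and detection
   limits;
2. an **interlaboratory comparison**: the same ~40 field samples measured by
   two laboratories running the same platform, analysed by Passing–Bablok
   regression and Bland–Altman agreement;
3. a **total-error phase** combining the imprecision with each available
   bias estimate into the observed total error.

# Statistical model and estimators

## Precision

For level $l$ with replicates $y_{ldr}$ on day $d$, the within-run CV is

$$\mathrm{CV}_{l}^{within} = \frac{1}{D}\sum_d 100\,
  \frac{s(y_{ld\cdot})}{\bar y_{ld\cdot}},$$

the unweighted mean over days of the per-day CV (sample SD, $n-1$
denominator). The between-run CV is the CV of the daily means
$\bar y_{ld\cdot}$. Both are scale invariant. The overall CVs of a panel are
unweighted means of the per-level CVs over the spiked levels, matching the
convention of quoting a single "overall imprecision" for a panel.

Two readings of the repeatability design exist: day-1 only, or all days
averaged. The package averages over all days by default — it uses all the
data and is the interpretation consistent with quoting one within-run CV per
level from a multi-day design — and exposes a `days =` filter that
reproduces the day-1-only reading exactly.

CV-vs-concentration trendlines are ordinary least squares in either the
log-linear form $\mathrm{CV\%} = b_0 + b_1 \log_{10} c$ (the usual
immunoassay shape: imprecision rises as concentration falls) or a quadratic
in $c$. These are descriptive fits; no weighting is applied.

## Recovery and spiking-recovery bias

$$\mathrm{recovery\%} = 100\,\frac{\bar y_l - \bar y_0}{\text{spiked}_l},
\qquad \mathrm{SRB\%} = \mathrm{recovery\%} - 100 .$$

The control mean $\bar y_0$ is the grand mean of the unspiked matrix over
all days (after censoring resolution): the protocol subtracts a single
baseline value rather than per-day baselines, and pooling all 25 control
readings is the lowest-variance version of that.

## Detection limits

The protocol uses the classical mean-plus-multiplier forms:
$\mathrm{LOB} = \bar y_{blank} + 1.65\,s$,
$\mathrm{LOD} = \bar y_{0} + 1.65\,s$, and per candidate level
$\mathrm{LOQ} = \bar y_l + 2\,s$, each SD taken over the between-run series
(one value per run). The multipliers 1.65 and 2 are the protocol's stated
constants, not percentile machinery from a full limit-of-detection study;
the LOQ form in particular is a protocol convention (quoted together with
the level's between-run CV) rather than the textbook
"lowest concentration meeting a CV target" definition, and is implemented
as stated.

## Linearity

OLS of the level means on the spiked concentrations, with two-sided t-tests
and 95% CIs. Bias is flagged from the intervals: constant bias when the
intercept CI excludes 0, proportional bias when the slope CI excludes 1 —
the CI-versus-1 rule is the defensible reading for proportionality (a test
of slope = 0 says nothing about departure from the identity). Since
calibration plots appear in both orientations, the reverse fit (spiked on
measured) is reported alongside. A paired t-test of the per-level deviations
(measured − spiked) against zero is reported as a rough global deviation
check, without an interpretive label: with only a handful of levels it
conflates bias with lack of fit.

On an exactly linear input the residual variance is zero and the t
machinery degenerates; the fit then reports point confidence intervals,
`NA` p-values, $R^2 = 1$, and decides the flags by comparing the
coefficients to 0 and 1 with a numerical tolerance.

## Passing–Bablok regression

All pairwise slopes $S_{ij} = (y_j - y_i)/(x_j - x_i)$, $i<j$, are formed;
slopes undefined by $x_i = x_j$ and slopes exactly $-1$ are excluded (the
standard convention making the estimator invariant under axis swap). With
$K$ the count of remaining slopes below $-1$, the slope estimate is the
order statistic of the sorted slopes at the median rank shifted by $K$
(mean of the two middle shifted entries for an even count). CI bounds sit
at ranks $M_1 = \mathrm{round}\left((N - w)/2\right)$ and
$M_2 = N - M_1 + 1$, shifted by $K$, with
$w = z_{1-\alpha/2}\sqrt{n(n-1)(2n+5)/18}$. Rank rounding conventions
differ between implementations; this one rounds $M_1$ half-up, and that
choice is stated here because it moves the CI bounds by one order statistic
either way at small $n$. The intercept is $\mathrm{median}(y - b\,x)$ with
CI endpoints evaluated at the slope bounds. At $n \lesssim 5$ the CI ranks
fall outside the slope list: the fit then errors advising a larger n, or
returns point estimates only under `conf = FALSE`.

The regression direction is `value_b` (y) on `value_a` (x). Proportional
bias is flagged when the slope CI excludes 1, constant bias when the
intercept CI excludes 0.

## Bland–Altman agreement

Differences are `value_a − value_b` (laboratory A is always the minuend),
either absolute or as a percentage of the pair mean — the pair mean, not
one laboratory's value, is the denominator, since neither laboratory is
error-free. Limits of agreement use the fixed 1.96 factor of the protocol's
formula, while the CIs around the mean bias ($\pm t\,s/\sqrt n$) and around
each limit ($\pm t\,s\sqrt{3/n}$) use t quantiles: a deliberately mixed
convention that reproduces the classical "bias ± 1.96 SD" limits yet gives
finite-sample interval estimates. Proportional error is assessed by OLS of
the differences on the pair means.

## Range-based bias and the observed total error

The paired samples, sorted by pair mean, are split into contiguous bins of
as-equal-as-possible size (larger bins first; ties broken by sample id), a
partition chosen over the published overlapping group ranges because those
ranges cannot coexist with a partition. Each bin's range-based bias is the
mean percentage difference of its members.

The observed total error is
$$\mathrm{TEo\%} = 2\,\mathrm{CV\%} + |\mathrm{bias\%}|$$
in three variants: TEo\_SR pairs each level's within-run CV with its SRB;
TEo\_RB takes the bias of the concentration bin whose pair-mean range
contains the level's spiked value (nearest bin midpoint when none does —
the containment-else-nearest rule reproduces the level-to-group
correspondence of the reference report); TEo\_AB applies the single overall
Bland–Altman percentage bias uniformly at every level, which is what the
formula defines. Bias signs are preserved in every table — directional
reporting matters for interpretation — and the absolute value is taken only
inside the TEo formula. The QC summary combines the **between-run** CV with
the bias against the nominal target; the between-run CV is the relevant
imprecision for material measured across runs, and is the convention that
reproduces the reference QC total-error values.

# The synthetic-data generator

No raw instrument data are distributed with the protocol, so the generator
stands in for the instrument. A measurement is

$$y_{ldr} = \tau_l \cdot \delta_d \cdot (1 + \varepsilon_{ldr}),$$

with truth $\tau_l = (\beta + \text{spiked}_l)\,R(\beta + \text{spiked}_l)$
for baseline $\beta$ and recovery factor $R$, day effect $\delta_d$
lognormal with mean 1 and relative SD `sd_between_day` (one draw per day,
shared by all levels — a run-level calibration shift, which is what a
between-run CV computed on daily means estimates), and
$\varepsilon \sim N(0, (\mathrm{CV}(\tau_l)/100)^2)$. Noise is
multiplicative throughout because the assay's dispersion is parameterized
as CV%; additive noise would make the CV fall with concentration faster
than observed. Values outside the reporting limits are emitted censored
(`"<0.2"` / `">40"`), as the instrument reports them.

Defaults are the fitted plasma characteristics of the reference assay:
within-run $\mathrm{CV\%} = 8.9 - 1.7\log_{10} c$ (floored at 0.5%),
$\mathrm{SRB\%} = -20.7 + 3.3\log_{10} c$ (so
$R(c) = 1 + \mathrm{SRB}(c)/100$), baseline 0.3 ng/mL, reporting range
0.2–40 ng/mL, and a 5 × 5 day-by-replicate design. The published equations
are labeled "power function" trendlines but are written — and implemented —
as linear in $\log_{10}$. The day-effect SD is not separately published;
5% is used, chosen so that the implied between-run CV
($\sqrt{\sigma_{day}^2 + \mathrm{CV}_{within}^2/5}$ on daily means of five
replicates) lands in the reported 3–9% between-run band, and it is fixed,
not tuned.

The paired-comparison generator draws truths log-uniformly over
0.3–28 ng/mL (field samples for a comparison are deliberately chosen to
span the physiological decades), with
`value_a = truth (1 + e_a)` and `value_b = (0.05 + 1.09·truth)(1 + e_b)` at
5% analytical CV per laboratory. Note the sign consequence: laboratory B is
the one reading high, so the simulated Bland–Altman bias (A − B) is
*negative* with the default model, around −10%; the magnitude, not the
sign, mirrors a typical interlaboratory offset. The QC generator applies
the day-effect and CV machinery directly to the nominal targets (QC
material is value-assigned; no matrix baseline or recovery loss).

What the generator deliberately does not model: antibody cross-reactivity,
hemolysis/lipemia interference, carry-over, calibration drift within a
lot, or heteroscedastic day effects. Passing tests therefore demonstrate
that the estimators recover the statistical structure they assume — not
that a particular physical instrument meets specification.

# Censoring

Readings below the calibrated range arrive as `"<0.2"`. Before averaging,
`resolve_censored()` applies one of three policies: substitute the limit
(default — conservative for a below-limit value, and consistent with
quoting an undetectable matrix as "about 0.2"), substitute half the limit
(the common censored-data convention), or drop the rows (with a warning if
a level-day cell empties). The protocol's own pooling rule for below-limit
day means is not stated anywhere, so the policy is explicit and
configurable rather than silently guessed; the default is recorded in the
table's metadata and in the report.

# Numerical conventions

- Sample SD ($n-1$) everywhere; the protocol does not state a denominator
  and the replicate counts are small.
- Report rounding is round-half-to-even at one decimal (base R `round()`),
  matching one-decimal summary-table presentation.
- Concentrations are ng/mL throughout; negative input concentrations are
  rejected, never clamped.
- All simulation randomness flows from one integer seed per object; the
  pipeline derives its pair/QC seeds as seed + 1, seed + 2, and two runs
  with the same configuration produce byte-identical reports.
- Degenerate inputs (zero-variance days, empty cells, all-equal x in a
  regression, zero pair means in percent mode) raise errors naming the
  offending level or sample rather than propagating NaN.

# Problem sizes used in the test suite

The Monte-Carlo checks run at the design's own scale: 200 simulated 5 × 5
panels for the CV/SRB recovery checks (estimator means within 1.5
percentage points of the injected curves at every level), 500 simulated
40-pair comparisons for the Passing–Bablok slope (median within 0.03 of
the injected 1.09), 500 random small datasets for the exact
enumeration-equivalence check of the Passing–Bablok slope, and 500
two-level panels for the between-day variance recovery. These sizes keep
each estimator's Monte-Carlo standard error well under the tolerance it is
tested against.

# Known limitations

- The within-run CV estimator averages per-day CVs; for five replicates the
  sample SD underestimates $\sigma$ by the $c_4(5) \approx 0.94$ factor, so
  recovered CVs sit ~6% (relative) below the injected curve. This is a
  property of the classical estimator, shared with the protocol itself, and
  stays well inside the Monte-Carlo tolerances.
- Passing–Bablok CIs are the analytic rank intervals; no bootstrap
  alternative is provided.
- No outlier rejection anywhere (the protocol applies none), no Deming
  regression, no CLSI EP6 lack-of-fit testing, no allowable-total-error
  (TEa) verdicts: TEa for veterinary endocrinology has no accepted value,
  so TEo is reported for the reader to compare against whatever TEa their
  setting adopts.
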