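---
title: "Peptide-level mixed-model differential abundance and targeted lipidomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide-level mixed-model differential abundance and targeted lipidomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oslfq)
```

## Scope

`oslfq` implements the quantitative core of a label-free proteomics and
targeted lipidomics study of photoreceptor outer segments (OS): two
differential-abundance procedures for protein intensities (a peptide-level
mixed-effects model for enriched OS samples, and a protein-level
pooled-variance t-test for whole-eye lysates), a missingness-aware pseudo
fold-change rule for features undetected in one genotype, two
false-discovery-rate procedures, internal-standard lipid quantification
with dilution-series quality control, and a synthetic-data generator with
known ground truth that makes the whole pipeline testable end to end
without any external data.

## The peptide-level model

The OS analysis works on the peptide report of a label-free search engine
(MaxQuant `peptides.txt` dialect). Intensities of zero mean "not
detected" and are removed; the remaining intensities are log2 transformed
and normalized per sample with a robust z-score,

$$ z_{is} = \frac{x_{is} - \mathrm{median}_s}{1.4826 \cdot \mathrm{MAD}_s}, $$

where the 1.4826 factor makes the MAD a consistent estimator of a
Gaussian standard deviation. We interpret the "modified" robust z-score
as the rescaled variant, which maps the z-scores back onto a pooled
log2-intensity scale (`z * mean(1.4826 MAD_s) + mean(median_s)`). The
rescaling matters because the pseudo fold-change imputation below uses
"smallest intensities", which is only meaningful on an intensity-like
scale.

For each protein, normalized intensities are modelled with a linear mixed
model with a random intercept per peptide,

$$ y_{ijs} = \mu + \beta \cdot \mathrm{mutant}_s + b_j + \varepsilon_{ijs},
   \qquad b_j \sim N(0, \sigma^2_{pep}),\
   \varepsilon \sim N(0, \sigma^2_e), $$

fitted by REML (`lmerTest::lmer`), with Satterthwaite denominator degrees
of freedom for the two-sided t-test on the genotype contrast. When a
second design factor is supplied (e.g. genetic background), the fixed
part is the full factorial of the factors; non-contrast factors are coded
sum-to-zero so the reported contrast is the marginal mutant-minus-control
effect. For a balanced complete design the estimate reduces exactly to
the difference of condition means, which is one of the strongest
regression tests in the suite.

Degenerate fits degrade deterministically: a protein with a single
peptide, or a singular fit (peptide variance estimated at zero), is refit
by ordinary least squares on the same fixed effects with residual degrees
of freedom, flagged `method = "ols"` in the results. A protein with fewer
observations than fixed-effect parameters is skipped with a logged
reason. Every input protein therefore appears either in the results or in
the skip log.

### Pseudo fold changes

Proteins with no observations in one condition cannot be modelled. For
these, the per-peptide mean intensity per condition is first computed
dataset-wide; the missing condition's peptide intensity is imputed as the
mean of the `ceiling(0.1 N)` smallest per-peptide condition means in that
condition (at least one); per-peptide log2 fold changes (oriented mutant
minus control) are then summarized by their median. No p-value is
attached to these estimates, and the Benjamini-Hochberg family contains
only model-based p-values. The protein-level variant replaces the missing
group average by the mean of the 10% smallest per-protein condition means
in that condition. Both variants rest on the left-censoring premise:
undetected usually means low-abundance.

## The protein-level (whole-eye) procedure

Whole-eye lysates are analysed on pre-aggregated protein intensities:
proteins need at least 2 peptides and at most 4 missing values across the
8 samples; intensities are log2 transformed, normalized with the same
rescaled robust z-score, and tested per protein with the classical
pooled-variance t-test. Proteins fully missing in one condition again
receive a pseudo fold change. For targeted comparisons of a protein set
(e.g. all BBSome subunits), `summed_lfq_compare()` sums each protein's
normalized peptide intensities per sample (undetected peptides contribute
zero; the normalized log2 values are mapped back to the linear scale
before summing, so the sums are detected signal on a common intensity
scale), tests each protein with an independent pooled t, and controls the
FDR over the comparisons with the two-stage step-up procedure at Q = 1%.
Complete absence in one condition is reported explicitly, mirroring the
"#" annotation of the study's bar plots.

## Multiple testing

Two procedures are exposed. `bh_adjust()` is the Benjamini-Hochberg
step-up (delegating to `stats::p.adjust`); `bky_two_stage()` is the
adaptive Benjamini-Krieger-Yekutieli two-stage step-up: a first BH pass
at `q/(1+q)` estimates the number of true nulls `m0 = m - r1`, and a
second BH pass at `q/(1+q) * m/m0` declares discoveries, with the
boundary branches (no stage-1 rejections: nothing; all rejected:
everything) handled explicitly. Volcano categories follow the study's
convention: significant-and-large (`adj_p < 0.05` and linear fold change
beyond 2, i.e. `|log2 FC| >= 1`), significant-small, large-only, and
non-significant; the significance cut is strict (`<`), the fold-change
cut inclusive (`>=`). Estimates without a p-value (pseudo fold changes)
are classified on fold change alone and flagged.

## Targeted lipidomics

Each lipid species is quantified as the ratio of its peak area to the
area of its assigned internal standard in the same sample, which cancels
per-sample injection and instrument-response factors exactly. The QC
dilution series (pooled samples at 1x, 0.8x, 0.5x, 0.2x, 0.1x, each in
triplicate) yields a CV% per lipid and level (`100 * sd/mean`, n-1
standard deviation); a lipid is reported when its CV% at the decision
level is below 30. The default decision level is the undiluted (1x) QC,
with an option to require all five levels. The triplicate CV estimate at
a single level is itself noisy: for a lipid with a true CV of 50% the
probability of estimating below 30% from three replicates is about 0.3
(chi-square tail), so reliable removal of noisy lipids needs the
all-levels rule; the single-level default mirrors the reporting
convention of the study, not a detection guarantee.

Ratios are then median-normalized per sample (division by the sample's
median positive ratio, on the linear scale) and compared per lipid with a
pooled-variance t-test on log2 ratios, zeros treated as missing. The
`significant` flag follows the study's volcano convention on the raw
p-value (`p < 0.05` and `|log2 FC| >= 1`); BH-adjusted values are
reported alongside.

## The synthetic-data generator

`peptide_truth()` / `simulate_peptide_dataset()` emulate the structure
the peptide-level model assumes: per-protein baseline log2 abundances
(`N(25, 2)` in arbitrary LFQ log2 units), per-peptide random intercepts
(sd 0.5), residual noise (sd 0.3), per-sample affine distortions, and
intensity-dependent left-censored missingness
(`P(missing | x) = 1/(1 + exp((x - 23.2)/0.5))`, chosen analytically to
censor roughly 20% of records under the defaults) plus an optional MCAR
component and designated fully-missing protein sets. Default dimensions
mirror the study: 300 proteins with 3-10 peptides, 4 vs 4 samples; the
non-null fraction (0.2) draws log2 effects from ±{1, 2}. The lipid
generator (`lipid_truth()` / `simulate_lipid_panel()`) produces
internal standards shared per class, per-sample injection scale factors,
lognormal biological noise, and the full five-level QC triplicate design;
default sample sizes are 15 control vs 13 mutant. All draws derive from
one integer seed (default 20220311); a single RNG stream per call keeps
regeneration bit-identical.

What the generator does *not* emulate: peptide-specific ionization
efficiencies with heavy-tailed distributions, correlated missingness
within runs, shared peptides between protein groups, retention-time
drift, and interference. Passing recovery tests on this generator
therefore validates the estimation machinery under the model's own
assumptions, not robustness to all features of real data.

## Calibration properties and known limitations

Three empirical properties shape how the test suite is organized.

*Normalization interacts with censoring.* When per-sample distortions and
left-censoring act together, the per-sample median/MAD are computed from
differentially truncated data, leaving residual sample-level offsets that
the peptide-level model (which has no sample random effect) cannot
absorb. In single null datasets this can inflate the fraction of raw
p < 0.05 several-fold. Even censoring alone distorts the extreme tail of
the null distribution through selection on the residuals. The type-I and
FDR calibration checks therefore run on the pure-noise null (no
missingness, no distortions), which isolates the calibration of the test
statistic itself; parameter-recovery checks keep the censoring.

*Normalization leaks real effects at small panel sizes.* The per-sample
median and MAD are estimated from the features themselves. When a
substantial fraction of features carries real group differences (the
default generator draws 20% non-null), the mutant samples' location and
scale estimates absorb part of those effects, and the correction leaks a
group-differential shift into every feature. With only a few hundred
features this inflates the realized false-discovery proportion well
above the nominal level (we measure mean FDP ≈ 0.35 at 500 features,
20% non-null). The effect shrinks with feature count and effect
sparsity, so datasets with thousands of proteins and few strong changes
are much less affected — but it is a real property of
normalize-then-test pipelines worth knowing when interpreting results on
small targeted panels.

*Full-null false-discovery proportion is tail-sensitive.* On a complete
null, the per-dataset false-discovery proportion equals the indicator of
any rejection, so its average estimates the probability that the
smallest p-value survives the step-up — a quantity far more sensitive to
slight miscalibration of the extreme tail (Satterthwaite approximation,
the post-hoc selection implicit in the singular-fit fallback) than the
bulk uniformity that a Kolmogorov-Smirnov test checks.

*A power criterion at the threshold is a coin flip.* A detection rule
that requires the estimated `|log2 FC| >= 1` has probability near 0.5 of
flagging a lipid whose true log2 fold change is exactly 1, however many
samples are measured, because the estimate is continuous and centred at
the threshold (median normalization with a finite panel additionally
shrinks it slightly). Detection power in the p-value sense is essentially
1 at the study's sample sizes (15 vs 13, CV 10%); the compound flag is
not a power statement at that effect size. The test suite keeps the
compound-flag check in its literal form, and the acceptance script
reports the p-only detection rate alongside it.

## Numerical and design choices

- MAD scaling uses 1.4826 throughout (`stats::mad` default).
- A constant sample (zero MAD) is a hard error naming the sample, not a
  silent degenerate normalization.
- Imputation pool counts use `ceiling(0.1 N)` with a minimum of one.
- Contrast direction is mutant over control everywhere; signed linear
  fold changes are `2^lfc` for increases and `-2^|lfc|` for decreases, so
  their magnitude is always at least 1.
- Pooled-variance t with zero pooled variance resolves to `t = 0, p = 1`
  for equal means and `p = 0` with a degeneracy flag otherwise.
- The two-stage procedure's per-test q-values are the adaptive BH values
  (`adj_p * m0_hat/m`) when stage 2 is reached, consistent with its
  discovery threshold.
- Peptide-to-protein mapping keeps the full semicolon-joined accession
  group string as the protein identifier; no razor-protein resolution is
  attempted, and shared peptides across groups are a hard error at read
  time.
- Reported problem sizes in the test suite: recovery at 300 proteins
  (one run), type-I at 200, false-discovery proportion at 500 proteins
  over 20 replicates, two-stage FDR on 50 uniform vectors of length
  1000, lipid power over 200 replicates. These sizes keep each property
  estimable with usefully small Monte-Carlo error.

## Worked example

```{r example, eval = FALSE}
tr <- peptide_truth(n_absent_mutant = 5, seed = 20220311)
sim <- simulate_peptide_dataset(tr)          # 4 control vs 4 mutant
fit <- run_os_da(sim$peptides, sim$annotation)
fit
summary(fit)
plot(fit)                                    # volcano
write_results(fit, "os_results.tsv")
```
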