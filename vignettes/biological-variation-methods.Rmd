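---
title: "Methods: biological variation, reference intervals, and partition analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biological variation, reference intervals, and partition analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chelonRI)
```

# The model

A blood analyte measured repeatedly in a population of animals is modeled
with two nested levels of variation. Animal $a$ carries a latent setpoint
$\mu_a$ drawn around the population mean $\mu$ with between-animal SD
$\sigma_b$; each sample from that animal scatters around $\mu_a$ with
within-animal SD $\sigma_w$. Everything downstream follows from the ratio of
these two spreads:

* When $\sigma_b$ dominates, individual setpoints are far apart and a
  population reference interval (the central 95% range in healthy animals)
  carries little information about any one animal. The **index of
  individuality** $I = CV_I / CV_G$ (with $CV_I = \sigma_w/\bar{x}$,
  $CV_G = \sigma_b/\bar{x}$) quantifies this; below the conventional 0.6
  threshold, interpretation switches to subject-based: compare the animal
  against its own history, using the **reference change value**
  $RCV = 1.96\sqrt{2}\sqrt{CV_A^2 + CV_I^2}$ as the smallest serial change
  distinguishable from within-animal plus analytical noise at 95%
  confidence.
* Otherwise, a **population reference interval** is computed by the
  parametric method, $\bar{x} \pm 1.96 s$, with each bound's sampling
  uncertainty summarized by a 90% percentile-bootstrap confidence interval.

## Variance-component estimation

The design is unbalanced (animals contribute 2–6 samples), so the components
come from the one-way random-effects method of moments restricted to animals
with at least two usable samples: singletons carry no information about
$\sigma_w$ and are excluded from CV estimation (they still contribute to
reference intervals and partition analyses). With $k$ animals, $n_a$ samples
each, $N = \sum n_a$:

$$s_w^2 = \frac{\sum_a \sum_j (x_{aj} - \bar{x}_a)^2}{\sum_a (n_a - 1)},
\qquad
s_b^2 = \max\!\left(0, \frac{MS_{between} - s_w^2}{n_0}\right),
\qquad
n_0 = \frac{N - \sum_a n_a^2 / N}{k - 1}.$$

A negative moment estimate of $s_b^2$ is truncated to zero (reported
$CV_G = 0$, with the index then undefined and the analyte typed subject-based
with a warning). On a balanced design this reduces exactly to the closed-form
one-way ANOVA decomposition, which is how the implementation is
oracle-checked. CVs are computed on the raw measurement scale from the grand
mean of the repeat-sampled subset; no month/year adjustment is applied before
decomposition.

## Two index formulas, two RCV formulas

Published biological-variation tables are not always internally consistent
about whether the analytical CV enters the index and the RCV. Both variants
of each quantity are therefore computed and reported side by side:

* `index_without_cva` $= CV_I/CV_G$ and `index_with_cva`
  $= (CV_I + CV_A)/CV_G$. The RI-type decision defaults to the without-CVa
  form (the form that printed subject/population decisions in the source
  tables actually follow), switchable via `index_variant`.
* `rcv_stated` $= 1.96\sqrt{2}\,CV_I$ and `rcv_combined`
  $= 1.96\sqrt{2}\sqrt{CV_A^2 + CV_I^2}$ (equal when no $CV_A$ exists).
  The combined form is the headline value.

An index exactly at the 0.6 threshold is typed population-based: the decision
rule in the literature covers only strictly-less and strictly-greater, and
the population RI is the more general object to fall back to.

# Screening

Three gates precede interval construction, in this order: (1) whole-sample
exclusion on physical-exam and sample-quality flags; (2) one pass of
per-analyte outlier flagging; (3) per-analyte Shapiro-Wilk normality
classification on the retained values. Screening before normality assessment
is a deliberate ordering choice — a gross outlier should not drive the
distribution call — and only a single outlier pass is made, since iterated
trimming on clean data keeps eating the tails.

The default outlier method is Horn's: estimate the maximum-likelihood Box-Cox
exponent $\lambda$ (values first shifted to be strictly positive by
$-\min(x) + 0.001\,\mathrm{range}(x)$ when needed), transform, and flag
values outside $[Q_1 - 1.5\,IQR,\; Q_3 + 1.5\,IQR]$. Raw-scale Tukey fences
and "no screening" are selectable. Fewer than 20 values skip detection with a
warning; a zero IQR flags nothing. On null standard-normal data (n = 10⁴) the
method flags well under 2% of points.

Normality is decided by Shapiro-Wilk at $\alpha = 0.05$; sample skewness and
excess kurtosis are reported as diagnostics but never override the test,
since no numeric thresholds for them are standard. Constant vectors are
classified non-normal with a warning rather than erroring the pipeline.

# Reference intervals

* **Parametric** (normal-called analytes): $\bar{x} \pm 1.96 s$. Lower
  bounds below zero for physically nonnegative analytes are clamped to 0 and
  flagged; clamping can never invert the bounds.
* **Box-Cox parametric** (default for non-normal population analytes): ML
  $\lambda$, mean ± 1.96 SD on the transformed scale, bounds back-transformed
  (a bound outside the image of the transform back-transforms to 0 or
  $\infty$ rather than erroring). Printed intervals for skewed analytes are
  asymmetric about the mean in a way raw $\bar{x} \pm 1.96s$ cannot produce,
  which is why a transform is the default; raw parametric and nonparametric
  (2.5th/97.5th percentiles, type-7 interpolation) are selectable.
* **Bootstrap bound CIs**: percentile method, resampling the n values with
  replacement, B = 1000 by default, 90% level, fully seeded. B and the
  bootstrap variant are not dictated by guideline text; the percentile
  method is the simplest defensible default and B = 1000 makes the CI
  endpoints stable to well under the display rounding.

Guideline sample-size minima (n ≥ 40 parametric, n ≥ 120 nonparametric) are
warnings, not errors: subgroup-limited analytes still get intervals, flagged.

The Box-Cox exponent is found by maximizing the closed-form profile
log-likelihood $-\tfrac{n}{2}\log \widehat{\sigma}^2(\lambda) +
(\lambda - 1)\sum \log x_i$ with one-dimensional `optimize()` on
$[-3, 3]$; it agrees with the grid-search implementation in MASS to the
grid's resolution (cross-checked in the test suite).

# Partition analysis

Per-factor summaries follow the field's reporting convention: each level
reports its mean with a t-based 95% CI when the level's own values pass
Shapiro-Wilk, otherwise its median with 10th/90th percentiles, plus min and
max always. Levels with fewer than two usable samples are dropped with a
warning — this is what removes a single-sample month from monthly
comparisons while keeping it in the dataset.

Test dispatch is a pure function of the per-level normality calls: all
levels normal → t-test (two levels, Welch) or one-way ANOVA; otherwise
Mann-Whitney U or Kruskal-Wallis. A significant omnibus on a factor with
more than two levels triggers all pairwise two-sample tests of the matching
kind. For sex, pairwise reporting is restricted to female vs male; the
"unknown" level stays in the omnibus test but a pairwise contrast against an
indeterminate category is not meaningful. Raw p-values are reported without
multiple-testing correction, matching standard practice in this literature;
a Holm option exists on the comparison output for users who want it.

Model selection fits OLS candidates (reference-level dummy coding; aliased
columns dropped with a warning) and ranks by small-sample AIC,

$$AICc = n \ln(RSS/n) + 2k + \frac{2k(k+1)}{n - k - 1},$$

with $k$ = estimated coefficients + 1 for the residual variance, plus Akaike
weights. The default candidate set is every main-effect subset of
{age class, sex, month, year, site} plus the global model with all two-way
interactions; higher-order interactions are excluded on degrees-of-freedom
grounds. Candidates with $n - k - 1 \le 0$, or that fail to fit (e.g. a
factor collapsing to one level in a small subset), are skipped with a
warning.

Repeat samples from the same animal would pseudo-replicate a fixed-effects
model, so modeling defaults to the first chronological sample per animal
(`dedup = "first"`); using all samples is available as `dedup = "all"`. A
linear mixed model with animal as a random effect would be the fuller
treatment of repeat-sampled subject-type analytes; that is deliberately out
of scope here, and the de-duplicated GLM is the documented default path.

# The synthetic-data generator

`default_study_config()` encodes the study conditions the pipeline is
validated under: 157 animals sampled once plus 70 sampled repeatedly
(25×2, 17×3, 12×4, 9×5, 7×6 — 393 samples from 227 animals), two sites
(57%/43%), three sexes (65/26/9%), three age classes (68/22/10%), months
allocated exactly as 134 May / 160 June / 98 July / 1 August, years
59%/41%. Site, sex, age class and year are constant within animal; month
varies per sample. Analyte means and spreads come from the published panel
summary (`reference_summary()`); per-analyte missingness reproduces the
published per-analyte N.

Choices the source data do not determine, made once:

* **Distribution families.** Normal-called analytes (PCV, TS, H:L, calcium)
  simulate as Gaussian (truncated at 0 where physically required); the rest
  as log-normal, with log-scale spreads chosen so the raw-scale mean and
  raw-scale between/within SDs match the configured values. No claim is made
  that the animals' true distributions are log-normal; it is a modeling
  choice for right-skewed analytes.
* **Between/within split for population-typed analytes.** The source tables
  print only a total SD for them, so the generator splits it
  $\sigma_w^2 = 0.6\,\sigma^2$, $\sigma_b^2 = 0.4\,\sigma^2$, putting the
  implied index at $\sqrt{0.6/0.4} \approx 1.22 > 0.6$ — consistent with
  their published population-based typing.
* **Group effects** are additive on the draw scale (raw for Gaussian, log
  for log-normal): a vitellogenesis-like calcium elevation in adults and
  females, site shifts in PCV and AST, a seasonal eosinophil rise, and a
  spring phosphorus dip. Interactions are deliberately absent so model
  selection can be checked for *not* finding them.
* **Censoring.** Values below an analyte's quantitation floor (uric acid,
  0.8 mg/dl) are reported at the floor, exactly as the analyzer reports
  them — left-censoring, not truncation.

What the generator does **not** emulate: lymph hemodilution artifacts,
assay drift, clinically abnormal animals, animal-specific seasonal
trajectories, or any dependence between analytes. Passing tests on this
synthetic data therefore validate the *inference machinery* — estimator
correctness, decision routing, coverage, error rates, determinism — not the
biological fidelity of any particular turtle population.

## Validation experiments and problem sizes

The test suite runs these study-condition experiments (all seeded):

* **Parameter recovery**: 70 animals × 3 samples, Gaussian, AST-like truth
  (mean 64.7, $CV_I$ 33%, $CV_G$ 56%), 20 replicates; median relative error
  of both CVs must be ≤ 15%. Truncation at zero is disabled in this
  experiment so the configured $\sigma$'s are exactly the truth being
  recovered (with truncation, several percent of the Gaussian mass would be
  folded at 0 and the generating values would no longer be the estimand).
* **RI coverage**: parametric intervals on Gaussian samples of n = 400, 50
  replicates, each checked against 10⁵ fresh draws; mean coverage within
  95% ± 1%.
* **Type-I error**: the dispatched omnibus comparison on three null Gaussian
  groups of 30, 200 replicates; rejection rate must fall in [2%, 9%] at
  $\alpha = 0.05$.
* **Bootstrap CI behavior**: 50 Gaussian replicates of n = 400 at B = 200;
  each bound's 90% CI must contain the true quantile bound in ≥ 85% of
  replicates.
* **Determinism**: two pipeline runs with identical config and seed must be
  byte-identical across all seven output files.

A known limitation worth stating: the raw-scale moment estimator applied to
log-normal repeated measures is biased upward for $CV_I$ (the pooled
within-animal variance averages over animals whose conditional variances
scale with their squared setpoints), so on the default synthetic panel the
skewed analytes' estimated indexes drift above their configured raw-CV
ratios, and fewer analytes come out subject-typed than their generating
parameters alone would suggest. The estimator is the standard raw-scale
procedure; the bias is a property of applying it to multiplicative data and
is shared by the field's common practice. The recovery guarantees above are
stated, and tested, for the Gaussian model the estimator matches.
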