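---
title: "Methods: validating a story-recall screen for MCI and dementia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating a story-recall screen for MCI and dementia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsrscreen)
```

## The problem

A story-recall test probes verbal episodic memory: a short story of 28
idea units is read aloud, recalled immediately (ISR) and again after a
20–30 minute delay (DSR), each idea credited 2 points for accurate
recall, 1 for partial recall, 0 otherwise, so totals range 0–56.
Delayed recall is among the earliest and steepest casualties of
Alzheimer-type pathology, which makes the DSR attractive as a screen for
mild cognitive impairment (MCI) in memory clinics. But a raw total is
not an instrument: it needs norms (what is normal for a 78-year-old with
five years of schooling?), cutoffs (below what score should we worry?),
and calibrated post-test probabilities (what does a positive screen mean
at 10% community prevalence versus 50% clinic prevalence?). This package
implements that full validation chain, together with a synthetic cohort
generator so every stage can be exercised, tested and reproduced without
patient data.

## Operational classification

Screening cohorts are labelled by scale-based gates alone:

* **NC** (normal cognition): global CDR 0, preserved daily living
  (ADL < 16), MMSE above an education-adjusted threshold — strictly
  greater than 26 (higher education), 23 (middle school), 22 (primary
  school) or 19 (illiterate), the convention validated for Chinese
  populations where schooling strongly shifts MMSE scores.
* **MCI**: CDR global 0.5 with memory-domain 0.5, normal-range MMSE,
  ADL < 16, HAMD-17 ≤ 12 (no clinically relevant depression) and
  HIS ≤ 4 (no vascular pattern).
* **AD-candidate**: MMSE at or below the education threshold, CDR ≥ 0.5,
  ADL ≥ 16, HIS ≤ 4, HAMD-17 ≤ 12.

Everything else is `excluded`, with a reason from a fixed gate order —
depression, then vascular, then the residual cognitive/functional
profile. The order is a package convention: the source criteria list
the gates without prioritising them, and a deterministic order makes the
excluded-reason reproducible. We deliberately label the dementia arm
*AD-candidate*: a true AD diagnosis additionally requires imaging and
clinical judgment that no score table can encode, and pretending
otherwise would overstate what tabular screening can do.

## The synthetic cohort generator

`table1_spec()` encodes the published group-conditional distributions of
a 631-subject memory-clinic validation sample: NC n = 249 (DSR
26.60 ± 8.49, age 66.94 ± 8.87, education 12.89 ± 3.30 years, MMSE
28.41 ± 1.50), MCI n = 134 (DSR 9.40 ± 8.88) and AD n = 97 (DSR
1.60 ± 4.58), with matching ISR, HAMD and sex-ratio structure and a
56-subject MCI retest subset. These defaults *are* the study conditions;
they are not tuning knobs.

**Bounded scores.** A printed mean ± SD cannot be realised by an
untruncated normal on a bounded integer range when the SD is large
relative to the distance from the bounds. The generator matches moments
within the *truncated*-normal family (the latent normal conditioned on
[0, 56]) where feasible. Feasibility has a hard limit: on a left-bounded
range the truncated family's coefficient of variation approaches 1 from
below (the exponential tail limit), so a target like mean 1.60, SD 4.58
— CV 2.86, typical of severe floor effects in dementia — is provably out
of reach. For such targets the generator switches to the *censored*
(clipped) normal, which places genuine probability mass at the floor:
exactly the many-zeros-plus-thin-tail shape such groups show clinically.
The matched latent parameters can be extreme (the MCI target needs
μ ≈ −213, σ ≈ 47), so all tail arithmetic — interval probabilities,
moments, quantiles — is done in log space, and sampling is inverse-CDF
through the stable quantile function rather than rejection.

**Moment matching is pre-rounding.** Matching is exact (to 1e-6) for the
continuous bounded normal; integer rounding then perturbs sample moments
by well under 0.05 score units. Exact post-rounding matching would be
overdetermined and is not attempted.

**Regression structure.** With `nc_regression` present, NC delayed
recall is generated as
`intercept + 0.746·education − 0.206·age + N(0, σ_res)`, using the
published slopes; the default derives σ_res from the variance identity
so the marginal SD stays at the group target (σ_res ≈ 7.92 for SD 8.49),
and anchors the intercept so the marginal mean stays at the group mean.
Age and education are drawn independently (no covariance was published),
clipped to plausible ranges (50–85 years; 0–22 years of schooling) and
rounded *before* the score is generated, so fitting the norming
regression on simulated data recovers the generating slopes without
attenuation.

**MMSE dependence.** The MMSE–DSR association is injected through a
Gaussian copula on the scores' latent drivers with within-group latent
correlation `mmse_dsr_partial_r` (default 0.575). The recovery property
is checked on a single normative group: pooling diagnostic groups adds
between-group mean covariance that a single partial-correlation
coefficient cannot constrain.

**What the generator does not emulate.** Item-level recall, real
skewness beyond what bounded normals induce, age–education covariance,
diagnostic misclassification, drop-out, and any ISR–DSR within-subject
correlation (the two totals are drawn independently given the group).
Passing tests therefore demonstrate that the *pipeline arithmetic* is
right under the published first and second moments — not that real score
distributions are bounded normals. This is also why replicating the real
data's sensitivity/specificity pairs at printed cutoffs is out of reach
at simulation scale, while moment-driven quantities (regression slopes,
AUC) do replicate.

## Norms and cutoffs

Normative cells are age bands 50–64, 65–74, 75–85 crossed with education
≤ 9 / > 9 years (both configurable). Percentiles use the
weighted-average-at-(n+1)p order-statistic estimator (`quantile`
type 6) — the convention of the SPSS lineage in which such normative
tables are traditionally computed, recognisable by fractional values
like 3.75 in small cells. Cell retention is the mean of per-subject
DSR/ISR ratios, which weights every subject equally; ratio-of-means is
available as an option. How the original tables aggregated retention is
not stated, and the two conventions differ exactly when retention
covaries with immediate recall, which is why both are exposed.

The Petersen-style cutoff is `mean − 1.5·SD` per cell, reported raw and
at one decimal — e.g. the 50–64 stratum's published 28.10 ± 8.54 gives
15.29 → 15.3.

## Regression-based T scores

`fit_norm_regression()` fits OLS of DSR on education years and age in
the normative group; `t_score()` computes
`T = 10·(raw − expected)/σ_res + 50`. Two conventions deserve comment:

* **Residual SD.** The default is the n−1 sample SD of the residuals
  (so the fitting sample has T mean exactly 50 and SD exactly 10); the
  regression RMSE (n−p−1) is selectable. The published procedure's
  wording ("residual standard deviation") reads as the former.
* **No clipping.** T scores outside 0–100 are legal; a floor would
  destroy the metric's interpretability in severe impairment.

A fit whose residuals are numerically zero (an exact plane) is flagged
degenerate and refuses to produce T scores rather than dividing by
noise.

## ROC analysis

Impairment lowers scores, so a subject screens positive when the score
falls *strictly below* the threshold; candidate thresholds are midpoints
between adjacent distinct scores plus sentinels, which on integer data
yields the conventional half-integer cutoffs and makes < versus ≤
immaterial. The AUC uses the Mann–Whitney identity
`P(case < control) + ½·P(tie)` via midranks — exact under heavy ties,
and verified in the tests against both brute-force pair counting and
trapezoidal integration of the swept curve. The 95% CI uses the
Hanley–McNeil variance (the convention of the era's software); a
bootstrap would also be defensible but adds nothing at these sample
sizes. The "optimal" cutoff maximises Youden's J = sens + spec − 1; the
original report never names its criterion, but every printed cutoff is
consistent with half-integer Youden maximisers, and minimum distance to
the (0, 1) corner is selectable. Ties in J are resolved toward higher
sensitivity (screening favours detection), then toward the lower
threshold; J values are compared after rounding at 1e-12 so
floating-point jitter cannot leapfrog a true tie.

## Predictive values

PPV and NPV come from Bayes' rule at an assumed base rate, reported at
two decimals in the published grid layout. One published cell (cutoff
10.50, 10% base rate, printed PPV 0.63) disagrees at the second decimal
with arithmetic from its own printed sensitivity/specificity (0.637);
the printed value evidently derives from unrounded counts, and the test
suite pins that cell at the table's one-cent granularity rather than
enshrining the rounding artifact. Known typographic cells (e.g.
"0.60/1.00" where the row's neighbours make 0.82/0.99 inevitable) are
not pinned at all.

## Reliability

Test-retest reliability is complete-case Pearson correlation over the
retested subset (by design a 56-subject MCI subsample). The published
retest p-value (p = 0.011 alongside r = 0.887 at n = 56) is internally
inconsistent — an r that large at that n implies a vastly smaller p — so
the package reports its own p from the t transform and the suite does
not pin the published one. Partial correlation uses the residual method
(correlate the residuals after projecting both scores on the covariates
plus intercept), which the tests verify against the closed-form
recursion; with no covariates it reduces exactly to Pearson.

## Problem sizes and determinism

The simulation-backed checks use 200 normative cohorts of n = 249 for
coefficient recovery and 50 two-group cohorts of n = 383 for the AUC —
sizes at which Monte Carlo error is comfortably inside the tolerances
while the whole suite runs in well under a minute. Every generator call
is driven by one root seed with per-group child streams (a Lehmer-style
scramble), so the same seed reproduces a cohort byte-for-byte and adding
a group never perturbs the others' records.

## Limitations

The package validates the statistics of a screening test, not the test
itself: it cannot score free-recall transcripts (credits are adjudicated
by humans upstream), cannot stand in for clinical diagnosis (the
AD-candidate label is explicitly not a diagnosis), and its simulated
cohorts carry only the first- and second-moment structure of the
published sample. Real normative values for a new population still
require real subjects; what this package guarantees is that every
computation applied to them is correct, conventional and reproducible.
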