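---
title: "Methods: prognostic tyrosine-kinase signature discovery in TNBC"
author: "tksig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prognostic tyrosine-kinase signature discovery in TNBC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tksig)
```

# Overview

`tksig` implements a complete discovery pipeline for multigene prognostic
signatures in pooled, multi-study breast cancer expression cohorts, with
triple-negative breast cancer (TNBC) and an 86-gene tyrosine kinase (TK)
panel as the motivating application. The pipeline stages are:

1. **Harmonization** — collapse probes to genes by maximal per-dataset
   variance, call ER/PR/ERBB2 receptor status from the bimodal expression
   of `ESR1`/`PGR`/`ERBB2`, z-score every study against its luminal-A-like
   anchor samples, pool over the common gene set, and select the
   survival-informative TN subgroup.
2. **Discovery** — split the analysis set 2/3 (learning) and 1/3
   (validation) stratified by platform; screen each panel gene by
   univariate Cox regression on disease-free survival (DFS, Wald p ≤
   0.05); select the final combination by AIC stepwise search; build a
   two-class risk classifier from the Cox linear predictor dichotomized at
   the median learning-set score; evaluate by Kaplan–Meier, the log-rank
   test, and the class hazard ratio on both sets.
3. **Resampling null** — compare the observed signature's validation
   p-value with those of random same-size gene subsets run through the
   identical learn-then-classify recipe.
4. **Characterization** — moderated-t differential expression between
   risk classes with empirical-Bayes variance shrinkage and joint
   p/q/fold-change thresholds, and a nearest-centroid correlation score
   for independent samples.

A synthetic multi-study generator with a full ground-truth channel stands
in for pooled patient data and drives all calibration and power testing.

# The survival model and its assumptions

All survival analysis assumes right-censored times in months and
proportional hazards. Cox models are fitted by maximum partial likelihood
with **Efron tie handling** — the default of the R `survival` ecosystem
the original analyses were performed in — and report Wald statistics
(`beta/se` against the standard normal), `AIC = -2·loglik + 2k`, and 95%
hazard-ratio intervals `exp(beta ± 1.96·se)`. Monotone likelihood
(separation) is detected when any |beta| exceeds 15; such fits are
returned flagged rather than as errors, because degenerate hazard ratios
legitimately occur in small validation strata and belong in the report.
Kaplan–Meier bands use the Greenwood variance on the log-log scale, and
the median is the smallest event time with S(t) ≤ 0.5 (no interpolation).

Screened genes enter the Cox models as **continuous z-scores**; whether
the original analysis used continuous or dichotomized expression is not
derivable from its description, and the continuous choice preserves power
and avoids an extra cutpoint.

# Harmonization choices

- **Z-score transform**: each value becomes `(x − m)/s`, with `m`, `s`
  the per-gene mean and SD over the study's anchor samples. The anchored
  version cancels affine per-dataset batch distortion exactly and is
  idempotent.
- **Anchors**: anchor (luminal-A-like) labels are an *input* — the truth
  channel in simulations, or user-supplied labels on real data. When
  absent, a documented heuristic (ER- or PR-positive, ERBB2-negative
  samples of the same dataset) substitutes; the package does not
  re-implement intrinsic-subtype classifiers. Studies with fewer than 3
  anchors fall back to all-sample moments with a log entry; genes with
  zero anchor SD fall back to the all-sample SD.
- **Receptor calling** is per dataset, on the raw log2 values, because
  bimodality is platform-dependent. A two-component Gaussian mixture
  (`mclust`) supplies the cutpoint at the posterior-0.5 crossing between
  the component means; degenerate fits (component weight < 0.05 or mean
  separation < 0.5 pooled SD) fall back to the deepest kernel-density
  valley between the two largest modes, and unimodal distributions raise
  a "not bimodal" error with a manual-cutpoint escape hatch.
- **Gene space**: the intersection of the studies' gene sets, avoiding
  imputation.
- RNA-seq inputs are assumed already log2-transformed; the reader warns
  when values fall outside [-10, 30].

# Discovery choices

- **Split**: stratified by platform so each technology keeps close to its
  global share in both sets; deterministic given a seed.
- **Stepwise direction**: bidirectional from the full screened model. At
  every step all single-gene deletions and re-additions are scored and
  the largest AIC decrease is applied; ties prefer deletion, then
  lexicographic gene order, making the search fully deterministic.
  Non-convergent intermediate fits are skipped with a warning.
- **Dichotomization**: the risk score is the Cox linear predictor
  `sum(beta_g z_g)`; the cutoff is the **median learning-set score**,
  applied unchanged to validation and to any new cohort. A median rule is
  the simplest rule consistent with the near-even class sizes reported in
  this literature; no refitting ever happens outside the learning set.

# Resampling null

Each of `B` random k-subsets of the panel is pushed through exactly the
same recipe as the observed signature: coefficients fitted on the
learning set, median-cutoff classifier, validation log-rank p. Any
asymmetry between observed and random recipes would invalidate the
comparison, so "apply the signature" is interpreted as "refit its
coefficients on the learning set", which also matches how the observed
signature was built. The headline empirical p is the **strict**
proportion of null p-values below the observed one; because a zero
proportion is otherwise possible, the `(1 + count)/(B + 1)` smoothed
variant is reported alongside. Degenerate resampled fits are recorded
conservatively at p = 1. `B` defaults to 10,000 at desk scale and is
configurable upward.

# Moderated t-test

The two-group moderated t shrinks each gene's pooled variance `s2_g`
(with `d = n1 + n2 − 2` df) towards a prior `(d0, s0sq)` estimated by
moment-matching the log sample variances: with
`e_g = log(s2_g) − digamma(d/2) + log(d/2)`, the excess of `var(e)` over
`trigamma(d/2)` determines `d0` through a Newton inversion of the
trigamma function, and `s0sq` follows from `mean(e)`. When no excess
dispersion exists, `d0 = Inf` and all posterior variances collapse to the
mean sample variance, with a normal reference for the p-value (the
degrees of freedom are *not* capped at the pooled residual df, a small
deliberate difference from `limma`, which the test suite documents by
using heteroskedastic data for the cross-check). `d0 = 0` reduces exactly
to the ordinary pooled t-test, which the tests exploit as an oracle.

The log fold change is `mean(first class) − mean(second class)`; the
pipeline orders the classes `low-risk`, `high-risk`, so positive logFC
means over-expressed in low-risk samples. Significance uses the joint
thresholds p < 0.01, q < 0.01 (Benjamini–Hochberg), and linear fold
change above 1.25 (|logFC| > log2 1.25 ≈ 0.322, since inputs are log2).

The **centroid score** of a sample is the Pearson correlation of its
DE-gene profile with the median profile of high-risk learning samples
minus that with the low-risk centroid; positive scores predict
high-risk. Pearson is the default (profiles are continuous z-scores);
Spearman is available via an argument.

# The synthetic cohort generator

`simulateCohort()` emulates the features the pipeline relies on, with a
full truth channel (true receptor classes and subtypes, latent event and
censoring times, per-gene true log-hazards):

- Expression of gene g in sample i of dataset d is
  `mu_g + shift_d + scale_d · (signal_gi + eps)`, an affine per-dataset
  batch distortion of a latent signal plus measurement noise
  (SD 0.3).
- Receptor-gene signals are two-component Gaussian draws tied to the
  sample's true class (component means ±2.5 around the gene baseline, SD
  0.8) — clearly separated, as receptor transcripts are in practice;
  configurations whose components are not separable (mean difference
  below half the largest SD) are rejected at construction.
- Planted prognostic genes carry a standard-normal latent covariate that
  enters the DFS hazard; the default plants five of the 86 panel genes at
  log-hazard ±0.8 per z-unit.
- DFS is Weibull (shape 1.2, scale 98 months — baseline median near six
  years); censoring is independent exponential with the rate solved
  numerically against the realized event times to hit the target
  censored fraction (default 40%), under a 240-month administrative
  horizon. OS is the DFS event time plus an exponential lag (mean 24
  months) for 70% of relapsers, sharing the censoring process.
- Defaults produce 4 datasets × 400 samples with 20% luminal-A-like
  anchors, 50% triple-negatives (≈800 analysis samples) and one RNA-seq
  dataset among microarrays; clinical covariates are drawn from marginal
  frequencies typical of early TNBC series and are independent of the
  hazard.
- All randomness flows from one seed; identical seeds give
  byte-identical bundles.

What the generator does **not** emulate: correlated immune-infiltration
programs, intrinsic-subtype structure beyond the receptor classes,
platform-specific noise shapes, or informative censoring. Passing tests
therefore demonstrate the pipeline's statistical behaviour under its own
assumptions — calibration under the null, power against planted effects,
batch-affine robustness — not performance on any real cohort.

# Numerical conventions and degenerate inputs

- Probe collapse breaks exact variance ties by the lexicographically
  smaller probe id, with a warning.
- Cox convergence: `survival`'s Newton iterations (max 50, eps 1e-9);
  |beta| > 15 flags separation.
- The stepwise search stops when no move lowers AIC by more than 1e-8.
- Fisher's exact test falls back to a seeded Monte-Carlo p-value when a
  table exceeds the exact algorithm's capacity.
- Samples with missing signature-gene values are excluded from scoring
  with a log entry; empty risk classes, cohorts without events, and
  constant covariates raise immediate errors naming the offender.

# Problem sizes used by the test suite

The calibration and power suites run at the package's documented study
conditions: screens at ~800 analysis samples over the 86-gene panel (50
seeds), stepwise recovery with 5 planted + 20 null candidates (25
seeds), pipeline null calibration at ~350 analysis samples (100 seeds),
and resampling-null behaviour at B = 2,000 random 13-gene signatures per
cohort over 20 seeds plus B = 150 across 30 null cohorts for the
uniformity check. These are desk-scale choices; the estimators themselves
are size-agnostic and `B` scales to 100,000 unchanged.

# Known limitations

- Anchor identification on real data is an input or a heuristic, not a
  re-implementation of intrinsic-subtype calling.
- The published 13-gene signature ships as a gene list with effect
  directions only (`publishedSignature()`); its original coefficients
  were never published, so applying it to new data requires refitting.
- No time-varying covariates, stratified baselines, frailty, or
  competing risks.
- The moderated t assumes a common two-group design; covariate-adjusted
  differential expression is out of scope.
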