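# tksig

Discovery and validation of multigene prognostic expression signatures in
pooled multi-study breast cancer cohorts, centred on an 86-gene tyrosine
kinase (TK) panel in triple-negative breast cancer (TNBC).

TNBC lacks the receptor targets that drive therapy choice in other breast
cancer subtypes, and neither classical clinicopathological factors nor the
marketed proliferation-based signatures separate good- from poor-prognosis
patients in this subtype. `tksig` implements, as a tested and reusable
pipeline, the strategy of mining a kinase gene panel for a disease-free
survival (DFS) signature across many pooled retrospective datasets:

- **Harmonization** — probes collapse to genes by maximal per-dataset
  variance; each study is z-scored against its luminal-A-like anchor
  samples, `z = (x − m_anchor)/s_anchor`, which cancels affine batch
  distortion; ER/PR/ERBB2 status is called per dataset from the bimodal
  expression of *ESR1*, *PGR* and *ERBB2* (Gaussian-mixture cutpoint at
  the posterior-0.5 crossing); triple-negative = all three negative.
- **Discovery** — a platform-stratified 2/3 : 1/3 learning/validation
  split; per-gene univariate Cox screen on the learning set (Wald
  p ≤ 0.05); AIC stepwise search over the screened set
  (`AIC = −2·loglik + 2k`, bidirectional from the full model,
  deterministic tie-breaks); risk score `sum(beta_g · z_g)` dichotomized
  at the median learning score into "low-risk"/"high-risk"; evaluation by
  Kaplan–Meier, log-rank, and the class hazard ratio, on the untouched
  validation set.
- **Resampling null** — B random same-size gene subsets of the panel run
  through the identical learn-then-classify recipe; the empirical p is
  the proportion of random signatures beating the observed validation
  p-value.
- **Characterization** — empirical-Bayes moderated t-test between risk
  classes (p < 0.01, q < 0.01, fold change > 1.25×), nearest-centroid
  correlation scores for independent samples, metagene scoring, and
  Fisher/Welch association tables.

A synthetic multi-study generator (`simulateCohort()`) with a complete
ground-truth channel — true receptor classes, planted prognostic genes
with known log-hazards, known batch parameters, latent event and
censoring times — stands in for pooled patient data and underpins the
calibration, power, and recovery tests. The published 13-TK gene list
ships as a fixture (`publishedSignature()`) with effect directions; its
coefficients were never published, so applying it requires refitting.

## Worked example

```r
library(tksig)

sim    <- simulateCohort(simConfig(seed = 42))          # 4 studies, 1600 samples
cohort <- buildCohort(studies(sim), clinicalData(sim),
                      anchorIds = with(groundTruth(sim)$samples,
                                       sample_id[true_subtype == "anchor"]))
tn   <- selectSubgroup(cohort, "TN", "dfs")
disc <- runDiscovery(tn, seed = 42)
disc
disc$model
disc$evalValidation
```

```
[tksig] selectSubgroup: 831 of 1600 samples retained (subtype=TN, endpoint=dfs)
[tksig] splitCohort: learning 554, validation 277
[tksig] univariateScreen: 9 of 86 genes pass at alpha = 0.05
Signature discovery (dfs): 9 screened -> 8 signature genes
Validation: log-rank p = 5.33e-20 ; HR = 4.28 (3.06-5.98)
SignatureModel: 8 genes; cutoff = 0.005248; learning AIC = 3223.04
   ALK=+0.626 EPHA4=+0.625 FLT1=+0.533 FGFR4=+0.147 PTK6=+0.116 JAK3=-0.150 ITK=-0.615 ZAP70=-0.616
Risk-class evaluation (n = 277 ):
     class    surv5y     lower     upper
  low-risk 0.7782966 0.6889624 0.8448260
 high-risk 0.2428395 0.1713477 0.3212363
log-rank p = 5.33e-20 ; HR high vs low = 4.28 (3.06-5.98)
```

Reading this: 831 of 1600 simulated samples are survival-informative
triple-negatives. The screen keeps 9 of the 86 panel genes; the stepwise
search retains 8, including all five genes the generator planted (the
±0.6 coefficients) plus three small-effect passengers. Applied to the 277
held-out validation samples, the median-cutoff classifier separates
5-year DFS of 78% (low-risk) versus 24% (high-risk), hazard ratio 4.28
(95% CI 3.06–5.98) — large, as expected for the generator's strong
planted effects.

The resampling null then quantifies non-randomness:

```r
sv <- survivalData(tn, "dfs"); z <- zMatrix(tn)
L <- disc$split$learning; V <- disc$split$validation
nd <- resamplingNull(signatureGenes(disc$model), tkPanel(),
                     sv[L, "time"], sv[L, "event"], z[, L],
                     sv[V, "time"], sv[V, "event"], z[, V],
                     B = 10000, seed = 1)
nd
```

A config-driven command interface (`cmdSimulate`, `cmdPreprocess`,
`cmdDiscover`, `cmdNull`, `cmdDiffexp`, `cmdReport`) mirrors the same
flow for file-based runs, with a thin CLI in `inst/scripts/tksig.R`; runs
are sealed by a split hash so the resampling stage refuses a mismatched
learning/validation partition.

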