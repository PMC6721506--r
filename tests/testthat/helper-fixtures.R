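# Shared fixture builders. All data are generated in code at test time.

# A compact simulation configuration for fast tests: one small panel, two
# datasets, and optional overrides passed straight to simConfig().
smallSimConfig <- function(seed = 1L, ...) {
  args <- list(
    nDatasets = 2L, samplesPerDataset = 150L, nGenesTotal = 40L,
    panelGenes = c("EPHA4", "FLT1", "ALK", "ITK", "ZAP70", "SRC", "FYN",
                   "EPHA1", "EPHB4", "KIT", "MET", "RET", "AXL", "LYN",
                   "SYK", "TEC", "ABL1", "EGFR", "JAK1", "LCK"),
    seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(simConfig, args)
}

# Simple uncorrelated survival data for unit tests of the fitters.
makeSurvData <- function(n, beta = 0, x = stats::rnorm(n),
                         censRate = 0.01) {
  time <- stats::rexp(n, exp(beta * x) / 50)
  cens <- stats::rexp(n, censRate / 50)
  data.frame(time = pmin(time, cens), event = as.integer(time <= cens),
             x = x)
}

# Harmonized TN matrix + survival data from a simulated cohort, using the
# truth channel for anchor labels (receptor calling exercised elsewhere).
harmonizedTN <- function(sim) {
  tr <- groundTruth(sim)$samples
  anchors <- tr$sample_id[tr$true_subtype == "anchor"]
  cohort <- suppressMessages(
    buildCohort(studies(sim), clinicalData(sim), anchorIds = anchors))
  tn <- suppressMessages(selectSubgroup(cohort, "TN", "dfs"))
  list(cohort = cohort, tn = tn, z = zMatrix(tn),
       sv = survivalData(tn, "dfs"))
}
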