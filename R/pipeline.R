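# End-to-end orchestration: the discovery pipeline, config-driven command
# wrappers mirroring the analysis flow (simulate / discover / null /
# diffexp / report), and Markdown reporting. A thin Rscript entry point
# over these functions ships in inst/scripts/tksig.R.

#' Run the signature-discovery pipeline on a harmonized cohort
#'
#' Splits the analysis cohort 2/3-1/3 stratified by platform, screens the
#' candidate panel by univariate Cox regression on the learning set,
#' selects the signature by AIC stepwise search, fixes the median-cutoff
#' classifier on the learning set, and evaluates it on both sets. The
#' validation set is never touched before the classifier is frozen.
#'
#' @param cohort A [TKCohort-class] restricted to the analysis subgroup
#'   (see [selectSubgroup()]).
#' @param panel Candidate gene identifiers (default [tkPanel()]
#'   intersected with the cohort genes).
#' @param endpoint `"dfs"` (default) or `"os"`.
#' @param alpha Screen threshold (default 0.05).
#' @param fractions Learning/validation proportions (default 2/3, 1/3).
#' @param seed Seed for the split.
#' @return List of class `tkDiscovery`: `split`, `screen`, `model`,
#'   `evalLearning`, `evalValidation`, `endpoint`.
#' @export
runDiscovery <- function(cohort, panel = tkPanel(),
                         endpoint = c("dfs", "os"), alpha = 0.05,
                         fractions = c(2, 1) / 3, seed = 1L) {
  endpoint <- match.arg(endpoint)
  panel <- intersect(panel, rownames(cohort))
  if (length(panel) == 0L) stop("no panel genes present in the cohort")
  sv <- survivalData(cohort, endpoint)
  z <- zMatrix(cohort)
  split <- splitCohort(colnames(cohort),
                       stratum = colData(cohort)$platform,
                       fractions = fractions, seed = seed)
  L <- split$learning; V <- split$validation
  screen <- univariateScreen(sv[L, "time"], sv[L, "event"],
                             z[panel, L, drop = FALSE], alpha = alpha)
  if (length(screen$passing) == 0L) {
    stop("no genes passed the univariate screen")
  }
  model <- stepwiseAic(sv[L, "time"], sv[L, "event"],
                       z[, L, drop = FALSE], screen$passing)
  model <- buildClassifier(model, z[, L, drop = FALSE])
  model@provenance$screen_alpha <- alpha
  model@provenance$endpoint <- endpoint
  model@provenance$split_hash <- split$hash
  evalL <- evaluateClassifier(model, sv[L, "time"], sv[L, "event"],
                              z[, L, drop = FALSE])
  evalV <- evaluateClassifier(model, sv[V, "time"], sv[V, "event"],
                              z[, V, drop = FALSE])
  res <- list(split = split, screen = screen, model = model,
              evalLearning = evalL, evalValidation = evalV,
              endpoint = endpoint)
  class(res) <- "tkDiscovery"
  res
}

#' @export
print.tkDiscovery <- function(x, ...) {
  cat("Signature discovery (", x$endpoint, "): ",
      length(x$screen$passing), " screened -> ",
      length(signatureGenes(x$model)), " signature genes\n", sep = "")
  cat("Validation: log-rank p =",
      format(x$evalValidation$logrank$p, digits = 3),
      "; HR =", x$evalValidation$hrText, "\n")
  invisible(x)
}

# ------------------------------------------------------------------
# Config handling and command wrappers
# ------------------------------------------------------------------

#' Read and validate a pipeline configuration file
#'
#' YAML key-value config; recognised keys: `expression` (named list of
#' dataset -> list(path, platform)), `clinical`, `anchors` (file of anchor
#' sample ids, optional), `panel` (file of gene symbols, optional),
#' `screen_alpha`, `split_seed`, `fractions`, `resampling_B`,
#' `resampling_k`, `resampling_seed`, `endpoint`, `subgroup`, `out_dir`.
#'
#' @param path YAML file.
#' @return Validated config list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  cfg$screen_alpha <- num(cfg$screen_alpha, 0.05)
  if (cfg$screen_alpha <= 0 || cfg$screen_alpha >= 1) {
    stop("config field 'screen_alpha' must be in (0, 1)")
  }
  cfg$split_seed <- as.integer(num(cfg$split_seed, 1))
  if (is.na(cfg$split_seed)) stop("config field 'split_seed' must be an integer")
  cfg$fractions <- if (is.null(cfg$fractions)) c(2, 1) / 3 else
    as.numeric(cfg$fractions)
  if (abs(sum(cfg$fractions) - 1) > 1e-8) {
    stop("config field 'fractions' must sum to 1")
  }
  cfg$resampling_B <- as.integer(num(cfg$resampling_B, 10000))
  if (cfg$resampling_B < 1) stop("config field 'resampling_B' must be >= 1")
  cfg$resampling_seed <- as.integer(num(cfg$resampling_seed, 1))
  cfg$endpoint <- if (is.null(cfg$endpoint)) "dfs" else cfg$endpoint
  cfg$subgroup <- if (is.null(cfg$subgroup)) "TN" else cfg$subgroup
  for (f in c(vapply(cfg$expression, function(e) e$path, character(1)),
              cfg$clinical, cfg$anchors, cfg$panel)) {
    if (!is.null(f) && !file.exists(f)) stop("missing input file: ", f)
  }
  cfg
}

#' Simulate command: write a synthetic fixture directory
#'
#' @param simCfg A [simConfig()] list.
#' @param outDir Output directory.
#' @param force Overwrite an existing manifest?
#' @return Invisibly, the fixture manifest.
#' @export
cmdSimulate <- function(simCfg, outDir, force = FALSE) {
  bundle <- simulateCohort(simCfg)
  writeFixture(bundle, outDir, force = force)
}

# Load studies and clinical data as directed by a pipeline config.
.loadInputs <- function(cfg) {
  studiesList <- lapply(names(cfg$expression), function(ds) {
    e <- cfg$expression[[ds]]
    readExpressionStudy(e$path, platform = e$platform, datasetId = ds)
  })
  clinical <- utils::read.delim(cfg$clinical, stringsAsFactors = FALSE)
  anchors <- if (!is.null(cfg$anchors)) readLines(cfg$anchors) else NULL
  panel <- if (!is.null(cfg$panel)) readLines(cfg$panel) else tkPanel()
  list(studies = studiesList, clinical = clinical, anchors = anchors,
       panel = panel)
}

#' Discover command: harmonize, discover, evaluate, serialize
#'
#' Runs harmonization, subgroup selection, and [runDiscovery()], writes
#' the signature JSON, evaluation TSVs and a run manifest into the output
#' directory, and (when the cohort contains non-target samples) applies
#' the frozen classifier to the non-TN subgroup as a specificity check.
#'
#' @param cfg Config list from [readPipelineConfig()].
#' @param outDir Output directory.
#' @return Invisibly, a list with the discovery result and file paths.
#' @export
cmdDiscover <- function(cfg, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  inp <- .loadInputs(cfg)
  cohort <- buildCohort(inp$studies, inp$clinical, anchorIds = inp$anchors)
  sub <- selectSubgroup(cohort, subtype = cfg$subgroup,
                        endpoint = cfg$endpoint)
  disc <- runDiscovery(sub, panel = inp$panel, endpoint = cfg$endpoint,
                       alpha = cfg$screen_alpha,
                       fractions = cfg$fractions, seed = cfg$split_seed)
  sigPath <- file.path(outDir, "signature.json")
  writeSignature(disc$model, sigPath)
  utils::write.table(disc$screen$table,
                     file.path(outDir, "screen.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeEvaluationTsv(disc$evalValidation,
                     file.path(outDir, "evaluation_validation.tsv"))
  writeEvaluationTsv(disc$evalLearning,
                     file.path(outDir, "evaluation_learning.tsv"))
  nonTarget <- NULL
  if (cfg$subgroup == "TN" &&
      any(!is.na(subtypes(cohort)) & subtypes(cohort) != "TN")) {
    nt <- tryCatch(selectSubgroup(cohort, "non_tn", cfg$endpoint),
                   error = function(e) NULL)
    if (!is.null(nt)) {
      svNT <- survivalData(nt, cfg$endpoint)
      nonTarget <- tryCatch(
        evaluateClassifier(disc$model, svNT$time, svNT$event, zMatrix(nt)),
        error = function(e) NULL)
    }
  }
  manifest <- list(config = cfg[setdiff(names(cfg), "expression")],
                   split_hash = disc$split$hash,
                   seed = cfg$split_seed,
                   version = as.character(utils::packageVersion("tksig")),
                   files = list(signature = unname(tools::md5sum(sigPath))),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(discovery = disc, nonTarget = nonTarget,
                 signature = sigPath, outDir = outDir))
}

# Per-class KM + HR rows as TSV.
writeEvaluationTsv <- function(ev, path) {
  df <- ev$fiveYear
  df$medianSurv <- unname(ev$median[df$class])
  df$logrank_p <- ev$logrank$p
  df$hr <- c(NA, unname(ev$cox$hr))[seq_len(nrow(df))]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Null command: resampling null for a frozen discovery run
#'
#' Refuses to run when the signature's recorded split hash does not match
#' the split regenerated from the config (guards against leakage between
#' learning and validation).
#'
#' @param cfg Config list from [readPipelineConfig()].
#' @param discoverDir Directory written by [cmdDiscover()].
#' @param B,k,seed Optional overrides of the config resampling settings.
#' @return The [NullDistribution-class]; a summary JSON is written next to
#'   the signature.
#' @export
cmdNull <- function(cfg, discoverDir, B = NULL, k = NULL, seed = NULL) {
  model <- readSignature(file.path(discoverDir, "signature.json"))
  inp <- .loadInputs(cfg)
  cohort <- buildCohort(inp$studies, inp$clinical, anchorIds = inp$anchors)
  sub <- selectSubgroup(cohort, subtype = cfg$subgroup,
                        endpoint = cfg$endpoint)
  split <- splitCohort(colnames(sub), stratum = colData(sub)$platform,
                       fractions = cfg$fractions, seed = cfg$split_seed)
  if (!identical(split$hash, model@provenance$split_hash)) {
    stop("split hash mismatch between signature and config; refusing to ",
         "run the resampling null on a different split")
  }
  sv <- survivalData(sub, cfg$endpoint)
  z <- zMatrix(sub)
  L <- split$learning; V <- split$validation
  nd <- resamplingNull(
    signatureGenes(model), intersect(inp$panel, rownames(z)),
    sv[L, "time"], sv[L, "event"], z[, L, drop = FALSE],
    sv[V, "time"], sv[V, "event"], z[, V, drop = FALSE],
    B = if (is.null(B)) cfg$resampling_B else B,
    k = if (is.null(k)) length(signatureGenes(model)) else k,
    seed = if (is.null(seed)) cfg$resampling_seed else seed)
  jsonlite::write_json(
    list(B = nd@B, k = nd@k, observed_p = nd@observedP,
         empirical_p = nd@empiricalP,
         empirical_p_smoothed = nd@empiricalPSmoothed,
         degenerate = nd@degenerate, seed = nd@seed),
    file.path(discoverDir, "null_summary.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  utils::write.table(data.frame(null_p = nd@nullP),
                     gzfile(file.path(discoverDir, "null_pvalues.tsv.gz")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  nd
}

#' Preprocess command: harmonize studies and write the pooled matrix
#'
#' @param cfg Config list from [readPipelineConfig()].
#' @param outDir Output directory; receives `harmonized.tsv` (pooled
#'   z-scores), `calls.tsv` (receptor calls, subtype, anchor flag) and
#'   `receptor_thresholds.json`.
#' @return Invisibly, the [TKCohort-class].
#' @export
cmdPreprocess <- function(cfg, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  inp <- .loadInputs(cfg)
  cohort <- buildCohort(inp$studies, inp$clinical, anchorIds = inp$anchors)
  .writeTsvMatrix(zMatrix(cohort), file.path(outDir, "harmonized.tsv"))
  calls <- clinicalData(cohort)[, c("sample_id", "dataset_id", "er_call",
                                    "pr_call", "erbb2_call", "subtype",
                                    "anchor")]
  utils::write.table(calls, file.path(outDir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(metadata(cohort)$receptor_thresholds,
                       file.path(outDir, "receptor_thresholds.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(cohort)
}

#' Differential-expression command: characterize the risk classes
#'
#' Classifies the analysis cohort with the frozen signature, runs the
#' moderated t-test between classes on the learning half of the split,
#' writes the DE table, and scores the validation half with the
#' nearest-centroid correlation score over the significant genes.
#'
#' @param cfg Config list from [readPipelineConfig()].
#' @param discoverDir Directory written by [cmdDiscover()].
#' @return Invisibly, list with the DE table, gene lists and centroid
#'   score.
#' @export
cmdDiffexp <- function(cfg, discoverDir) {
  model <- readSignature(file.path(discoverDir, "signature.json"))
  inp <- .loadInputs(cfg)
  cohort <- buildCohort(inp$studies, inp$clinical, anchorIds = inp$anchors)
  sub <- selectSubgroup(cohort, subtype = cfg$subgroup,
                        endpoint = cfg$endpoint)
  split <- splitCohort(colnames(sub), stratum = colData(sub)$platform,
                       fractions = cfg$fractions, seed = cfg$split_seed)
  z <- zMatrix(sub)
  clsAll <- classifyRisk(model, z)
  # convention: first level low-risk, so positive logFC = up in low-risk
  de <- moderatedT(z[, split$learning, drop = FALSE],
                   clsAll[match(split$learning, colnames(z))])
  lists <- deGeneList(de)
  deGenes <- c(lists$upInLow, lists$upInHigh)
  cs <- NULL
  if (length(deGenes) >= 3L) {
    cs <- centroidScore(
      z[deGenes, split$learning, drop = FALSE],
      clsAll[match(split$learning, colnames(z))],
      z[deGenes, split$validation, drop = FALSE],
      newClasses = clsAll[match(split$validation, colnames(z))])
  }
  utils::write.table(de, file.path(discoverDir, "diffexp.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(de = de, lists = lists, centroid = cs))
}

#' Report command: human-readable Markdown summary of a run directory
#'
#' @param runDir Directory holding the outputs of [cmdDiscover()] (and
#'   optionally [cmdNull()]).
#' @param file Optional output path; default `report.md` inside `runDir`.
#' @return Invisibly, the report path. Partial runs produce partial
#'   reports with explicit gaps.
#' @export
cmdReport <- function(runDir, file = file.path(runDir, "report.md")) {
  lines <- c("# Signature discovery report", "")
  sigPath <- file.path(runDir, "signature.json")
  if (file.exists(sigPath)) {
    model <- readSignature(sigPath)
    b <- signatureBeta(model)
    lines <- c(lines, "## Signature", "",
               paste0("- genes (", length(b), "): ",
                      paste(names(b), collapse = ", ")),
               paste0("- cutoff: ", format(signatureCutoff(model),
                                           digits = 4)), "",
               "| gene | beta |", "|---|---|",
               sprintf("| %s | %+.4f |", names(b), b), "")
  } else {
    lines <- c(lines, "signature: not run", "")
  }
  evPath <- file.path(runDir, "evaluation_validation.tsv")
  if (file.exists(evPath)) {
    ev <- utils::read.delim(evPath)
    lines <- c(lines, "## Validation evaluation", "",
               "| class | 5-year survival (95% CI) | median (months) |",
               "|---|---|---|",
               sprintf("| %s | %.0f%% (%.0f-%.0f) | %s |", ev$class,
                       100 * ev$surv5y, 100 * ev$lower, 100 * ev$upper,
                       ifelse(is.na(ev$medianSurv), "not reached",
                              round(ev$medianSurv))),
               "",
               paste0("- log-rank p = ",
                      format(ev$logrank_p[1], digits = 3)),
               paste0("- HR (high vs low) = ",
                      format(ev$hr[2], digits = 3)), "")
  } else {
    lines <- c(lines, "evaluation: not run", "")
  }
  nullPath <- file.path(runDir, "null_summary.json")
  if (file.exists(nullPath)) {
    ns <- jsonlite::read_json(nullPath, simplifyVector = TRUE)
    lines <- c(lines, "## Resampling null", "",
               sprintf("- B = %d random %d-gene signatures", ns$B, ns$k),
               sprintf("- observed validation p = %.3g", ns$observed_p),
               sprintf("- empirical p = %.3g (smoothed %.3g)",
                       ns$empirical_p, ns$empirical_p_smoothed), "")
  } else {
    lines <- c(lines, "resampling: not run", "")
  }
  writeLines(lines, file)
  invisible(file)
}
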