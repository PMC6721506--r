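#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<- rowData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

# -------------------------------------------------------------------------
# ExpressionStudy: one study's probe/gene x sample log2 expression matrix
# -------------------------------------------------------------------------

#' ExpressionStudy: a single study's expression matrix
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] carrying one study's
#' probe- or gene-level log2 expression (assay `"exprs"`), a probe-to-gene
#' map in `rowData` (columns `probe_id`, `gene_id`), and the study's
#' `dataset_id` and `platform` (`"microarray"` or `"rnaseq"`) in
#' `metadata`.
#'
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

.validExpressionStudy <- function(object) {
  msg <- character()
  md <- metadata(object)
  if (is.null(md$platform) ||
      !md$platform %in% c("microarray", "rnaseq")) {
    msg <- c(msg, "metadata 'platform' must be 'microarray' or 'rnaseq'")
  }
  if (is.null(md$dataset_id) || !nzchar(md$dataset_id)) {
    msg <- c(msg, "metadata 'dataset_id' must be a non-empty string")
  }
  if (anyDuplicated(colnames(object))) {
    msg <- c(msg, "sample ids (colnames) must be unique")
  }
  if (!all(c("probe_id", "gene_id") %in% colnames(rowData(object)))) {
    msg <- c(msg, "rowData must contain 'probe_id' and 'gene_id'")
  }
  x <- assay(object, "exprs")
  if (nrow(x) > 0 && ncol(x) > 0 && any(rowSums(!is.na(x)) == 0)) {
    msg <- c(msg, "matrix contains all-missing rows")
  }
  if (length(msg)) msg else TRUE
}
setValidity("ExpressionStudy", .validExpressionStudy)

#' Construct an ExpressionStudy
#'
#' @param exprs Numeric matrix, probes/genes in rows, samples in columns,
#'   log2-scale values; rownames are probe (or gene) identifiers, colnames
#'   sample identifiers.
#' @param platform `"microarray"` or `"rnaseq"`.
#' @param datasetId Study identifier string.
#' @param probeMap Optional named character vector mapping probe id to gene
#'   id; defaults to the identity map (rows already at gene level).
#' @return An [ExpressionStudy-class] object.
#' @export
ExpressionStudy <- function(exprs, platform, datasetId, probeMap = NULL) {
  exprs <- as.matrix(exprs)
  if (is.null(rownames(exprs)) || is.null(colnames(exprs))) {
    stop("'exprs' must have rownames (probes/genes) and colnames (samples)")
  }
  if (is.null(probeMap)) {
    probeMap <- stats::setNames(rownames(exprs), rownames(exprs))
  }
  if (!all(rownames(exprs) %in% names(probeMap))) {
    stop("probeMap does not cover all matrix rows")
  }
  rd <- DataFrame(probe_id = rownames(exprs),
                  gene_id = unname(probeMap[rownames(exprs)]))
  se <- SummarizedExperiment(
    assays = list(exprs = exprs), rowData = rd,
    metadata = list(platform = platform, dataset_id = datasetId))
  new("ExpressionStudy", se)
}

#' @describeIn ExpressionStudy-class the study's platform tag.
#' @param object,x An `ExpressionStudy`.
#' @export
setGeneric("platform", function(object) standardGeneric("platform"))

#' @rdname ExpressionStudy-class
#' @export
setMethod("platform", "ExpressionStudy",
          function(object) metadata(object)$platform)

#' @describeIn ExpressionStudy-class the study's dataset identifier.
#' @export
setGeneric("datasetId", function(object) standardGeneric("datasetId"))

#' @rdname ExpressionStudy-class
#' @export
setMethod("datasetId", "ExpressionStudy",
          function(object) metadata(object)$dataset_id)

#' @describeIn ExpressionStudy-class the log2 expression matrix.
#' @export
setGeneric("exprs", function(object) standardGeneric("exprs"))

#' @rdname ExpressionStudy-class
#' @export
setMethod("exprs", "ExpressionStudy", function(object) assay(object, "exprs"))

setMethod("show", "ExpressionStudy", function(object) {
  cat("ExpressionStudy '", datasetId(object), "' (", platform(object), "): ",
      nrow(object), " features x ", ncol(object), " samples\n", sep = "")
})

# -------------------------------------------------------------------------
# TKCohort: pooled harmonized cohort
# -------------------------------------------------------------------------

#' TKCohort: a harmonized multi-study cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose assay `"z"` holds
#' the pooled gene x sample matrix of luminal-A-anchored z-scores and whose
#' `colData` carries the clinical table plus derived columns: receptor calls
#' (`er_call`, `pr_call`, `erbb2_call`), molecular `subtype`
#' (`"TN"`, `"ER+/ERBB2-"`, `"ERBB2+"`), and the `anchor` flag marking
#' luminal-A-like reference samples.
#'
#' @export
setClass("TKCohort", contains = "SummarizedExperiment")

.cohortRequiredCols <- c(
  "sample_id", "dataset_id", "platform",
  "er_call", "pr_call", "erbb2_call", "subtype", "anchor")

.validTKCohort <- function(object) {
  msg <- character()
  cd <- colData(object)
  miss <- setdiff(.cohortRequiredCols, colnames(cd))
  if (length(miss)) {
    msg <- c(msg, paste("colData missing columns:",
                        paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(colnames(object))) {
    msg <- c(msg, "sample ids must be unique")
  }
  if (!"z" %in% names(assays(object))) msg <- c(msg, "assay 'z' required")
  if (length(msg)) msg else TRUE
}
setValidity("TKCohort", .validTKCohort)

#' @describeIn TKCohort-class per-sample receptor calls as a data.frame with
#'   columns `er_call`, `pr_call`, `erbb2_call`.
#' @param object,x A `TKCohort`.
#' @export
setGeneric("receptorCalls", function(object) standardGeneric("receptorCalls"))

#' @rdname TKCohort-class
#' @export
setMethod("receptorCalls", "TKCohort", function(object) {
  as.data.frame(colData(object)[, c("er_call", "pr_call", "erbb2_call")])
})

#' @describeIn TKCohort-class per-sample molecular subtype factor.
#' @export
setGeneric("subtypes", function(object) standardGeneric("subtypes"))

#' @rdname TKCohort-class
#' @export
setMethod("subtypes", "TKCohort", function(object) colData(object)$subtype)

#' @describeIn TKCohort-class the clinical table (all colData) as a
#'   data.frame.
#' @export
setGeneric("clinicalData", function(object) standardGeneric("clinicalData"))

#' @rdname TKCohort-class
#' @export
setMethod("clinicalData", "TKCohort",
          function(object) as.data.frame(colData(object)))

#' @describeIn TKCohort-class the harmonized z-score matrix.
#' @export
setGeneric("zMatrix", function(object) standardGeneric("zMatrix"))

#' @rdname TKCohort-class
#' @export
setMethod("zMatrix", "TKCohort", function(object) assay(object, "z"))

setMethod("show", "TKCohort", function(object) {
  st <- table(colData(object)$subtype)
  cat("TKCohort: ", nrow(object), " genes x ", ncol(object), " samples (",
      length(unique(colData(object)$dataset_id)), " datasets)\n", sep = "")
  cat("  subtypes:",
      paste(names(st), st, sep = "=", collapse = ", "), "\n")
})

#' Extract time/event columns for an endpoint
#'
#' @param cohort A [TKCohort-class].
#' @param endpoint `"dfs"` or `"os"`.
#' @return data.frame with columns `time` (months) and `event` (0/1),
#'   rownames = sample ids.
#' @export
survivalData <- function(cohort, endpoint = c("dfs", "os")) {
  endpoint <- match.arg(endpoint)
  cd <- colData(cohort)
  tc <- paste0(endpoint, "_months")
  ec <- paste0(endpoint, "_event")
  if (!all(c(tc, ec) %in% colnames(cd))) {
    stop("cohort lacks columns ", tc, "/", ec)
  }
  data.frame(time = cd[[tc]], event = cd[[ec]],
             row.names = colnames(cohort))
}

# -------------------------------------------------------------------------
# SignatureModel
# -------------------------------------------------------------------------

#' SignatureModel: a fitted multigene risk signature
#'
#' Holds the ordered signature gene list, the Cox log-hazard coefficients
#' per z-score unit, the learning-set risk-score cutoff defining the
#' low-/high-risk dichotomy, the learning-set AIC, and a provenance list
#' (screen alpha, stepwise trace, split hash).
#'
#' @slot genes Character vector of gene identifiers.
#' @slot beta Named numeric vector of coefficients, aligned to `genes`.
#' @slot cutoff Risk-score threshold; `NA` until [buildClassifier()] runs.
#' @slot learningAic Learning-set AIC of the final model.
#' @slot provenance List of free-form provenance entries.
#' @export
setClass("SignatureModel",
         representation(genes = "character", beta = "numeric",
                        cutoff = "numeric", learningAic = "numeric",
                        provenance = "list"))

.validSignatureModel <- function(object) {
  msg <- character()
  if (length(object@genes) < 1L) msg <- c(msg, "at least one gene required")
  if (length(object@beta) != length(object@genes)) {
    msg <- c(msg, "beta and genes must be the same length")
  }
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate signature genes")
  if (length(msg)) msg else TRUE
}
setValidity("SignatureModel", .validSignatureModel)

#' Construct a SignatureModel
#'
#' @param genes Character vector of gene identifiers.
#' @param beta Numeric coefficients aligned to `genes`.
#' @param cutoff Risk-score cutoff (default `NA` until a classifier is
#'   built).
#' @param learningAic Learning-set AIC (optional).
#' @param provenance List of provenance entries.
#' @return A [SignatureModel-class] object.
#' @export
SignatureModel <- function(genes, beta, cutoff = NA_real_,
                           learningAic = NA_real_, provenance = list()) {
  new("SignatureModel", genes = as.character(genes),
      beta = stats::setNames(as.numeric(beta), genes),
      cutoff = as.numeric(cutoff), learningAic = as.numeric(learningAic),
      provenance = provenance)
}

#' @describeIn SignatureModel-class signature gene identifiers.
#' @param object A `SignatureModel`.
#' @export
setGeneric("signatureGenes",
           function(object) standardGeneric("signatureGenes"))

#' @rdname SignatureModel-class
#' @export
setMethod("signatureGenes", "SignatureModel", function(object) object@genes)

#' @describeIn SignatureModel-class named coefficient vector.
#' @export
setGeneric("signatureBeta", function(object) standardGeneric("signatureBeta"))

#' @rdname SignatureModel-class
#' @export
setMethod("signatureBeta", "SignatureModel", function(object) object@beta)

#' @describeIn SignatureModel-class risk-score cutoff.
#' @export
setGeneric("signatureCutoff",
           function(object) standardGeneric("signatureCutoff"))

#' @rdname SignatureModel-class
#' @export
setMethod("signatureCutoff", "SignatureModel", function(object) object@cutoff)

setMethod("show", "SignatureModel", function(object) {
  cat("SignatureModel: ", length(object@genes), " genes; cutoff = ",
      format(object@cutoff, digits = 4), "; learning AIC = ",
      format(object@learningAic, digits = 6), "\n", sep = "")
  b <- sort(object@beta, decreasing = TRUE)
  cat("  ", paste(sprintf("%s=%+.3f", names(b), b), collapse = " "), "\n")
})

# -------------------------------------------------------------------------
# NullDistribution
# -------------------------------------------------------------------------

#' NullDistribution: a resampling null of random same-size signatures
#'
#' Stores the validation-set log-rank p-values of `B` random `k`-gene
#' signatures drawn from a gene universe, the observed signature's p-value
#' computed by the identical recipe, and the empirical significance (the
#' proportion of random signatures with p strictly below the observed p,
#' plus the `(1 + count)/(B + 1)` smoothed variant).
#'
#' @slot B Number of random signatures.
#' @slot k Signature size.
#' @slot universe Gene universe sampled from.
#' @slot nullP Numeric vector of B null p-values.
#' @slot observedP Observed signature's p-value.
#' @slot empiricalP Proportion of null p-values strictly below `observedP`.
#' @slot empiricalPSmoothed `(1 + count)/(B + 1)` variant.
#' @slot degenerate Number of random signatures whose learning fit failed
#'   (recorded with p = 1).
#' @slot seed Seed used for the resampling stream.
#' @export
setClass("NullDistribution",
         representation(B = "integer", k = "integer", universe = "character",
                        nullP = "numeric", observedP = "numeric",
                        empiricalP = "numeric",
                        empiricalPSmoothed = "numeric",
                        degenerate = "integer", seed = "integer"))

.validNullDistribution <- function(object) {
  msg <- character()
  if (length(object@nullP) != object@B) {
    msg <- c(msg, "nullP must have length B")
  }
  if (!is.na(object@empiricalP) &&
      (object@empiricalP < 0 || object@empiricalP > 1)) {
    msg <- c(msg, "empiricalP outside [0, 1]")
  }
  if (object@k > length(object@universe)) {
    msg <- c(msg, "k exceeds universe size")
  }
  if (length(msg)) msg else TRUE
}
setValidity("NullDistribution", .validNullDistribution)

#' @describeIn NullDistribution-class the vector of null p-values.
#' @param object A `NullDistribution`.
#' @export
setGeneric("nullPvalues", function(object) standardGeneric("nullPvalues"))

#' @rdname NullDistribution-class
#' @export
setMethod("nullPvalues", "NullDistribution", function(object) object@nullP)

#' @describeIn NullDistribution-class the empirical p (strict proportion).
#' @export
setGeneric("empiricalP", function(object) standardGeneric("empiricalP"))

#' @rdname NullDistribution-class
#' @export
setMethod("empiricalP", "NullDistribution", function(object) object@empiricalP)

setMethod("show", "NullDistribution", function(object) {
  cat("NullDistribution: B = ", object@B, ", k = ", object@k,
      ", |universe| = ", length(object@universe), "\n",
      "  observed p = ", format(object@observedP, digits = 4),
      "; empirical p = ", format(object@empiricalP, digits = 4),
      " (smoothed ", format(object@empiricalPSmoothed, digits = 4), ")\n",
      sep = "")
  if (object@degenerate > 0L) {
    cat("  ", object@degenerate, " degenerate resamples recorded at p = 1\n",
        sep = "")
  }
})

# -------------------------------------------------------------------------
# SimulatedCohort
# -------------------------------------------------------------------------

#' SimulatedCohort: a synthetic multi-study bundle with ground truth
#'
#' The output of [simulateCohort()]: a list of [ExpressionStudy-class]
#' objects (one per dataset), the pooled clinical table, and the truth
#' channel (per-sample true receptor classes/subtype/latent event and
#' censoring times; per-gene true log-hazard coefficients) used by
#' parameter-recovery tests.
#'
#' @slot studies List of `ExpressionStudy` objects.
#' @slot clinical data.frame clinical table (one row per sample).
#' @slot truth List with elements `samples` (data.frame) and `genes`
#'   (data.frame).
#' @slot config The [simConfig()] list used.
#' @export
setClass("SimulatedCohort",
         representation(studies = "list", clinical = "data.frame",
                        truth = "list", config = "list"))

setMethod("show", "SimulatedCohort", function(object) {
  cat("SimulatedCohort: ", length(object@studies), " studies, ",
      nrow(object@clinical), " samples, ",
      nrow(object@studies[[1]]), " genes (seed ", object@config$seed,
      ")\n", sep = "")
  st <- table(object@truth$samples$true_subtype)
  cat("  true subtypes:",
      paste(names(st), st, sep = "=", collapse = ", "), "\n")
})

#' @describeIn SimulatedCohort-class the list of per-dataset studies.
#' @param object A `SimulatedCohort`.
#' @export
setGeneric("studies", function(object) standardGeneric("studies"))

#' @rdname SimulatedCohort-class
#' @export
setMethod("studies", "SimulatedCohort", function(object) object@studies)

#' @describeIn SimulatedCohort-class the clinical table.
#' @export
setMethod("clinicalData", "SimulatedCohort",
          function(object) object@clinical)

#' @describeIn SimulatedCohort-class the ground-truth channel.
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname SimulatedCohort-class
#' @export
setMethod("groundTruth", "SimulatedCohort", function(object) object@truth)
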