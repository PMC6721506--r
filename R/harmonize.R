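# Cross-study harmonization: probe collapsing, luminal-A-anchored
# z-scoring, bimodal receptor calling, subtype assignment, cohort pooling,
# and analysis-subgroup selection.

#' Collapse probes to genes by maximal variance
#'
#' When several probes map to the same gene, the probe with the highest
#' sample variance in that dataset is retained (missing values excluded
#' from the variance). Exact variance ties are broken by the
#' lexicographically smaller probe id, with a warning.
#'
#' @param study An [ExpressionStudy-class] at probe level.
#' @return A gene-level [ExpressionStudy-class]; the chosen probe id per
#'   gene is recorded in `rowData` column `probe_id`.
#' @export
collapseProbes <- function(study) {
  stopifnot(is(study, "ExpressionStudy"))
  if (ncol(study) < 2L) stop("at least 2 samples required")
  x <- exprs(study)
  geneId <- rowData(study)$gene_id
  if (anyNA(geneId)) stop("probe map does not cover all rows")
  v <- apply(x, 1L, stats::var, na.rm = TRUE)
  v[is.na(v)] <- 0
  ord <- order(geneId, -v, rowData(study)$probe_id, method = "radix")
  keep <- ord[!duplicated(geneId[ord])]
  dup <- geneId %in% geneId[duplicated(geneId)]
  if (any(dup)) {
    tied <- vapply(split(v[dup], geneId[dup]), function(vv) {
      length(vv) > 1L && sum(vv == max(vv)) > 1L
    }, logical(1))
    if (any(tied)) {
      warning("variance tie for gene(s) ",
              paste(names(tied)[tied], collapse = ", "),
              "; first probe id retained")
    }
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- geneId[keep]
  ExpressionStudy(out, platform = platform(study),
                  datasetId = datasetId(study),
                  probeMap = stats::setNames(geneId[keep], geneId[keep])) ->
    res
  rowData(res)$probe_id <- rowData(study)$probe_id[keep]
  res
}

#' Z-score a study against luminal-A-like anchor samples
#'
#' Each gene is transformed as `(x - m) / s`, with `m` and `s` the mean and
#' SD of that gene over the study's anchor samples, so that anchors have
#' per-gene mean 0 and SD 1 and affine per-dataset batch distortion
#' cancels.
#'
#' @param study A gene-level [ExpressionStudy-class].
#' @param anchorIds Sample ids of the anchor (luminal-A-like) samples.
#' @param minAnchors Minimum anchors required before falling back to
#'   all-sample moments (default 3).
#' @param hardFail If `TRUE`, too few anchors is an error instead of a
#'   logged fallback.
#' @return An [ExpressionStudy-class] of z-scores.
#' @export
zscoreByAnchor <- function(study, anchorIds, minAnchors = 3L,
                           hardFail = FALSE) {
  stopifnot(is(study, "ExpressionStudy"))
  x <- exprs(study)
  anchorIds <- intersect(anchorIds, colnames(x))
  if (length(anchorIds) < minAnchors) {
    if (hardFail) {
      stop("study ", datasetId(study), " has fewer than ", minAnchors,
           " anchor samples")
    }
    tkLog("study ", datasetId(study), ": only ", length(anchorIds),
          " anchors; falling back to all-sample moments")
    anchorIds <- colnames(x)
  }
  a <- x[, anchorIds, drop = FALSE]
  m <- rowMeans(a, na.rm = TRUE)
  s <- apply(a, 1L, stats::sd, na.rm = TRUE)
  zeroSd <- !is.na(s) & s == 0
  if (any(zeroSd)) {
    tkLog("study ", datasetId(study), ": ", sum(zeroSd),
          " gene(s) with zero anchor SD; using all-sample SD")
    s[zeroSd] <- apply(x[zeroSd, , drop = FALSE], 1L, stats::sd,
                       na.rm = TRUE)
    s[!is.na(s) & s == 0] <- 1  # fully constant gene: centre only
  }
  z <- (x - m) / s
  res <- ExpressionStudy(z, platform = platform(study),
                         datasetId = datasetId(study))
  rowData(res)$probe_id <- rowData(study)$probe_id
  res
}

# Posterior-0.5 crossing between two Gaussian components.
.gmmCrossing <- function(m, s, w) {
  o <- order(m)
  m <- m[o]; s <- s[o]; w <- w[o]
  f <- function(x) {
    w[1] * stats::dnorm(x, m[1], s[1]) - w[2] * stats::dnorm(x, m[2], s[2])
  }
  # f > 0 near m[1], < 0 near m[2] when components are separated
  if (f(m[1]) <= 0 || f(m[2]) >= 0) return(mean(m))
  stats::uniroot(f, lower = m[1], upper = m[2], tol = 1e-9)$root
}

# Deepest kernel-density valley between the two largest modes.
.kdeValley <- function(values) {
  d <- stats::density(values, na.rm = TRUE)
  y <- d$y
  n <- length(y)
  isMax <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
  if (length(isMax) < 2L) return(NULL)
  top2 <- sort(isMax[order(y[isMax], decreasing = TRUE)][1:2])
  seg <- seq(top2[1], top2[2])
  valley <- seg[which.min(y[seg])]
  if (valley %in% top2) return(NULL)
  d$x[valley]
}

#' Call receptor status from bimodal expression
#'
#' Fits a two-component Gaussian mixture to one gene's expression values in
#' one dataset and places the positive/negative cutpoint at the point
#' between the component means where posterior membership is 0.5. If the
#' mixture is degenerate (a component weight below 0.05 or a
#' mean-separation below half the pooled SD) the deepest kernel-density
#' valley between the two largest modes is used instead. Calls are
#' `"positive"` for values strictly above the cutpoint.
#'
#' @param values Named numeric vector: one gene's expression per sample in
#'   one dataset (log2 or z units).
#' @param method `"gmm"` (default) or `"kde_valley"`.
#' @param cutpoint Optional manual cutpoint overriding estimation.
#' @return List with `threshold` (list: cutpoint, method, mixture
#'   parameters) and `calls` (character vector `"positive"`/`"negative"`
#'   named by sample).
#' @export
callReceptor <- function(values, method = c("gmm", "kde_valley"),
                         cutpoint = NULL) {
  method <- match.arg(method)
  vals <- values[is.finite(values)]
  if (is.null(cutpoint)) {
    if (length(vals) < 20L) stop("at least 20 samples required")
    if (stats::sd(vals) == 0) stop("not bimodal")
    mix <- NULL
    if (method == "gmm") {
      fit <- tryCatch(
        mclust::Mclust(vals, G = 2, modelNames = "V", verbose = FALSE),
        error = function(e) NULL)
      if (!is.null(fit)) {
        p <- fit$parameters
        mns <- as.numeric(p$mean)
        sds <- sqrt(as.numeric(p$variance$sigmasq))
        sds <- rep_len(sds, 2L)
        w <- as.numeric(p$pro)
        pooled <- sqrt(mean(sds^2))
        degenerate <- min(w) < 0.05 ||
          abs(diff(mns)) / pooled < 0.5
        if (!degenerate) {
          cutpoint <- .gmmCrossing(mns, sds, w)
          mix <- list(means = sort(mns), sds = sds[order(mns)],
                      weight = w[order(mns)][1])
        }
      }
    }
    if (is.null(cutpoint)) {
      cutpoint <- .kdeValley(vals)
      if (is.null(cutpoint)) stop("not bimodal")
      method <- "kde_valley"
    }
  } else {
    method <- "manual"
  }
  calls <- ifelse(values > cutpoint, "positive", "negative")
  names(calls) <- names(values)
  list(threshold = list(cutpoint = cutpoint, method = method,
                        mixture = if (exists("mix", inherits = FALSE))
                          mix else NULL),
       calls = calls)
}

#' Assign molecular subtype from receptor calls
#'
#' `ERBB2+` if ERBB2 is positive; `ER+/ERBB2-` if ERBB2 is negative and ER
#' or PR is positive; `TN` if all three are negative. Samples with a
#' missing call get `NA` and are logged.
#'
#' @param er,pr,erbb2 Character vectors of `"positive"`/`"negative"` calls
#'   (or logicals, `TRUE` = positive).
#' @return Factor with levels `TN`, `ER+/ERBB2-`, `ERBB2+`.
#' @export
assignSubtype <- function(er, pr, erbb2) {
  toL <- function(v) if (is.logical(v)) v else v == "positive"
  erL <- toL(er); prL <- toL(pr); e2L <- toL(erbb2)
  out <- ifelse(e2L, "ERBB2+",
                ifelse(erL | prL, "ER+/ERBB2-", "TN"))
  out[is.na(erL) | is.na(prL) | is.na(e2L)] <- NA
  nas <- is.na(out)
  if (any(nas)) {
    tkLog(sum(nas), " sample(s) with missing receptor call excluded from ",
          "subtype assignment")
  }
  factor(out, levels = c("TN", "ER+/ERBB2-", "ERBB2+"))
}

#' Assemble a harmonized multi-study cohort
#'
#' Runs the per-study pipeline — probe collapsing, per-dataset receptor
#' calling on the raw log2 values, luminal-A-anchored z-scoring — then
#' pools the studies over their common gene set into a [TKCohort-class].
#' Anchor samples are taken from `anchorIds` when supplied (e.g. the
#' generator's truth channel or user labels); otherwise a documented
#' heuristic is used: samples called ER- or PR-positive and
#' ERBB2-negative in their dataset.
#'
#' @param studyList List of [ExpressionStudy-class] objects.
#' @param clinical Clinical data.frame with a `sample_id` column covering
#'   all study samples.
#' @param anchorIds Optional character vector of anchor sample ids.
#' @param receptorGenes Length-3 character: the ER, PR and ERBB2
#'   transcripts (default `ESR1`, `PGR`, `ERBB2`).
#' @param method Receptor-calling method, see [callReceptor()].
#' @return A [TKCohort-class]; receptor thresholds per dataset are stored
#'   in `metadata(cohort)$receptor_thresholds`.
#' @export
buildCohort <- function(studyList, clinical, anchorIds = NULL,
                        receptorGenes = c("ESR1", "PGR", "ERBB2"),
                        method = "gmm") {
  stopifnot(length(studyList) >= 1L, "sample_id" %in% colnames(clinical))
  studyList <- lapply(studyList, collapseProbes)
  geneSets <- lapply(studyList, rownames)
  genes <- sort(Reduce(intersect, geneSets))
  if (length(genes) == 0L) stop("no genes common to all studies")

  callsList <- list()
  thresholds <- list()
  zList <- list()
  for (st in studyList) {
    ds <- datasetId(st)
    x <- exprs(st)
    calls <- list()
    for (i in seq_along(receptorGenes)) {
      rg <- receptorGenes[i]
      if (!rg %in% rownames(x)) {
        stop("receptor gene ", rg, " absent from study ", ds)
      }
      cr <- callReceptor(x[rg, ], method = method)
      calls[[rg]] <- cr$calls
      thresholds[[ds]][[rg]] <- cr$threshold
    }
    df <- data.frame(sample_id = colnames(x),
                     er_call = unname(calls[[receptorGenes[1]]]),
                     pr_call = unname(calls[[receptorGenes[2]]]),
                     erbb2_call = unname(calls[[receptorGenes[3]]]),
                     stringsAsFactors = FALSE)
    callsList[[ds]] <- df

    anch <- if (!is.null(anchorIds)) {
      intersect(anchorIds, colnames(x))
    } else {
      df$sample_id[(df$er_call == "positive" |
                      df$pr_call == "positive") &
                     df$erbb2_call == "negative"]
    }
    zList[[ds]] <- zscoreByAnchor(st, anch)
    colData(zList[[ds]])$anchor <- colnames(x) %in% anch
  }

  z <- do.call(cbind, lapply(zList, function(s) exprs(s)[genes, ,
                                                         drop = FALSE]))
  calls <- do.call(rbind, callsList)
  anchorFlag <- unlist(lapply(zList, function(s) colData(s)$anchor),
                       use.names = FALSE)
  cd <- data.frame(sample_id = colnames(z), stringsAsFactors = FALSE)
  cd$dataset_id <- rep(vapply(studyList, datasetId, character(1)),
                       vapply(studyList, ncol, integer(1)))
  cd$platform <- rep(vapply(studyList, platform, character(1)),
                     vapply(studyList, ncol, integer(1)))
  idx <- match(cd$sample_id, calls$sample_id)
  cd$er_call <- calls$er_call[idx]
  cd$pr_call <- calls$pr_call[idx]
  cd$erbb2_call <- calls$erbb2_call[idx]
  cd$subtype <- assignSubtype(cd$er_call, cd$pr_call, cd$erbb2_call)
  cd$anchor <- anchorFlag
  cidx <- match(cd$sample_id, clinical$sample_id)
  for (col in setdiff(colnames(clinical),
                      c("sample_id", "dataset_id", "platform"))) {
    cd[[col]] <- clinical[[col]][cidx]
  }
  rownames(cd) <- cd$sample_id

  se <- SummarizedExperiment(
    assays = list(z = z), colData = as(cd, "DataFrame"),
    metadata = list(receptor_thresholds = thresholds))
  new("TKCohort", se)
}

#' Select an analysis subgroup with informative survival
#'
#' Retains samples of the requested molecular subtype whose requested
#' endpoint has a positive, non-missing time and a non-missing event
#' indicator.
#'
#' @param cohort A [TKCohort-class].
#' @param subtype Subtype label to keep (default `"TN"`); `"all"` keeps
#'   every subtype, `"non_tn"` keeps everything except TN.
#' @param endpoint `"dfs"` or `"os"`.
#' @return The filtered [TKCohort-class].
#' @export
selectSubgroup <- function(cohort, subtype = "TN",
                           endpoint = c("dfs", "os")) {
  endpoint <- match.arg(endpoint)
  cd <- colData(cohort)
  keepSub <- switch(subtype,
                    all = rep(TRUE, ncol(cohort)),
                    non_tn = !is.na(cd$subtype) & cd$subtype != "TN",
                    !is.na(cd$subtype) & cd$subtype == subtype)
  sv <- survivalData(cohort, endpoint)
  keep <- keepSub & !is.na(sv$time) & sv$time > 0 & !is.na(sv$event)
  tkLog("selectSubgroup: ", sum(keep), " of ", ncol(cohort),
        " samples retained (subtype=", subtype, ", endpoint=", endpoint,
        ")")
  if (!any(keep)) stop("no samples match subtype '", subtype,
                       "' with informative ", endpoint)
  cohort[, keep]
}
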