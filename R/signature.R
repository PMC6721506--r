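# Signature discovery: platform-stratified cohort split, AIC stepwise
# selection over the screened candidates, the median-cutoff two-class risk
# classifier, and its evaluation.

#' Stratified learning/validation split
#'
#' Randomly assigns samples to a learning and a validation set in the
#' given proportions, stratified by platform so that both technologies are
#' represented in each set in close to their global shares.
#'
#' @param sampleIds Character vector of sample ids.
#' @param stratum Per-sample stratum (e.g. platform tag), same length.
#' @param fractions Length-2 proportions summing to 1 (default 2/3, 1/3).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List of class `tkSplit`: `learning`, `validation` (id vectors),
#'   `fractions`, `seed`, `hash` (a digest of the sorted learning set used
#'   to detect split mismatches downstream).
#' @export
splitCohort <- function(sampleIds, stratum = NULL, fractions = c(2, 1) / 3,
                        seed = 1L) {
  n <- length(sampleIds)
  stopifnot(n >= 10L, abs(sum(fractions) - 1) < 1e-8)
  if (is.null(stratum)) stratum <- rep("all", n)
  stopifnot(length(stratum) == n)
  learning <- character()
  withSeed(seed, {
    for (lev in sort(unique(stratum))) {
      ids <- sampleIds[stratum == lev]
      if (length(ids) < 2L) {
        warning("stratum '", lev, "' has < 2 samples; assigned to learning")
        learning <- c(learning, ids)
        next
      }
      nL <- round(fractions[1] * length(ids))
      nL <- min(max(nL, 1L), length(ids) - 1L)
      learning <- c(learning, sample(ids, nL))
    }
  })
  validation <- setdiff(sampleIds, learning)
  res <- list(learning = sort(learning), validation = sort(validation),
              fractions = fractions, seed = as.integer(seed),
              hash = splitHash(sort(learning)))
  class(res) <- "tkSplit"
  tkLog("splitCohort: learning ", length(res$learning), ", validation ",
        length(res$validation))
  res
}

# Digest of a sorted id vector; used to tie a signature to its split.
splitHash <- function(ids) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(ids, f)
  unname(tools::md5sum(f))
}

#' AIC stepwise gene selection for a Cox model
#'
#' Bidirectional greedy search starting from the full candidate model. At
#' each step every single-gene deletion and (re-)addition is evaluated and
#' the move with the largest AIC decrease is applied; the search stops when
#' no move decreases the AIC. Ties in AIC decrease prefer deletion over
#' addition, then lexicographic gene order, so the search is
#' deterministic. Non-convergent intermediate fits are skipped with a
#' warning. The full move trace is recorded in the model provenance.
#'
#' @param time,event Learning-set follow-up and event vectors.
#' @param x Gene x sample z-score matrix (learning set).
#' @param candidates Candidate gene identifiers (typically the screen's
#'   passing set).
#' @return A [SignatureModel-class] with fitted coefficients and learning
#'   AIC (no cutoff yet; see [buildClassifier()]).
#' @export
stepwiseAic <- function(time, event, x, candidates) {
  if (length(candidates) == 0L) stop("no candidate genes")
  stopifnot(all(candidates %in% rownames(x)))
  candidates <- sort(candidates)
  y <- survival::Surv(time, event)
  ctrl <- survival::coxph.control(iter.max = 50, eps = 1e-9)
  # fast partial-likelihood evaluator for the move search; the final model
  # is refitted through coxFit() for full Wald statistics
  fitSet <- function(genes) {
    if (length(genes) == 0L) {
      f <- suppressWarnings(coxFit(time, event,
                                   data.frame(g = x[candidates[1], ])))
      return(list(aic = -2 * f$loglik0, ok = TRUE))
    }
    X <- t(x[genes, , drop = FALSE])
    f <- tryCatch(
      survival::coxph.fit(X, y, strata = NULL, offset = NULL,
                          init = NULL, control = ctrl, weights = NULL,
                          method = "efron", rownames = rownames(X)),
      error = function(e) NULL)
    if (is.null(f) || any(!is.finite(f$coefficients)) ||
        any(abs(f$coefficients) > 15)) {
      return(list(aic = Inf, ok = FALSE))
    }
    list(aic = -2 * f$loglik[2] + 2 * length(genes), ok = TRUE)
  }
  current <- candidates
  cur <- fitSet(current)
  if (!cur$ok || !is.finite(cur$aic)) {
    stop("full candidate model did not converge")
  }
  trace <- data.frame(step = 0L, action = "start",
                      gene = NA_character_, aic = cur$aic,
                      size = length(current), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    step <- step + 1L
    moves <- rbind(
      if (length(current)) data.frame(action = "drop", gene = sort(current),
                                      stringsAsFactors = FALSE),
      if (length(setdiff(candidates, current)))
        data.frame(action = "add", gene = sort(setdiff(candidates, current)),
                   stringsAsFactors = FALSE))
    if (is.null(moves) || nrow(moves) == 0L) break
    aics <- rep(Inf, nrow(moves))
    for (j in seq_len(nrow(moves))) {
      genes <- if (moves$action[j] == "drop") {
        setdiff(current, moves$gene[j])
      } else c(current, moves$gene[j])
      fj <- fitSet(genes)
      if (!fj$ok) {
        warning("move ", moves$action[j], " ", moves$gene[j],
                " skipped (non-convergent fit)")
        next
      }
      aics[j] <- fj$aic
    }
    best <- min(aics)
    if (!(best < cur$aic - 1e-8)) break
    # deterministic tie-break: deletion first, then gene order (moves are
    # already listed drops-first in sorted gene order)
    j <- which(aics <= best + 1e-8)[1]
    current <- if (moves$action[j] == "drop") {
      setdiff(current, moves$gene[j])
    } else sort(c(current, moves$gene[j]))
    cur <- fitSet(current)
    trace <- rbind(trace, data.frame(step = step, action = moves$action[j],
                                     gene = moves$gene[j], aic = cur$aic,
                                     size = length(current),
                                     stringsAsFactors = FALSE))
    if (step > 10L * length(candidates)) break
  }
  if (length(current) == 0L) {
    stop("stepwise search removed all genes (no model beats the null AIC)")
  }
  final <- suppressWarnings(
    coxFit(time, event, as.data.frame(t(x[current, , drop = FALSE]))))
  SignatureModel(genes = current, beta = final$beta[current],
                 learningAic = final$aic,
                 provenance = list(candidates = candidates,
                                   trace = trace))
}

#' Per-sample risk score of a signature
#'
#' The Cox linear predictor `sum_g beta_g * z_gi`.
#'
#' @param model A [SignatureModel-class].
#' @param x Gene x sample z-score matrix containing all signature genes.
#' @return Named numeric vector of scores; samples with a missing
#'   signature-gene value get `NA` with a log entry.
#' @export
riskScore <- function(model, x) {
  genes <- signatureGenes(model)
  miss <- setdiff(genes, rownames(x))
  if (length(miss)) {
    stop("matrix lacks signature gene(s): ", paste(miss, collapse = ", "))
  }
  sc <- drop(crossprod(x[genes, , drop = FALSE], signatureBeta(model)))
  if (anyNA(sc)) {
    tkLog("riskScore: ", sum(is.na(sc)),
          " sample(s) with missing signature values excluded")
  }
  sc
}

#' Fix the risk-score cutoff on the learning set
#'
#' The classifier dichotomizes the risk score at the median learning-set
#' score: `high-risk` strictly above the cutoff, `low-risk` otherwise.
#'
#' @param model A [SignatureModel-class] with fitted coefficients.
#' @param x Learning-set gene x sample z-score matrix.
#' @return The model with `cutoff` set and the learning scores stored in
#'   provenance.
#' @export
buildClassifier <- function(model, x) {
  if (all(signatureBeta(model) == 0)) stop("null signature")
  sc <- riskScore(model, x)
  cutoff <- stats::median(sc, na.rm = TRUE)
  model@cutoff <- cutoff
  model@provenance$learning_n <- sum(!is.na(sc))
  model
}

#' Classify samples into risk classes
#'
#' @param model A [SignatureModel-class] with a cutoff.
#' @param x Gene x sample z-score matrix.
#' @return Factor with levels `low-risk`, `high-risk` (`high-risk` iff
#'   score > cutoff).
#' @export
classifyRisk <- function(model, x) {
  if (is.na(signatureCutoff(model))) {
    stop("model has no cutoff; run buildClassifier() first")
  }
  sc <- riskScore(model, x)
  factor(ifelse(sc > signatureCutoff(model), "high-risk", "low-risk"),
         levels = c("low-risk", "high-risk"))
}

#' Evaluate a risk classifier on a sample set
#'
#' Kaplan-Meier estimates per class with 95% CI at five years (60 months),
#' median survival per class, the two-group log-rank test, and a
#' univariate Cox model of the class (hazard ratio for high- vs low-risk).
#'
#' @param model A [SignatureModel-class] with a cutoff.
#' @param time,event Follow-up and event vectors (aligned to matrix
#'   columns).
#' @param x Gene x sample z-score matrix of the evaluation set.
#' @return List of class `tkEvaluation`: `classes`, `km` (per class),
#'   `fiveYear` (data.frame), `median` (named vector), `logrank`, `cox`
#'   (the binary-class fit), `hrText`.
#' @export
evaluateClassifier <- function(model, time, event, x) {
  cls <- classifyRisk(model, x)
  keep <- !is.na(cls) & !is.na(time) & !is.na(event)
  cls <- cls[keep]; time <- time[keep]; event <- event[keep]
  if (any(table(cls) == 0)) stop("one risk class is empty")
  km <- lapply(split(seq_along(cls), cls), function(i) {
    kmFit(time[i], event[i])
  })
  fy <- do.call(rbind, lapply(names(km), function(g) {
    s <- survivalAt(km[[g]], 60)
    data.frame(class = g, surv5y = s$surv, lower = s$lower,
               upper = s$upper, stringsAsFactors = FALSE)
  }))
  lr <- logrankTest(time, event, cls)
  cx <- suppressWarnings(
    coxFit(time, event, data.frame(highRisk = as.integer(cls ==
                                                           "high-risk"))))
  res <- list(classes = cls, km = km, fiveYear = fy,
              median = vapply(km, function(k) k$median, numeric(1)),
              logrank = lr, cox = cx,
              hrText = formatHR(cx$beta[1], cx$se[1]),
              n = length(cls))
  class(res) <- "tkEvaluation"
  res
}

#' @export
print.tkEvaluation <- function(x, ...) {
  cat("Risk-class evaluation (n =", x$n, "):\n")
  print(x$fiveYear, row.names = FALSE)
  cat("log-rank p =", format(x$logrank$p, digits = 3),
      "; HR high vs low =", x$hrText, "\n")
  invisible(x)
}
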