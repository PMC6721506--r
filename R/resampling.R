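# Resampling null: are random same-size gene signatures as prognostic as
# the observed one? Each random k-subset of the gene universe is run
# through the identical recipe used for the observed signature: Cox
# coefficients fitted on the learning set, median-cutoff classifier,
# validation-set two-group log-rank p-value.

#' Draw a uniform random k-gene signature
#'
#' @param universe Gene identifiers to draw from.
#' @param k Signature size.
#' @return Sorted character vector: a uniform k-subset without
#'   replacement. Uses the current RNG stream (seed it with
#'   [resamplingNull()] or `set.seed`).
#' @export
randomSignature <- function(universe, k) {
  if (k > length(universe)) stop("k exceeds the universe size")
  sort(sample(universe, k))
}

# Fast learning-fit + validation log-rank for one gene set. Returns the
# p-value with attribute "degenerate" when the learning fit fails.
.signatureValidationP <- function(genes, timeL, eventL, xL,
                                  timeV, eventV, xV) {
  XL <- t(xL[genes, , drop = FALSE])
  fit <- tryCatch(
    survival::coxph.fit(XL, survival::Surv(timeL, eventL),
                        strata = NULL, offset = NULL, init = NULL,
                        control = survival::coxph.control(iter.max = 25),
                        weights = NULL, method = "efron",
                        rownames = rownames(XL)),
    error = function(e) NULL)
  degenerate <- is.null(fit) || any(!is.finite(fit$coefficients)) ||
    any(abs(fit$coefficients) > 15)
  if (degenerate) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  beta <- fit$coefficients
  cutoff <- stats::median(drop(XL %*% beta))
  scoreV <- drop(crossprod(xV[genes, , drop = FALSE], beta))
  cls <- scoreV > cutoff
  if (all(cls) || !any(cls) || sum(eventV) == 0) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  sd <- survival::survdiff(survival::Surv(timeV, eventV) ~ cls)
  p <- stats::pchisq(sd$chisq, 1, lower.tail = FALSE)
  attr(p, "degenerate") <- FALSE
  p
}

#' Validation p-value of one gene signature under the null recipe
#'
#' Fits Cox coefficients for the given genes on the learning set, builds
#' the median-cutoff classifier, classifies the validation samples, and
#' returns the validation two-group log-rank p — the identical recipe used
#' to evaluate the observed signature. Non-convergent or degenerate fits
#' return p = 1 with a `degenerate` attribute (conservative).
#'
#' @param genes Gene identifiers.
#' @param timeL,eventL,xL Learning-set survival vectors and gene x sample
#'   z-score matrix.
#' @param timeV,eventV,xV Validation-set counterparts.
#' @return Numeric p-value with attribute `degenerate`.
#' @export
nullPvalue <- function(genes, timeL, eventL, xL, timeV, eventV, xV) {
  stopifnot(all(genes %in% rownames(xL)), all(genes %in% rownames(xV)))
  .signatureValidationP(genes, timeL, eventL, xL, timeV, eventV, xV)
}

#' Empirical significance of an observed p against a null set
#'
#' The headline value is the strict proportion of null p-values below the
#' observed p; the `(1 + count)/(B + 1)` smoothed variant avoids exact
#' zeros.
#'
#' @param observedP Observed signature's validation p-value.
#' @param nullP Numeric vector of null p-values (length >= 100 advised).
#' @return List with `empirical`, `smoothed`, and `quantile` (the null
#'   quantile of the observed p).
#' @export
empiricalSignificance <- function(observedP, nullP) {
  if (length(nullP) == 0L) stop("empty null distribution")
  cnt <- sum(nullP < observedP)
  list(empirical = cnt / length(nullP),
       smoothed = (1 + cnt) / (length(nullP) + 1),
       quantile = stats::ecdf(nullP)(observedP))
}

#' Resampling null distribution for an observed signature
#'
#' Draws `B` random `k`-gene signatures from the universe and computes each
#' one's validation p-value by [nullPvalue()]; the observed signature's
#' genes are run through the same recipe to give `observedP`.
#'
#' @param observedGenes The observed signature's gene list.
#' @param universe Gene universe (e.g. the 86-gene panel).
#' @param timeL,eventL,xL Learning-set survival vectors and z-score matrix.
#' @param timeV,eventV,xV Validation-set counterparts.
#' @param B Number of random signatures (default 10000).
#' @param k Signature size (default `length(observedGenes)`).
#' @param seed Integer seed for the resampling stream.
#' @return A [NullDistribution-class].
#' @export
resamplingNull <- function(observedGenes, universe,
                           timeL, eventL, xL, timeV, eventV, xV,
                           B = 10000L, k = length(observedGenes),
                           seed = 1L) {
  stopifnot(B >= 1L, all(observedGenes %in% rownames(xL)))
  if (k > length(universe)) stop("k exceeds the universe size")
  universe <- intersect(universe, rownames(xL))
  obs <- nullPvalue(observedGenes, timeL, eventL, xL, timeV, eventV, xV)
  nullP <- numeric(B)
  degen <- 0L
  withSeed(seed, {
    for (b in seq_len(B)) {
      g <- randomSignature(universe, k)
      p <- .signatureValidationP(g, timeL, eventL, xL, timeV, eventV, xV)
      if (isTRUE(attr(p, "degenerate"))) degen <- degen + 1L
      nullP[b] <- as.numeric(p)
    }
  })
  es <- empiricalSignificance(as.numeric(obs), nullP)
  new("NullDistribution", B = as.integer(B), k = as.integer(k),
      universe = universe, nullP = nullP, observedP = as.numeric(obs),
      empiricalP = es$empirical, empiricalPSmoothed = es$smoothed,
      degenerate = degen, seed = as.integer(seed))
}
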