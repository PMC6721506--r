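# Risk-class characterization: empirical-Bayes moderated t-test,
# Benjamini-Hochberg FDR, thresholded DE gene lists, the nearest-centroid
# correlation prediction score, generic metagene scoring, and
# class-vs-clinical association tests.

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used by the moment estimator of the variance prior.
trigammaInverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy)) return(Inf)
    if (yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    x <- 0.5 + 1 / yy
    for (i in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

# Moment-match the scaled-F distribution of sample variances on the log
# scale: returns the prior degrees of freedom d0 and prior variance s0sq.
.estimateVariancePrior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 10L) {
    warning("fewer than 10 positive variances; prior not estimable, ",
            "using d0 = Inf")
    return(list(d0 = Inf, s0sq = stats::median(s2[ok])))
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  eMean <- mean(e)
  eVar <- stats::var(e)
  excess <- eVar - trigamma(df / 2)
  if (excess <= 0) {
    # no excess dispersion beyond chi-square sampling noise: variances are
    # exchangeable, the prior is the average sample variance
    return(list(d0 = Inf, s0sq = mean(s2[ok])))
  }
  d0 <- 2 * trigammaInverse(excess)
  s0sq <- exp(eMean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0sq = s0sq)
}

#' Moderated t-test with empirical-Bayes variance shrinkage
#'
#' Two-group comparison in which each gene's pooled variance `s2_g` (with
#' `d = n1 + n2 - 2` degrees of freedom) is shrunk towards a prior
#' `(d0, s0sq)` estimated by moment-matching the distribution of
#' `log(s2_g)` through digamma/trigamma identities. The posterior variance
#' is `(d0*s0sq + d*s2_g)/(d0 + d)`, the moderated t is the mean
#' difference over its posterior standard error, and p-values use a t
#' reference with `d0 + d` degrees of freedom (`d0 = Inf` collapses all
#' variances to `s0sq` and a normal reference).
#'
#' The log fold change is `mean(group1) - mean(group2)` where `group1` is
#' the first factor level, so with levels `c("low-risk", "high-risk")` a
#' positive logFC means over-expressed in low-risk samples.
#'
#' @param x Gene x sample matrix (log2 scale).
#' @param labels Two-level factor aligned to columns.
#' @param prior Optional list `list(d0 = , s0sq = )` overriding the
#'   estimated prior; `d0 = 0` gives the ordinary pooled-variance t-test.
#' @return data.frame (one row per gene): `gene`, `logFC`, `s2`, `tMod`,
#'   `df`, `p`, `q` (BH), with the prior in `attr(, "prior")`.
#' @export
moderatedT <- function(x, labels, prior = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  i1 <- which(labels == levels(labels)[1])
  i2 <- which(labels == levels(labels)[2])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stop("at least 2 samples per class required")
  if (is.null(prior) && nrow(x) < 10L) {
    stop("at least 10 genes required to estimate the variance prior")
  }
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  v1 <- apply(x[, i1, drop = FALSE], 1L, stats::var)
  v2 <- apply(x[, i2, drop = FALSE], 1L, stats::var)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  if (is.null(prior)) prior <- .estimateVariancePrior(s2, d)
  d0 <- prior$d0; s0sq <- prior$s0sq
  s2post <- if (is.infinite(d0)) rep(s0sq, length(s2)) else
    (d0 * s0sq + d * s2) / (d0 + d)
  logFC <- m1 - m2
  tMod <- logFC / sqrt(s2post * (1 / n1 + 1 / n2))
  dfTotal <- d0 + d
  p <- 2 * stats::pt(-abs(tMod), df = dfTotal)
  res <- data.frame(gene = rownames(x), logFC = logFC, s2 = s2,
                    tMod = tMod, df = dfTotal, p = p,
                    q = bhFdr(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "prior") <- list(d0 = d0, s0sq = s0sq)
  attr(res, "levels") <- levels(labels)
  res
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values (monotone in the p-ranking, capped
#'   at 1).
#' @export
bhFdr <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Threshold a moderated-t result into up/down gene lists
#'
#' A gene is significant when `p < pMax`, `q < qMax`, and its linear fold
#' change exceeds `fcMin` (i.e. `|logFC| > log2(fcMin)`). Genes split by
#' logFC sign: positive logFC = over-expressed in the first class
#' (low-risk under the pipeline's convention).
#'
#' @param result A [moderatedT()] data.frame.
#' @param pMax,qMax,fcMin Thresholds (defaults 1e-2, 1e-2, 1.25).
#' @return List with `upInLow`, `upInHigh` (character vectors) and
#'   `thresholds`.
#' @export
deGeneList <- function(result, pMax = 1e-2, qMax = 1e-2, fcMin = 1.25) {
  sig <- !is.na(result$p) & result$p < pMax & result$q < qMax &
    abs(result$logFC) > log2(fcMin)
  up <- result$gene[sig & result$logFC > 0]
  dn <- result$gene[sig & result$logFC < 0]
  tkLog("deGeneList: ", sum(sig), " significant genes (", length(up),
        " up in first class, ", length(dn), " up in second)")
  list(upInLow = up, upInHigh = dn,
       thresholds = list(pMax = pMax, qMax = qMax, fcMin = fcMin))
}

#' Nearest-centroid correlation prediction score
#'
#' Computes, for each new sample, the correlation of its DE-gene profile
#' with the median profile (centroid) of the learning-set high-risk and
#' low-risk classes; the score is `r_high - r_low` and the predicted class
#' is high-risk when the score is positive. When known classes are
#' supplied for the new samples, a Welch t-test comparing the score
#' between classes is reported.
#'
#' @param xLearn Gene x sample matrix restricted to the DE genes (learning
#'   set).
#' @param classes Two-level factor (`low-risk`/`high-risk`) for the
#'   learning samples.
#' @param xNew Gene x sample matrix for the samples to score (same genes).
#' @param newClasses Optional known classes of the new samples.
#' @param method Correlation type: `"pearson"` (default) or
#'   `"spearman"`.
#' @return List of class `tkCentroidScore`: `score`, `rHigh`, `rLow`,
#'   `predicted`, `centroids`, and `tTest` (or `NULL`).
#' @export
centroidScore <- function(xLearn, classes, xNew, newClasses = NULL,
                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  classes <- factor(classes)
  if (nrow(xLearn) < 3L) stop("at least 3 genes required")
  stopifnot(identical(rownames(xLearn), rownames(xNew)))
  if (!all(c("low-risk", "high-risk") %in% levels(classes))) {
    stop("classes must contain 'low-risk' and 'high-risk'")
  }
  centHigh <- apply(xLearn[, classes == "high-risk", drop = FALSE], 1L,
                    stats::median, na.rm = TRUE)
  centLow <- apply(xLearn[, classes == "low-risk", drop = FALSE], 1L,
                   stats::median, na.rm = TRUE)
  sds <- apply(xNew, 2L, stats::sd, na.rm = TRUE)
  flat <- !is.finite(sds) | sds == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance sample profile(s); score undefined")
  }
  rHigh <- suppressWarnings(
    apply(xNew, 2L, stats::cor, y = centHigh, method = method,
          use = "pairwise.complete.obs"))
  rLow <- suppressWarnings(
    apply(xNew, 2L, stats::cor, y = centLow, method = method,
          use = "pairwise.complete.obs"))
  rHigh[flat] <- NA_real_; rLow[flat] <- NA_real_
  score <- rHigh - rLow
  predicted <- factor(ifelse(score > 0, "high-risk", "low-risk"),
                      levels = c("low-risk", "high-risk"))
  tt <- NULL
  if (!is.null(newClasses)) {
    newClasses <- factor(newClasses,
                         levels = c("low-risk", "high-risk"))
    tt <- stats::t.test(score[newClasses == "high-risk"],
                        score[newClasses == "low-risk"])
  }
  res <- list(score = score, rHigh = rHigh, rLow = rLow,
              predicted = predicted,
              centroids = cbind(high = centHigh, low = centLow),
              tTest = tt)
  class(res) <- "tkCentroidScore"
  res
}

#' @export
print.tkCentroidScore <- function(x, ...) {
  cat("Centroid correlation score: ", length(x$score), " samples; ",
      sum(x$predicted == "high-risk", na.rm = TRUE),
      " predicted high-risk\n", sep = "")
  if (!is.null(x$tTest)) {
    cat("  high vs low score t-test p =",
        format(x$tTest$p.value, digits = 3), "\n")
  }
  invisible(x)
}

#' Metagene score for a gene set
#'
#' The per-sample mean of the (optionally weighted) member-gene
#' expressions after z-scoring each gene across samples. Members absent
#' from the matrix are dropped with a log entry.
#'
#' @param x Gene x sample matrix.
#' @param genes Gene-set members.
#' @param weights Optional numeric weights aligned to `genes` (e.g. +/-1);
#'   default uniform.
#' @param setName Name used in messages.
#' @return Named numeric vector of per-sample scores.
#' @export
metageneScore <- function(x, genes, weights = NULL, setName = "set") {
  if (is.null(weights)) weights <- rep(1, length(genes))
  stopifnot(length(weights) == length(genes))
  present <- genes %in% rownames(x)
  if (!any(present)) {
    stop("gene set '", setName, "' has no overlap with the matrix")
  }
  if (any(!present)) {
    tkLog("metageneScore: ", sum(!present), " member(s) of '", setName,
          "' absent; dropped")
  }
  g <- genes[present]; w <- weights[present]
  z <- t(scale(t(x[g, , drop = FALSE])))
  z[is.nan(z)] <- 0  # constant gene: contributes nothing
  drop(crossprod(z, w)) / length(g)
}

#' Association tests between risk classes and clinical variables
#'
#' For each clinical variable, a Fisher's exact test (categorical) or a
#' Welch two-sample t-test (continuous) against the two risk classes.
#' Categorical tables too large for the exact network algorithm fall back
#' to a seeded Monte-Carlo p-value. Variables with a single observed
#' level are skipped with a note.
#'
#' @param classes Two-level factor of risk classes.
#' @param clinical data.frame of clinical variables aligned to `classes`.
#' @param mcB Monte-Carlo replicates for oversized tables (default 1e5).
#' @return List with `summary` (data.frame: variable, test, p) and
#'   `tables` (per-variable count/percentage matrices for categorical
#'   variables).
#' @export
associationTests <- function(classes, clinical, mcB = 1e5) {
  classes <- factor(classes)
  stopifnot(nrow(clinical) == length(classes))
  rows <- list(); tables <- list()
  for (v in colnames(clinical)) {
    val <- clinical[[v]]
    ok <- !is.na(val) & !is.na(classes)
    if (is.numeric(val) && length(unique(val[ok])) > 5L) {
      tt <- stats::t.test(val[ok] ~ classes[ok])
      rows[[v]] <- data.frame(variable = v, test = "welch_t",
                              p = tt$p.value, stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(val[ok]), classes[ok])
      if (nrow(tab) < 2L) {
        tkLog("associationTests: '", v, "' has a single level; skipped")
        next
      }
      ft <- tryCatch(stats::fisher.test(tab),
                     error = function(e) stats::fisher.test(
                       tab, simulate.p.value = TRUE, B = mcB))
      rows[[v]] <- data.frame(variable = v, test = "fisher",
                              p = ft$p.value, stringsAsFactors = FALSE)
      pct <- round(100 * sweep(tab, 2L, colSums(tab), "/"))
      tables[[v]] <- list(counts = tab, percent = pct)
    }
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       tables = tables)
}
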