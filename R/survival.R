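# Survival statistics: Kaplan-Meier with log-log Greenwood bands, two-group
# log-rank test, Cox proportional-hazards fitting with Wald tests and AIC,
# and the per-gene univariate screen. The numerical engine is the
# `survival` package (Efron tie handling throughout); this module defines
# the pipeline's surfaces and result containers.

#' Kaplan-Meier estimate with Greenwood log-log 95% bands
#'
#' @param time Positive follow-up times (months).
#' @param event Event indicators (0/1).
#' @return A list of class `tkKM`: `times` (distinct event times), `surv`,
#'   `lower`/`upper` (log-log transformed Greenwood 95% CI), `median`
#'   (smallest time with S(t) <= 0.5, `NA` if never reached), `n`,
#'   `nEvents`, and the underlying `survfit` object.
#' @export
kmFit <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L)
  if (any(is.na(time)) || any(is.na(event))) stop("missing time/event")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log")
  ev <- fit$n.event > 0
  # median: smallest event time with S(t) <= 0.5, NA if never reached
  below <- fit$time[ev][fit$surv[ev] <= 0.5]
  res <- list(times = fit$time[ev], surv = fit$surv[ev],
              lower = fit$lower[ev], upper = fit$upper[ev],
              median = if (length(below)) min(below) else NA_real_,
              n = length(time), nEvents = sum(event), survfit = fit)
  class(res) <- "tkKM"
  res
}

#' @export
print.tkKM <- function(x, ...) {
  cat("Kaplan-Meier estimate: n =", x$n, ", events =", x$nEvents,
      ", median =", ifelse(is.na(x$median), "not reached", x$median), "\n")
  invisible(x)
}

#' Survival probability (and CI) at given times by step lookup
#'
#' @param km A [kmFit()] result.
#' @param at Times (months) at which to evaluate the step function.
#' @return data.frame with columns `time`, `surv`, `lower`, `upper`.
#' @export
survivalAt <- function(km, at) {
  s <- summary(km$survfit, times = at, extend = TRUE)
  data.frame(time = s$time, surv = s$surv, lower = s$lower,
             upper = s$upper)
}

#' Two-group log-rank test
#'
#' @param time,event Follow-up and event vectors.
#' @param group Two-level grouping factor/vector.
#' @return List with `chisq`, `df`, and `p` (chi-square reference).
#' @export
logrankTest <- function(time, event, group) {
  grp <- factor(group)
  if (nlevels(grp) < 2L) stop("two non-empty groups required")
  if (sum(event) == 0) stop("no events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  df <- length(sd$n) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit with Wald statistics and AIC
#'
#' Efron-handled ties; separation (monotone likelihood) is detected when
#' any |beta| exceeds 15 and reported as a flagged, non-converged fit with
#' its degenerate hazard ratio rather than an error, mirroring how such
#' fits are displayed in prognostic tables.
#'
#' @param time,event Follow-up and event vectors.
#' @param covariates data.frame or matrix of covariates (rows = samples).
#' @return A list of class `CoxFit`: `beta`, `se`, `z`, `p` (two-sided
#'   Wald), `hr`, `ci` (95% matrix), `loglik` (maximized log partial
#'   likelihood), `loglik0` (null), `aic` (= -2 loglik + 2k), `n`,
#'   `nEvents`, `converged`.
#' @export
coxFit <- function(time, event, covariates) {
  X <- as.data.frame(covariates)
  stopifnot(nrow(X) == length(time))
  clash <- colnames(X) %in% c("time", "event")
  if (any(clash)) colnames(X)[clash] <- paste0(colnames(X)[clash], "_cov")
  cc <- stats::complete.cases(X) & !is.na(time) & !is.na(event)
  if (!all(cc)) {
    tkLog("coxFit: ", sum(!cc), " incomplete row(s) dropped")
    X <- X[cc, , drop = FALSE]; time <- time[cc]; event <- event[cc]
  }
  if (sum(event) == 0) stop("at least one event required")
  const <- vapply(X, function(v) length(unique(v[!is.na(v)])) < 2L,
                  logical(1))
  if (any(const)) {
    stop("constant covariate(s): ",
         paste(colnames(X)[const], collapse = ", "))
  }
  k <- ncol(X)
  if (sum(event) < k + 1) {
    warning("fewer events (", sum(event), ") than covariates + 1 (",
            k + 1, ")")
  }
  converged <- TRUE
  fml <- survival::Surv(time, event) ~ .
  environment(fml) <- environment()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = X, ties = "efron",
                    control = survival::coxph.control(iter.max = 50,
                                                      eps = 1e-9)),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite",
                conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(abs(beta) > 15)) {
    converged <- FALSE
    warning("separation detected: |beta| > 15; hazard ratio is degenerate")
  }
  z <- beta / se
  zq <- stats::qnorm(0.975)
  res <- list(beta = beta, se = se, z = z,
              p = 2 * stats::pnorm(-abs(z)),
              hr = exp(beta),
              ci = cbind(lower = exp(beta - zq * se),
                         upper = exp(beta + zq * se)),
              loglik = fit$loglik[2], loglik0 = fit$loglik[1],
              aic = -2 * fit$loglik[2] + 2 * k,
              n = fit$n, nEvents = fit$nevent, converged = converged)
  class(res) <- "CoxFit"
  res
}

#' @export
print.CoxFit <- function(x, ...) {
  cat("Cox fit: n =", x$n, ", events =", x$nEvents,
      ", AIC =", format(x$aic, digits = 6),
      if (!x$converged) "(NOT converged)", "\n")
  for (i in seq_along(x$beta)) {
    cat(sprintf("  %-12s HR %s  p = %.3g\n", names(x$beta)[i],
                formatHR(x$beta[i], x$se[i]), x$p[i]))
  }
  invisible(x)
}

#' Univariate Cox screen over a gene matrix
#'
#' Fits one single-covariate Cox model per gene on its continuous z-scored
#' expression and returns all fits plus the genes passing the Wald
#' threshold, sorted by p-value.
#'
#' @param time,event Follow-up and event vectors (aligned to matrix
#'   columns).
#' @param x Gene x sample matrix of z-scores.
#' @param alpha Wald p-value threshold (default 0.05; genes with p <=
#'   alpha pass).
#' @return List with `table` (data.frame: gene, beta, se, hr, lower,
#'   upper, z, p, ordered by p) and `passing` (character vector).
#' @export
univariateScreen <- function(time, event, x, alpha = 0.05) {
  stopifnot(ncol(x) == length(time))
  rows <- vector("list", nrow(x))
  genes <- rownames(x)
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    if (any(!is.finite(v))) {
      warning("gene ", genes[i], " has non-finite values; skipped")
      next
    }
    f <- tryCatch(
      suppressWarnings(coxFit(time, event,
                              stats::setNames(data.frame(v), "expr"))),
      error = function(e) NULL)
    if (is.null(f)) next
    rows[[i]] <- data.frame(
      gene = genes[i], beta = unname(f$beta), se = unname(f$se),
      hr = unname(f$hr), lower = unname(f$ci[, "lower"]),
      upper = unname(f$ci[, "upper"]), z = unname(f$z),
      p = unname(f$p), converged = f$converged,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(gene = character(), p = numeric())
  tab <- tab[order(tab$p), , drop = FALSE]
  rownames(tab) <- NULL
  passing <- tab$gene[!is.na(tab$p) & tab$p <= alpha & tab$converged]
  tkLog("univariateScreen: ", length(passing), " of ", nrow(x),
        " genes pass at alpha = ", alpha)
  list(table = tab, passing = passing)
}

#' Select variables for a multivariate model
#'
#' Retains, in input order, the variables whose univariate p-value is
#' strictly below the entry threshold.
#'
#' @param p Named numeric vector of univariate p-values.
#' @param threshold Entry threshold (default 0.10).
#' @return Character vector of retained variable names.
#' @export
selectMultivariate <- function(p, threshold = 0.10) {
  stopifnot(!is.null(names(p)))
  keep <- names(p)[!is.na(p) & p < threshold]
  if (length(keep) == 0L) warning("no multivariate model")
  keep
}
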