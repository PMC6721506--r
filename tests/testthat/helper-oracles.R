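# Independent oracles used to check the pipeline's statistics. These are
# deliberately naive implementations (enumeration, grid search, hand
# formulas) and never share code with the package.

# Cox partial log-likelihood for a single covariate, no tied event times.
oracleCoxLoglik <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Grid-search MLE of the single-covariate Cox model.
oracleCoxGrid <- function(time, event, x, lo = -4, hi = 4, by = 1e-4) {
  grid <- seq(lo, hi, by = by)
  ll <- vapply(grid, oracleCoxLoglik, numeric(1), time = time,
               event = event, x = x)
  grid[which.max(ll)]
}

# Hand two-group log-rank chi-square (hypergeometric variance).
oracleLogrankChisq <- function(time, event, group) {
  group <- as.integer(factor(group)) == 1L
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    atRisk <- time >= t
    n <- sum(atRisk); n1 <- sum(atRisk & group)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Exact permutation distribution of the log-rank statistic over all
# balanced label assignments.
oraclePermutationLogrankP <- function(time, event, group) {
  obs <- oracleLogrankChisq(time, event, group)
  n <- length(time)
  k <- sum(as.integer(factor(group)) == 1L)
  combs <- utils::combn(n, k)
  stats <- apply(combs, 2L, function(idx) {
    g <- rep(2L, n); g[idx] <- 1L
    oracleLogrankChisq(time, event, g)
  })
  mean(stats >= obs - 1e-12)
}

# Hand product-limit table with Greenwood variance (no CI transform).
oracleKM <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n)
    out$surv[i] <- s
  }
  out
}

# Brute-force Benjamini-Hochberg step-up.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[o[i]] * m / i, 1)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# Exhaustive best-subset AIC over all non-empty candidate subsets.
oracleBestSubsetAic <- function(time, event, x, candidates) {
  best <- Inf
  for (size in seq_along(candidates)) {
    subs <- utils::combn(candidates, size, simplify = FALSE)
    for (g in subs) {
      f <- tryCatch(
        suppressWarnings(suppressMessages(
          coxFit(time, event, as.data.frame(t(x[g, , drop = FALSE]))))),
        error = function(e) NULL)
      if (!is.null(f) && f$converged && f$aic < best) best <- f$aic
    }
  }
  best
}

# Exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration.
oracleFisher2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  pObs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}
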