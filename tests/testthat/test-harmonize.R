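# Probe collapsing, anchor z-scoring, receptor calling, subtype rules,
# and subgroup selection.

mkStudy <- function(m, platform = "microarray", id = "DS01", map = NULL) {
  ExpressionStudy(m, platform = platform, datasetId = id, probeMap = map)
}

test_that("collapseProbes keeps the highest-variance probe per gene", {
  m <- rbind(p1 = c(1, 1.5, 2, 2.5), p2 = c(0, 3, -1, 4),
             p3 = c(5, 5.1, 5.2, 5.3))
  colnames(m) <- paste0("s", 1:4)
  st <- mkStudy(m, map = c(p1 = "G1", p2 = "G1", p3 = "G2"))
  out <- collapseProbes(st)
  expect_equal(rownames(out), c("G1", "G2"))
  expect_equal(unname(exprs(out)["G1", ]), unname(m["p2", ]))
  # single-probe gene passes through unchanged
  expect_equal(unname(exprs(out)["G2", ]), unname(m["p3", ]))
  expect_equal(SummarizedExperiment::rowData(out)$probe_id, c("p2", "p3"))
})

test_that("exact variance ties resolve to the smaller probe id, warning", {
  m <- rbind(pB = c(0, 1, 2), pA = c(10, 11, 12))
  colnames(m) <- paste0("s", 1:3)
  st <- mkStudy(m, map = c(pB = "G1", pA = "G1"))
  expect_warning(out <- collapseProbes(st), "variance tie")
  expect_equal(SummarizedExperiment::rowData(out)$probe_id, "pA")
})

test_that("collapseProbes is invariant to probe row order", {
  set.seed(1)
  m <- matrix(rnorm(40), 8, 5,
              dimnames = list(paste0("p", 1:8), paste0("s", 1:5)))
  map <- setNames(rep(c("G1", "G2"), each = 4), rownames(m))
  a <- collapseProbes(mkStudy(m, map = map))
  perm <- sample(8)
  b <- collapseProbes(mkStudy(m[perm, ], map = map[perm]))
  expect_equal(exprs(a), exprs(b)[rownames(a), ])
})

test_that("anchor z-scoring standardizes anchors and cancels batches", {
  set.seed(2)
  m <- matrix(rnorm(200, 8), 10, 20,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  anchors <- paste0("s", 1:6)
  z <- exprs(zscoreByAnchor(mkStudy(m), anchors))
  expect_equal(unname(rowMeans(z[, anchors])), rep(0, 10))
  expect_equal(unname(apply(z[, anchors], 1, sd)), rep(1, 10))
  # affine distortion of the study leaves the harmonized values unchanged
  zShifted <- exprs(zscoreByAnchor(mkStudy(1.5 * m + 2), anchors))
  expect_equal(z, zShifted, tolerance = 1e-9)
  # idempotence: re-standardizing already-standardized data is a no-op
  z2 <- exprs(zscoreByAnchor(mkStudy(z), anchors))
  expect_lt(max(abs(z2 - z)), 1e-9)
})

test_that("zero anchor SD and scarce anchors fall back gracefully", {
  m <- matrix(rnorm(40, 8), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  m[1, 1:3] <- 5  # constant across the anchors only
  expect_message(z <- zscoreByAnchor(mkStudy(m), paste0("s", 1:3)),
                 "zero anchor SD")
  expect_true(all(is.finite(exprs(z)[1, ])))
  expect_message(zscoreByAnchor(mkStudy(m), "s1"), "falling back")
  expect_error(zscoreByAnchor(mkStudy(m), "s1", hardFail = TRUE),
               "fewer than")
})

test_that("receptor cutpoint recovers the analytic posterior crossing", {
  set.seed(10)
  n <- 500
  comp <- runif(n) < 0.6
  vals <- ifelse(comp, rnorm(n, -2, 0.5), rnorm(n, 2, 0.5))
  names(vals) <- paste0("s", seq_len(n))
  res <- callReceptor(vals)
  # analytic posterior-0.5 point of the true mixture
  analytic <- 0.25 / 4 * log(0.6 / 0.4)
  expect_lt(abs(res$threshold$cutpoint - analytic), 0.3)
  truth <- ifelse(comp, "negative", "positive")
  expect_lt(mean(res$calls != truth), 0.02)
})

test_that("receptor calls are shift-equivariant", {
  set.seed(11)
  vals <- c(rnorm(150, -2, 0.5), rnorm(100, 2, 0.5))
  names(vals) <- paste0("s", seq_along(vals))
  a <- callReceptor(vals)
  b <- callReceptor(vals + 7)
  expect_identical(a$calls, b$calls)
  expect_equal(b$threshold$cutpoint - a$threshold$cutpoint, 7,
               tolerance = 1e-2)
})

test_that("degenerate distributions are rejected as not bimodal", {
  vals <- setNames(rep(3.2, 50), paste0("s", 1:50))
  expect_error(callReceptor(vals), "not bimodal")
  expect_error(callReceptor(setNames(rnorm(10), paste0("s", 1:10))),
               "at least 20")
  # a manual cutpoint overrides estimation
  res <- callReceptor(vals, cutpoint = 3.0)
  expect_true(all(res$calls == "positive"))
})

test_that("subtype assignment follows the precedence rules", {
  out <- assignSubtype(
    er = c("negative", "negative", "positive", "negative"),
    pr = c("negative", "positive", "positive", "negative"),
    erbb2 = c("negative", "negative", "positive", "positive"))
  expect_equal(as.character(out),
               c("TN", "ER+/ERBB2-", "ERBB2+", "ERBB2+"))
  withMiss <- suppressMessages(
    assignSubtype(c("negative", NA), c("negative", "positive"),
                  c("negative", "negative")))
  expect_true(is.na(withMiss[2]))
})

test_that("subgroup selection keeps survival-informative samples only", {
  sim <- simulateCohort(smallSimConfig(seed = 21,
                                       receptorMeans = c(-3, 3),
                                       receptorSds = c(0.5, 0.5)))
  cl <- clinicalData(sim)
  tr <- groundTruth(sim)$samples
  dropIds <- cl$sample_id[which(tr$true_subtype == "TN")[1:2]]
  cl$dfs_months[cl$sample_id %in% dropIds] <- NA
  anchors <- tr$sample_id[tr$true_subtype == "anchor"]
  cohort <- suppressMessages(
    buildCohort(studies(sim), cl, anchorIds = anchors))
  tn <- suppressMessages(selectSubgroup(cohort, "TN", "dfs"))
  expected <- setdiff(tr$sample_id[tr$true_subtype == "TN"], dropIds)
  expect_setequal(colnames(tn), expected)
  expect_error(suppressMessages(selectSubgroup(cohort, "no-such-subtype")),
               "no samples")
})

test_that("receptor-call accuracy exceeds 95% on well-separated cohorts", {
  sim <- simulateCohort(smallSimConfig(seed = 22, batchShift = c(-3, 3),
                                       batchScale = c(0.5, 2)))
  cohort <- suppressMessages(
    buildCohort(studies(sim), clinicalData(sim)))
  cd <- clinicalData(cohort)
  tr <- groundTruth(sim)$samples
  i <- match(cd$sample_id, tr$sample_id)
  expect_gt(mean((cd$er_call == "positive") == tr$true_er[i]), 0.95)
  expect_gt(mean((cd$pr_call == "positive") == tr$true_pr[i]), 0.95)
  expect_gt(mean((cd$erbb2_call == "positive") == tr$true_erbb2[i]), 0.95)
})
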