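# Cohort splitting, stepwise AIC selection, the median-cutoff classifier,
# and its evaluation.

test_that("the stratified split is deterministic and well balanced", {
  n <- 1226
  ids <- sprintf("P%04d", 1:n)
  strat <- rep(c("microarray", "rnaseq"), c(1027, 199))
  s1 <- suppressMessages(splitCohort(ids, strat, seed = 4))
  s2 <- suppressMessages(splitCohort(ids, strat, seed = 4))
  expect_identical(s1$learning, s2$learning)
  expect_identical(s1$hash, s2$hash)
  expect_length(intersect(s1$learning, s1$validation), 0)
  expect_setequal(c(s1$learning, s1$validation), ids)
  expect_lt(abs(length(s1$learning) - round(n * 2 / 3)), 3)
  # per-platform learning share close to the global share, several seeds
  for (seed in 1:5) {
    sp <- suppressMessages(splitCohort(ids, strat, seed = seed))
    for (lev in unique(strat)) {
      share <- mean(ids[strat == lev] %in% sp$learning)
      expect_lt(abs(share - 2 / 3), 0.05)
    }
  }
  expect_warning(suppressMessages(
    splitCohort(ids[1:20], rep(c("a", "b"), c(19, 1)), seed = 1)),
    "assigned to learning")
})

test_that("a single real-effect candidate is retained by stepwise AIC", {
  set.seed(40)
  n <- 200
  x <- matrix(rnorm(n), 1, n,
              dimnames = list("gene1", paste0("s", 1:n)))
  d <- makeSurvData(n, beta = 0.9, x = x[1, ])
  m <- stepwiseAic(d$time, d$event, x, "gene1")
  expect_equal(signatureGenes(m), "gene1")
  expect_equal(unname(signatureBeta(m)), 0.9, tolerance = 0.3)
  expect_error(stepwiseAic(d$time, d$event, x, character(0)),
               "no candidate")
})

test_that("stepwise AIC never beats the exhaustive best subset", {
  set.seed(41)
  n <- 120
  p <- 7
  x <- matrix(rnorm(p * n), p, n,
              dimnames = list(paste0("g", 1:p), paste0("s", 1:n)))
  lp <- 0.9 * x[1, ] - 0.9 * x[2, ]
  time <- rexp(n, exp(lp) / 40)
  cens <- rexp(n, 1 / 60)
  d <- data.frame(time = pmin(time, cens), event = as.integer(time <= cens))
  m <- suppressWarnings(stepwiseAic(d$time, d$event, x, rownames(x)))
  bestAic <- oracleBestSubsetAic(d$time, d$event, x, rownames(x))
  startFit <- coxFit(d$time, d$event, as.data.frame(t(x)))
  expect_lte(m@learningAic, startFit$aic)
  expect_gte(m@learningAic, bestAic - 1e-6)
  expect_true(all(c("g1", "g2") %in% signatureGenes(m)))
  trace <- m@provenance$trace
  expect_equal(trace$action[1], "start")
  expect_true(all(diff(trace$aic) < 0))
})

test_that("the median cutoff halves an even learning set", {
  set.seed(42)
  n <- 100
  x <- matrix(rnorm(2 * n), 2, n,
              dimnames = list(c("a", "b"), paste0("s", 1:n)))
  m <- SignatureModel(c("a", "b"), c(0.5, -0.25))
  m <- buildClassifier(m, x)
  cls <- classifyRisk(m, x)
  expect_equal(unname(table(cls)), c(n / 2, n / 2), ignore_attr = TRUE)
  expect_error(buildClassifier(SignatureModel(c("a", "b"), c(0, 0)), x),
               "null signature")
  expect_error(riskScore(m, x[1, , drop = FALSE]), "lacks signature gene")
  expect_error(classifyRisk(SignatureModel("a", 1), x), "no cutoff")
})

test_that("evaluation reports KM, log-rank and a reciprocal HR on swap", {
  set.seed(43)
  n <- 300
  x <- matrix(rnorm(2 * n), 2, n,
              dimnames = list(c("a", "b"), paste0("s", 1:n)))
  lp <- 0.8 * x["a", ]
  time <- rexp(n, exp(lp) / 60)
  cens <- rexp(n, 1 / 90)
  tt <- pmin(time, cens); ev <- as.integer(time <= cens)
  m <- buildClassifier(SignatureModel(c("a", "b"), c(0.8, 0)), x)
  evR <- evaluateClassifier(m, tt, ev, x)
  expect_equal(sort(evR$fiveYear$class), c("high-risk", "low-risk"))
  expect_lt(evR$logrank$p, 0.05)
  expect_gt(evR$cox$hr[1], 1)
  # label swap: negate the score scale => reciprocal hazard ratio
  mSwap <- SignatureModel(c("a", "b"), -c(0.8, 0),
                          cutoff = -signatureCutoff(m))
  evS <- evaluateClassifier(mSwap, tt, ev, x)
  expect_equal(unname(evS$cox$hr[1]), 1 / unname(evR$cox$hr[1]),
               tolerance = 0.05)
})

test_that("classes independent of outcome give a covering HR CI", {
  covered <- 0
  for (s in 1:60) {
    set.seed(500 + s)
    n <- 120
    x <- matrix(rnorm(n), 1, n,
                dimnames = list("a", paste0("s", 1:n)))
    d <- makeSurvData(n, beta = 0, censRate = 0.5)
    m <- buildClassifier(SignatureModel("a", 1), x)
    evR <- suppressWarnings(evaluateClassifier(m, d$time, d$event, x))
    if (evR$cox$ci[1, "lower"] <= 1 && 1 <= evR$cox$ci[1, "upper"]) {
      covered <- covered + 1
    }
  }
  # 3-SD band around 95% coverage of 60
  expect_gte(covered, 57 - 3 * sqrt(60 * 0.95 * 0.05))
})

test_that("validation outcomes cannot leak into the frozen signature", {
  sim <- simulateCohort(smallSimConfig(seed = 44,
                                       samplesPerDataset = 250L))
  h <- harmonizedTN(sim)
  d1 <- suppressMessages(suppressWarnings(
    runDiscovery(h$tn, panel = rownames(h$z), seed = 9)))
  # corrupt the validation outcomes only, keep the same split seed
  tnBad <- h$tn
  vIdx <- match(d1$split$validation, colnames(tnBad))
  cd <- SummarizedExperiment::colData(tnBad)
  set.seed(1)
  cd$dfs_months[vIdx] <- sample(cd$dfs_months[vIdx])
  cd$dfs_event[vIdx] <- sample(cd$dfs_event[vIdx])
  SummarizedExperiment::colData(tnBad) <- cd
  d2 <- suppressMessages(suppressWarnings(
    runDiscovery(tnBad, panel = rownames(h$z), seed = 9)))
  expect_identical(signatureGenes(d1$model), signatureGenes(d2$model))
  expect_equal(signatureBeta(d1$model), signatureBeta(d2$model))
  expect_equal(signatureCutoff(d1$model), signatureCutoff(d2$model))
})
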