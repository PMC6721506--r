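# Random-signature sampler, the shared evaluation recipe, and the
# empirical significance estimator.

test_that("randomSignature draws uniform subsets without replacement", {
  universe <- tkPanel()
  expect_error(randomSignature(universe, 100), "exceeds")
  expect_setequal(randomSignature(universe, length(universe)), universe)
  set.seed(50)
  a <- randomSignature(universe, 13)
  set.seed(50)
  b <- randomSignature(universe, 13)
  expect_identical(a, b)
  expect_length(unique(a), 13)
  # inclusion frequency ~ 13/86 within 3 binomial SDs
  set.seed(51)
  draws <- replicate(4000, randomSignature(universe, 13))
  freq <- table(factor(draws, levels = universe)) / 4000
  p0 <- 13 / 86
  # 4-SD band: 86 simultaneous comparisons under one fixed seed
  band <- 4 * sqrt(p0 * (1 - p0) / 4000)
  expect_true(all(abs(freq - p0) <= band + 1e-9))
})

test_that("nullPvalue reproduces the observed signature's own recipe", {
  sim <- simulateCohort(smallSimConfig(seed = 52,
                                       samplesPerDataset = 220L))
  h <- harmonizedTN(sim)
  sp <- suppressMessages(splitCohort(colnames(h$tn), seed = 2))
  L <- sp$learning; V <- sp$validation
  sv <- h$sv
  genes <- c("EPHA4", "FLT1", "ITK")
  p <- nullPvalue(genes, sv[L, "time"], sv[L, "event"],
                  h$z[, L, drop = FALSE],
                  sv[V, "time"], sv[V, "event"], h$z[, V, drop = FALSE])
  # identical recipe run via the classifier surfaces
  f <- coxFit(sv[L, "time"], sv[L, "event"],
              as.data.frame(t(h$z[genes, L])))
  m <- buildClassifier(SignatureModel(genes, f$beta[genes]),
                       h$z[, L, drop = FALSE])
  evR <- evaluateClassifier(m, sv[V, "time"], sv[V, "event"],
                            h$z[, V, drop = FALSE])
  expect_equal(as.numeric(p), evR$logrank$p, tolerance = 1e-9)
})

test_that("a single-gene signature reduces to that gene's median split", {
  sim <- simulateCohort(smallSimConfig(seed = 53,
                                       samplesPerDataset = 200L))
  h <- harmonizedTN(sim)
  sp <- suppressMessages(splitCohort(colnames(h$tn), seed = 5))
  L <- sp$learning; V <- sp$validation
  sv <- h$sv
  p <- nullPvalue("EPHA4", sv[L, "time"], sv[L, "event"],
                  h$z[, L, drop = FALSE],
                  sv[V, "time"], sv[V, "event"], h$z[, V, drop = FALSE])
  # direct median split on the gene (coefficient sign > 0 here)
  f <- coxFit(sv[L, "time"], sv[L, "event"],
              data.frame(g = h$z["EPHA4", L]))
  cut <- median(unname(f$beta) * h$z["EPHA4", L])
  grp <- unname(f$beta) * h$z["EPHA4", V] > cut
  lr <- logrankTest(sv[V, "time"], sv[V, "event"], grp)
  expect_equal(as.numeric(p), lr$p, tolerance = 1e-9)
})

test_that("empirical significance follows the strict-proportion rule", {
  expect_error(empiricalSignificance(0.01, numeric(0)), "empty")
  nullP <- seq(0.001, 1, length.out = 1000)
  es <- empiricalSignificance(min(nullP) / 2, nullP)
  expect_equal(es$empirical, 0)
  expect_equal(es$smoothed, 1 / 1001)
  esMed <- empiricalSignificance(median(nullP), nullP)
  expect_equal(esMed$empirical, 0.5, tolerance = 0.01)
})

test_that("resamplingNull is seeded and self-consistent", {
  sim <- simulateCohort(smallSimConfig(seed = 54,
                                       samplesPerDataset = 200L))
  h <- harmonizedTN(sim)
  sp <- suppressMessages(splitCohort(colnames(h$tn), seed = 3))
  L <- sp$learning; V <- sp$validation
  sv <- h$sv
  panel <- intersect(smallSimConfig()$panelGenes, rownames(h$z))
  args <- list(c("EPHA4", "ITK"), panel,
               sv[L, "time"], sv[L, "event"], h$z[, L, drop = FALSE],
               sv[V, "time"], sv[V, "event"], h$z[, V, drop = FALSE])
  nd1 <- do.call(resamplingNull, c(args, list(B = 50L, seed = 7L)))
  nd2 <- do.call(resamplingNull, c(args, list(B = 50L, seed = 7L)))
  expect_identical(nullPvalues(nd1), nullPvalues(nd2))
  expect_equal(nd1@observedP,
               as.numeric(do.call(nullPvalue, args[c(1, 3:8)])))
  expect_true(empiricalP(nd1) >= 0 && empiricalP(nd1) <= 1)
})

test_that("validation p is uniform when outcomes are permuted", {
  sim <- simulateCohort(smallSimConfig(seed = 55,
                                       samplesPerDataset = 250L,
                                       plantedBeta = numeric(0)))
  h <- harmonizedTN(sim)
  sp <- suppressMessages(splitCohort(colnames(h$tn), seed = 1))
  L <- sp$learning; V <- sp$validation
  sv <- h$sv
  genes <- c("EPHA4", "FLT1", "ITK", "SRC", "KIT")
  set.seed(56)
  ps <- replicate(150, {
    idx <- sample(length(V))
    as.numeric(nullPvalue(genes, sv[L, "time"], sv[L, "event"],
                          h$z[, L, drop = FALSE],
                          sv[V, "time"][idx], sv[V, "event"][idx],
                          h$z[, V, drop = FALSE]))
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  # conservativeness at the 5% level within 3 binomial SDs
  expect_lte(mean(ps <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 150))
})
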