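# Moderated t-test, FDR, DE lists, centroid score, metagenes, and
# association tests.

test_that("moderated t matches the closed-form arithmetic", {
  # gene with logFC = 1, pooled s2 = 1, n1 = n2 = 3, fixed prior
  # d0 = 3, s0sq = 1: s2post = (3 + 4)/7 = 1, t = 1/sqrt(2/3), df = 7
  g1 <- c(0, 1, 2, -1, 0, 1)
  g2 <- c(5, 6, 7, 5, 6, 7)
  x <- rbind(gene1 = g1, gene2 = g2)
  colnames(x) <- paste0("s", 1:6)
  labels <- factor(rep(c("low-risk", "high-risk"), each = 3),
                   levels = c("low-risk", "high-risk"))
  res <- moderatedT(x, labels, prior = list(d0 = 3, s0sq = 1))
  expect_equal(res$logFC[1], 1)
  expect_equal(res$s2[1], 1)
  expect_equal(res$tMod[1], 1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df[1], 7)
  expect_equal(res$p[1], 2 * pt(-abs(1 / sqrt(2 / 3)), 7))
})

test_that("d0 = 0 recovers the ordinary pooled t-test exactly", {
  set.seed(60)
  x <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  labels <- rep(c("A", "B"), each = 6)
  res <- moderatedT(x, labels, prior = list(d0 = 0, s0sq = 1))
  for (i in c(1, 17, 50)) {
    tt <- t.test(x[i, 1:6], x[i, 7:12], var.equal = TRUE)
    expect_equal(res$tMod[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("d0 = Inf ranks genes purely by fold change", {
  set.seed(61)
  x <- matrix(rnorm(30 * 10, sd = rep(runif(30, 0.5, 3), 10)), 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  res <- moderatedT(x, rep(c("A", "B"), each = 5),
                    prior = list(d0 = Inf, s0sq = 0.5))
  expect_equal(order(abs(res$tMod)), order(abs(res$logFC)))
})

test_that("the variance prior is recovered by moment matching", {
  set.seed(62)
  nGenes <- 5000; d0 <- 4; s0sq <- 0.25; n <- 4
  sigma2 <- d0 * s0sq / rchisq(nGenes, d0)
  x <- matrix(rnorm(nGenes * 2 * n, sd = sqrt(rep(sigma2, 2 * n))),
              nGenes, 2 * n,
              dimnames = list(paste0("g", 1:nGenes), paste0("s", 1:(2 * n))))
  res <- moderatedT(x, rep(c("A", "B"), each = n))
  prior <- attr(res, "prior")
  expect_gt(prior$d0, d0 / 2)
  expect_lt(prior$d0, d0 * 2)
  expect_lt(abs(prior$s0sq - s0sq) / s0sq, 0.25)
})

test_that("moderated t agrees with the limma reference implementation", {
  skip_if_not_installed("limma")
  set.seed(63)
  # heteroskedastic gene variances so the prior df is finite and both
  # implementations use the same t reference
  sigma2 <- 5 * 0.8 / rchisq(200, 5)
  x <- matrix(rnorm(200 * 14, sd = sqrt(rep(sigma2, 14))), 200, 14,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:14)))
  x[1:20, 1:7] <- x[1:20, 1:7] + 1.5
  labels <- factor(rep(c("grp1", "grp2"), each = 7),
                   levels = c("grp1", "grp2"))
  res <- moderatedT(x, labels)
  design <- cbind(1, as.integer(labels == "grp1"))
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(attr(res, "prior")$d0, fit$df.prior, tolerance = 1e-4)
  expect_equal(attr(res, "prior")$s0sq, fit$s2.prior, tolerance = 1e-4)
  expect_equal(res$tMod, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("BH adjustment matches hand step-up computations", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bhFdr(0.73), 0.73)
  expect_identical(bhFdr(numeric(0)), numeric(0))
  expect_error(bhFdr(c(0.5, 1.2)), "outside")
  set.seed(64)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    expect_equal(bhFdr(p), oracleBH(p), tolerance = 1e-12)
  }
})

test_that("DE thresholds apply jointly and split by direction", {
  res <- data.frame(
    gene = paste0("g", 1:6),
    logFC = c(1, -1, 0.1, 1, 1, -2),
    s2 = 1, tMod = 1, df = 10,
    p = c(1e-4, 1e-4, 1e-4, 0.5, 1e-4, 1e-3),
    q = c(1e-3, 1e-3, 1e-3, 0.6, 0.5, 1e-3))
  out <- suppressMessages(deGeneList(res))
  expect_equal(out$upInLow, c("g1"))
  expect_equal(out$upInHigh, c("g2", "g6"))
  vac <- suppressMessages(deGeneList(res, fcMin = 1))
  expect_true("g3" %in% c(vac$upInLow, vac$upInHigh))
})

test_that("centroid score is signed correctly at the centroids", {
  set.seed(65)
  xl <- matrix(rnorm(20 * 30), 20, 30,
               dimnames = list(paste0("g", 1:20), paste0("s", 1:30)))
  cls <- rep(c("low-risk", "high-risk"), each = 15)
  xl[, cls == "high-risk"] <- xl[, cls == "high-risk"] + 2 * rnorm(20)
  cent <- centroidScore(xl, cls, xl)$centroids
  xNew <- cbind(isHigh = cent[, "high"], isLow = cent[, "low"])
  cs <- centroidScore(xl, cls, xNew)
  rHL <- cor(cent[, "high"], cent[, "low"])
  expect_equal(unname(cs$score["isHigh"]), 1 - rHL, tolerance = 1e-9)
  expect_equal(unname(cs$score["isLow"]), rHL - 1, tolerance = 1e-9)
  expect_equal(as.character(cs$predicted), c("high-risk", "low-risk"))
  flat <- matrix(1, 20, 1, dimnames = list(rownames(xl), "flatS"))
  expect_warning(csF <- centroidScore(xl, cls, flat), "zero-variance")
  expect_true(is.na(csF$score[1]))
})

test_that("metagene scores average z-scored members", {
  set.seed(66)
  x <- matrix(rnorm(4 * 25), 4, 25,
              dimnames = list(c("a", "b", "c", "d"), paste0("s", 1:25)))
  one <- metageneScore(x, "a")
  expect_equal(unname(one), unname(scale(x["a", ])[, 1]), tolerance = 1e-12)
  x["b", ] <- -x["a", ]
  anti <- metageneScore(x, c("a", "b"))
  expect_lt(max(abs(anti)), 1e-9)
  expect_message(metageneScore(x, c("a", "zz"), setName = "S"), "absent")
  expect_error(metageneScore(x, c("q", "zz"), setName = "S"), "no overlap")
})

test_that("GMT files parse into named gene sets", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3",
               "setB\tdesc\tg2\tg4",
               "setC\tna\tg5\tg6\tg7\tg8"), f)
  sets <- readGmt(f)
  expect_named(sets, c("setA", "setB", "setC"))
  expect_equal(sets$setB, c("g2", "g4"))
  set.seed(67)
  x <- matrix(rnorm(8 * 10), 8, 10,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  scores <- sapply(sets, function(g) metageneScore(x, g))
  expect_equal(dim(scores), c(10L, 3L))
  expect_identical(scores, sapply(sets, function(g) metageneScore(x, g)))
})

test_that("association tests choose Fisher or Welch appropriately", {
  tab <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(fisher.test(tab)$p.value, oracleFisher2x2(tab),
               tolerance = 1e-9)
  classes <- factor(rep(c("low-risk", "high-risk"), each = 20))
  clin <- data.frame(
    age = c(rnorm(20, 50, 5), rnorm(20, 60, 5)),
    grade = factor(rep(c(1, 2, 3, 1), 10)),
    allsame = factor(rep("x", 40)))
  out <- suppressMessages(associationTests(classes, clin))
  expect_setequal(out$summary$variable, c("age", "grade"))
  expect_equal(out$summary$test[out$summary$variable == "age"], "welch_t")
  expect_equal(out$summary$test[out$summary$variable == "grade"], "fisher")
  # identical class-conditional distributions: p = 1
  same <- data.frame(g = factor(rep(c("a", "b"), 20)))
  outSame <- associationTests(classes, same)
  expect_equal(outSame$summary$p, 1)
  # column percentages sum to 100 within rounding
  pct <- out$tables$grade$percent
  expect_true(all(abs(colSums(pct) - 100) <= 2))
})
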