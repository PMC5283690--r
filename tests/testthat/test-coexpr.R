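test_that("preprocessing standardizes and removes batch locations", {
  set.seed(1)
  X <- matrix(rnorm(50 * 24), 50, 24,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:24)))
  # single batch: gene-standardized output
  out <- preprocessCohort(X)
  expect_equal(unname(rowMeans(out)), rep(0, 50), tolerance = 1e-12)
  expect_equal(apply(out, 1, function(v) sum(v^2) / (24 - 1)), rep(1, 50),
               tolerance = 1e-12, ignore_attr = TRUE)

  # constant per-gene offset between two batches is removed exactly
  batch <- rep(c("a", "b"), each = 12)
  delta <- rnorm(50, sd = 3)
  Xb <- X
  Xb[, batch == "b"] <- Xb[, batch == "b"] + delta
  outB <- preprocessCohort(Xb, batch)
  gap <- rowMeans(outB[, batch == "a"]) - rowMeans(outB[, batch == "b"])
  expect_equal(unname(gap), rep(0, 50), tolerance = 1e-12)

  expect_error(preprocessCohort(X, rep(c("a", "b"), c(22, 2))), ">= 3")
})

test_that("simulated batch effects vanish after correction (ANOVA R^2)", {
  gt <- generateGroundTruth(6, 10, 2, 0, 4, seed = 2)
  sim <- simulateCohortSet(gt, 60, batchSd = 2, batchesPerCohort = 2,
                           admixture = NULL, seed = 2)
  co <- sim$cohorts[[1]]
  out <- preprocessCohort(co$expr, co$batch)
  r2 <- apply(out, 1, function(v) {
    fit <- stats::aov(v ~ co$batch)
    sq <- summary(fit)[[1]][["Sum Sq"]]
    sq[1] / sum(sq)
  })
  expect_lt(max(r2), 0.01)
})

test_that("with two variables and no shrinkage, pcor equals Pearson", {
  set.seed(3)
  X <- matrix(rnorm(2 * 60), 2, 60, dimnames = list(c("tf1", "g1"), NULL))
  et <- shrinkagePartialCorrelation(X, "tf1", lambda = 0)
  expect_equal(edges(et)$pcor, unname(cor(X[1, ], X[2, ])), tolerance = 1e-12)
})

test_that("shrinkage pcor converges to classical pcor in the dense regime", {
  set.seed(4)
  p <- 10; n <- 2000
  A <- matrix(rnorm(p * p), p) / sqrt(p)
  X <- t(matrix(rnorm(n * p), n) %*% (diag(p) + A))
  rownames(X) <- c(paste0("tf", 1:3), paste0("g", 1:7))
  # the analytic intensity becomes negligible ...
  etHat <- shrinkagePartialCorrelation(X, paste0("tf", 1:3))
  expect_lt(shrinkageLambda(etHat), 0.01)
  # ... and at the lambda -> 0 limit the estimator is the textbook
  # inverse-correlation partial correlation
  et <- shrinkagePartialCorrelation(X, paste0("tf", 1:3), lambda = 0)
  P <- oraclePartialCor(X)
  ee <- edges(et)
  expect_lt(max(abs(ee$pcor - P[cbind(ee$tf, ee$target)])), 1e-3)
})

test_that("shrinkage contracts estimates on independent data", {
  set.seed(5)
  X <- matrix(rnorm(50 * 30), 50, 30, dimnames = list(paste0("g", 1:50), NULL))
  et <- shrinkagePartialCorrelation(X, paste0("g", 1:5))
  lam <- shrinkageLambda(et)
  expect_gt(lam, 0)
  expect_lte(lam, 1)
  R <- cor(t(X))
  expect_lt(mean(abs(edges(et)$pcor)), mean(abs(R[upper.tri(R)])))
})

test_that("edge significance uses the MAD empirical null", {
  ed <- data.frame(tf = "tf1", target = paste0("g", 1:500),
                   pcor = c(0, tanh(rnorm(499, sd = 0.05))),
                   z = NA_real_, p = NA_real_, q = NA_real_,
                   stringsAsFactors = FALSE)
  et <- methods::new("EdgeTable", edges = ed, cohort = "c", nSamples = 50L,
                     lambda = 0.5, sigma0 = NA_real_)
  out <- edgeSignificance(et)
  ee <- edges(out)
  expect_equal(ee$p[1], 1)                     # pcor 0 -> p 1
  expect_equal(nullScale(out),
               stats::mad(atanh(ed$pcor), center = 0), tolerance = 1e-12)
  # p-values approximately uniform for a pure null on the Fisher-z scale
  expect_gt(ks.test(ee$p, "punif")$p.value, 0.001)
})

test_that("a global-null cohort yields no significant edges", {
  set.seed(6)
  X <- matrix(rnorm(120 * 60), 120, 60,
              dimnames = list(sprintf("g%03d", 1:120), NULL))
  et <- shrinkagePartialCorrelation(X, sprintf("g%03d", 1:10))
  expect_gt(shrinkageLambda(et), 0.9)   # heavy shrinkage on pure noise
  out <- edgeSignificance(et)
  expect_equal(sum(edges(out)$q < 0.05), 0)

  # fully shrunk limit: every edge carries p = 1
  etFull <- shrinkagePartialCorrelation(X, sprintf("g%03d", 1:10), lambda = 1)
  expect_warning(outFull <- edgeSignificance(etFull), "fully shrunk")
  expect_true(all(edges(outFull)$q == 1))
  expect_equal(nrow(regulonTable(extractRegulons(outFull))), 0)
})

test_that("regulon extraction applies a strict q cutoff and keeps empty TFs", {
  ed <- data.frame(tf = rep(c("tfA", "tfB"), each = 2),
                   target = c("g1", "g2", "g3", "g4"),
                   pcor = c(0.5, -0.4, 0.3, 0.2),
                   z = 1, p = 0.01,
                   q = c(0.049, 0.05, 0.2, 1),
                   stringsAsFactors = FALSE)
  et <- methods::new("EdgeTable", edges = ed, cohort = "c", nSamples = 50L,
                     lambda = 0.2, sigma0 = 0.1)
  regs <- extractRegulons(et, qMax = 0.05)
  tb <- regulonTable(regs)
  expect_equal(tb$target, "g1")               # 0.049 in, 0.05 out (strict <)
  expect_equal(tb$mode, 1)
  expect_equal(tb$likelihood, 1 - 0.049)
  expect_setequal(tfIds(regs), c("tfA", "tfB"))
  expect_equal(unname(regulonSizes(regs)["tfB"]), 0L)
})

test_that("the planted network is recovered from a single cohort", {
  gt <- generateGroundTruth(55, 40, 3, 0.5, 27, seed = 1)
  sim <- simulateCohortSet(gt, 150, muUp = 0, admixture = NULL, seed = 101)
  pre <- suppressMessages(preprocessCohort(sim$cohorts[[1]]$expr,
                                           sim$cohorts[[1]]$batch))
  et <- edgeSignificance(shrinkagePartialCorrelation(pre, tfIds(gt)))
  ee <- edges(et)
  trueKey <- paste(edges(gt)$tf, edges(gt)$target)
  isTrue <- paste(ee$tf, ee$target) %in% trueKey
  expect_gt(mean(ee$q[isTrue] < 0.05), 0.9)    # sensitivity
  expect_lt(mean(ee$q[!isTrue] < 0.05), 0.05)  # false edge rate
  jac <- regulonJaccard(gt, extractRegulons(et))
  expect_gte(median(jac), 0.7)
  expect_gte(min(jac), 0.45)
})
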