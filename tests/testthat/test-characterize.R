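test_that("the product-limit estimator matches hand computation", {
  clin <- data.frame(sample = paste0("s", 1:4),
                     time = c(5, 8, 8, 12), event = c(1, 0, 0, 0))
  st <- data.frame(sample = clin$sample, subtype = 1)
  res <- compareSurvival(clin, st)
  expect_equal(res$km$surv[res$km$time == 5], 0.75)
})

test_that("the log-rank statistic matches a direct summation oracle", {
  clin <- data.frame(sample = paste0("s", 1:8),
                     time = 1:8,
                     event = c(1, 1, 0, 1, 1, 0, 1, 1))
  st <- data.frame(sample = clin$sample, subtype = rep(1:2, 4))
  res <- compareSurvival(clin, st)
  chi <- oracleLogrank(clin$time, clin$event, st$subtype)
  expect_equal(res$chisq, chi, tolerance = 1e-8)

  set.seed(1)
  clin2 <- data.frame(sample = paste0("t", 1:60),
                      time = round(rexp(60, 1 / 50)) + 1,
                      event = rbinom(60, 1, 0.7))
  st2 <- data.frame(sample = clin2$sample, subtype = rep(1:3, 20))
  res2 <- compareSurvival(clin2, st2)
  expect_equal(res2$chisq, oracleLogrank(clin2$time, clin2$event, st2$subtype),
               tolerance = 1e-8)
})

test_that("Cox estimates match a grid-search partial-likelihood oracle", {
  clin <- data.frame(sample = paste0("s", 1:6),
                     time = c(3, 5, 5, 8, 11, 14),
                     event = c(1, 1, 1, 0, 1, 1))
  st <- data.frame(sample = clin$sample, subtype = c(1, 2, 1, 2, 1, 2))
  fit <- coxPH(clin, st, covariates = character(0))
  x <- as.numeric(st$subtype == 2)
  bHat <- stats::optimize(function(b)
    -oracleCoxLogLik(b, clin$time, clin$event, x),
    c(-5, 5), tol = 1e-12)$minimum
  expect_equal(log(fit$table$hr), bHat, tolerance = 1e-6)
})

test_that("Cox recovers the null and respects covariate contracts", {
  set.seed(2)
  truth <- data.frame(sample = sprintf("s%03d", 1:200),
                      subtype = rep(1:2, each = 100))
  cm <- simulateClinicalMutations(truth, hazardRatios = c(1, 1),
                                  censorRate = 0.2, panel = "G1", seed = 2)
  fit <- coxPH(cm$clinical, truth)
  expect_true(fit$table$ci_lower <= 1 && 1 <= fit$table$ci_upper)
  clinBad <- cm$clinical
  clinBad$age <- 60
  expect_error(coxPH(clinBad, truth), "zero variance")
})

test_that("mutation burden applies the alteration filters verbatim", {
  mut <- data.frame(
    sample = c("s1", "s1", "s2", "s2", "s3", "s3", "s4"),
    gene = c("gA", "gB", "gA", "gB", "gA", "gB", "gA"),
    impact = c("HIGH", "LOW", "MODERATE", "NONE", "NONE", "NONE", "NONE"),
    copy_number = c(0, 0, 0, 5, 6, -1, 3),
    stringsAsFactors = FALSE)
  st <- data.frame(sample = paste0("s", 1:4), subtype = c(1, 1, 2, 2))
  br <- mutationBurden(mut, st, panel = c("gA", "gB"))
  fr <- br$fractions
  # s1 gA HIGH yes; s1 gB LOW no; s2 gA MODERATE yes; s2 gB cn 5 no;
  # s3 gA cn 6 yes (amplification > 5); s3 gB cn -1 yes (loss); s4 gA cn 3 no
  expect_equal(fr["gA", "1"], 1)    # s1, s2 altered
  expect_equal(fr["gB", "1"], 0)
  expect_equal(fr["gA", "2"], 0.5)  # s3 only
  expect_equal(fr["gB", "2"], 0.5)

  mutBad <- mut
  mutBad$impact[1] <- "WEIRD"
  expect_error(mutationBurden(mutBad, st, c("gA", "gB")), "WEIRD")
})

test_that("burden gradients give a powerful ANOVA across subtypes", {
  sigCount <- vapply(1:50, function(i) {
    truth <- data.frame(sample = sprintf("s%03d", 1:240),
                        subtype = rep(1:3, each = 80))
    cm <- simulateClinicalMutations(truth,
                                    burdenRates = c(0.094, 0.046, 0.032),
                                    panel = sprintf("KG%02d", 1:39),
                                    seed = 900 + i)
    mutationBurden(cm$mutations, truth, sprintf("KG%02d", 1:39))$anovaP < 0.01
  }, logical(1))
  expect_gte(sum(sigCount), 45)
})

test_that("ssGSEA reproduces the hand-evaluated running sum", {
  expr <- matrix(c(3, 2, 1), 3, 1,
                 dimnames = list(c("top", "mid", "low"), "s1"))
  sc <- ssgsea(expr, list(set = "top"), alpha = 0)
  # positions: in-set ECDF (1,1,1); out-set ECDF (0,1/2,1) -> 1 + 1/2 + 0
  expect_equal(unname(sc["set", "s1"]), 1.5, tolerance = 1e-12)
  expect_error(ssgsea(expr, list(all = c("top", "mid", "low"))), "all genes")
})

test_that("ssGSEA is rank-invariant and separates set from complement", {
  set.seed(3)
  expr <- matrix(rnorm(200 * 12), 200, 12,
                 dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:12)))
  sets <- list(a = sprintf("g%03d", 1:30), b = sprintf("g%03d", 31:200))
  s1 <- ssgsea(expr, sets)
  s2 <- ssgsea(apply(expr, 2, rank), sets)
  expect_equal(s1, s2, tolerance = 1e-10)
  expect_lt(cor(s1["a", ], s1["b", ]), 0)
})

test_that("admixture scores track the planted fractions", {
  st <- simulateStudy(nTfs = 12, targetsPerTf = 20, nCommunities = 3,
                      targetOverlap = 0.5, nPlantedMrs = 6,
                      cohortSizes = 200, seed = 5)
  gs <- studyGeneSets(st)
  expr <- cohorts(st)[[1]]$expr
  adm <- admixtureScores(expr, gs$stromal, gs$immune,
                         subtypes = stats::setNames(truthTable(st)$subtype,
                                                    truthTable(st)$sample))
  tr <- truthTable(st)
  expect_gte(cor(adm$scores["stromal", tr$sample], tr$f_stromal,
                 method = "spearman"), 0.8)
  expect_gte(cor(adm$scores["immune", tr$sample], tr$f_immune,
                 method = "spearman"), 0.7)
  expect_true(all(c("score", "subtype1", "subtype2", "p") %in%
                    names(adm$tests)))

  # shifting the immune marker genes raises the immune score
  e2 <- expr[, c(1, 1)]
  colnames(e2) <- c("orig", "shifted")
  e2[gs$immune, 2] <- e2[gs$immune, 2] + 2
  sc <- ssgsea(e2, list(immune = gs$immune))
  expect_gt(sc["immune", 2], sc["immune", 1])
})

test_that("deconvolution is exact on noiseless mixtures", {
  set.seed(6)
  S <- matrix(rexp(120 * 3), 120, 3,
              dimnames = list(sprintf("g%03d", 1:120), c("A", "B", "C")))
  fr <- c(0.3, 0.7, 0)
  mix <- S %*% fr
  colnames(mix) <- "m1"
  dec <- deconvolve(mix, S, nPerm = 200, seed = 7)
  expect_equal(as.numeric(dec[1, c("A", "B", "C")]), fr, tolerance = 1e-6)
  expect_lte(dec$p, 1 / 201)
  expect_equal(dec$R, 1, tolerance = 1e-9)
})

test_that("deconvolution flags pure noise as unexplained", {
  set.seed(8)
  S <- matrix(rexp(120 * 3), 120, 3,
              dimnames = list(sprintf("g%03d", 1:120), c("A", "B", "C")))
  ps <- vapply(1:20, function(i) {
    y <- matrix(rnorm(120), dimnames = list(rownames(S), "n1"))
    deconvolve(y, S, nPerm = 100, seed = 100 + i)$p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.8)
})

test_that("first-order partial correlation matches its algebra", {
  set.seed(9)
  n <- 200
  z <- rnorm(n)
  x <- 0.6 * z + rnorm(n, sd = 0.8)
  y <- 0.6 * z + rnorm(n, sd = 0.8)
  res <- firstOrderPartialCorrelation(x, y, z)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  expect_equal(res$estimate,
               (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)),
               tolerance = 1e-12)

  # independent conditioner: partial equals marginal
  w <- rnorm(n)
  resW <- firstOrderPartialCorrelation(x, y, w)
  expect_equal(resW$estimate,
               (cor(x, y) - cor(x, w) * cor(y, w)) /
                 sqrt((1 - cor(x, w)^2) * (1 - cor(y, w)^2)))

  # family-wise correction by multiplication, capped at 1
  res77 <- firstOrderPartialCorrelation(x, y, z, nTests = 77)
  expect_equal(res77$pAdjusted, min(1, res77$p * 77))
  expect_equal(0.0004 * 77, 0.0308)  # the correction arithmetic itself
  expect_error(firstOrderPartialCorrelation(x, y, x), "degenerate")
})

test_that("label-overlap enrichment matches the closed form", {
  a <- stats::setNames(rep(c("x", "y"), each = 5), paste0("s", 1:10))
  p <- overlapEnrichment(a, a)
  expect_equal(p["x", "x"], 1 / choose(10, 5), tolerance = 1e-12)
  expect_gt(p["x", "y"], p["x", "x"])
  expect_error(overlapEnrichment(a, a[-1]), "universe")
})

test_that("independent labelings show no spurious overlap enrichment", {
  set.seed(10)
  hits <- vapply(1:20, function(i) {
    a <- sample(1:3, 90, replace = TRUE)
    b <- sample(1:3, 90, replace = TRUE)
    p <- overlapEnrichment(a, b)
    min(p) * length(p) > 0.001  # Bonferroni-corrected minimum not tiny
  }, logical(1))
  expect_gte(sum(hits), 18)
})
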