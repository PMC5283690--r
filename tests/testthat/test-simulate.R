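test_that("ground-truth generation is reproducible and structurally sound", {
  gt1 <- generateGroundTruth(12, 20, 3, 0.5, 6, seed = 7)
  gt2 <- generateGroundTruth(12, 20, 3, 0.5, 6, seed = 7)
  expect_identical(edges(gt1), edges(gt2))
  expect_identical(plantedMrs(gt1), plantedMrs(gt2))

  ed <- edges(gt1)
  expect_length(intersect(tfIds(gt1), targetIds(gt1)), 0)
  expect_true(all(table(ed$tf) == 20))
  expect_true(all(ed$sign %in% c(-1, 1)))
  expect_true(all(ed$weight > 0.5 - 1e-12 & ed$weight <= 1))
  # planted MRs spread evenly over the three communities
  expect_equal(unname(table(tfCommunities(gt1)[plantedMrs(gt1)$tf])),
               c(2L, 2L, 2L), ignore_attr = TRUE)
})

test_that("zero overlap forces disjoint regulons", {
  gt <- generateGroundTruth(3, 10, 3, 0, 3, seed = 1)
  ed <- edges(gt)
  expect_equal(nrow(ed), 30)
  expect_equal(anyDuplicated(ed$target), 0L)
  expect_true(all(table(ed$tf) == 10))
})

test_that("community members share the configured regulon overlap", {
  gt <- generateGroundTruth(18, 40, 3, 0.5, 9, seed = 2)
  ed <- edges(gt)
  comm <- tfCommunities(gt)
  regs <- split(ed$target, ed$tf)
  sameComm <- combn(tfIds(gt), 2, function(p) comm[p[1]] == comm[p[2]])
  jac <- combn(tfIds(gt), 2, function(p) {
    a <- regs[[p[1]]]; b <- regs[[p[2]]]
    length(intersect(a, b)) / length(union(a, b))
  })
  # cross-community regulons never overlap; within-community overlap is
  # centred on the configured Jaccard of 0.5
  expect_true(all(jac[!sameComm] == 0))
  expect_gt(mean(jac[sameComm]), 0.35)
  expect_lt(mean(jac[sameComm]), 0.65)
})

test_that("generator rejects invalid arguments", {
  expect_error(generateGroundTruth(5, 10, 3, 1, 3, seed = 1), "targetOverlap")
  expect_error(generateGroundTruth(5, 10, 3, 0.5, 6, seed = 1), "nPlantedMrs")
  expect_error(generateGroundTruth(0, 10, 3, 0.5, 0, seed = 1), "nTfs")
  expect_error(generateGroundTruth(5, -2, 3, 0.5, 2, seed = 1), "targetsPerTf")
})

test_that("cohort simulation honours sizes, props and the gene universe", {
  gt <- generateGroundTruth(9, 15, 3, 0.5, 6, seed = 3)
  sim <- simulateCohortSet(gt, c(30, 20), seed = 3)
  expect_equal(vapply(sim$cohorts, function(co) ncol(co$expr), integer(1)),
               c(30L, 20L))
  rn <- rownames(sim$cohorts[[1]]$expr)
  expect_identical(rn, rownames(sim$cohorts[[2]]$expr))
  expect_true(all(c(tfIds(gt), targetIds(gt)) %in% rn))
  expect_true(all(sim$truth$f_stromal >= 0 & sim$truth$f_stromal <= 1))
  expect_error(simulateCohortSet(gt, c(30), subtypeProps = c(0.5, 0.4, 0.2)),
               "sum to 1")

  # subtype proportions converge to the configured simplex at n = 560
  sim2 <- simulateCohortSet(gt, c(242, 178, 36, 36, 26, 25, 17), seed = 11)
  props <- as.numeric(table(sim2$truth$subtype)) / 560
  expect_true(all(abs(props - 1 / 3) < 0.05))
})

test_that("edge signs propagate to expression in the near-noiseless limit", {
  gt <- generateGroundTruth(6, 10, 2, 0, 4, seed = 5)
  sim <- simulateCohortSet(gt, 120, muUp = 0, noiseSd = 1e-4, batchSd = 0,
                           admixture = NULL, seed = 5)
  X <- sim$cohorts[[1]]$expr
  ed <- edges(gt)
  cors <- mapply(function(tf, tg) cor(X[tf, ], X[tg, ]), ed$tf, ed$target)
  expect_true(all(sign(cors) == ed$sign))
  expect_true(all(abs(cors) > 0.99))
})

test_that("subtype activation separates community target expression", {
  gt <- generateGroundTruth(9, 15, 3, 0.5, 6, seed = 6)
  sim <- simulateCohortSet(gt, 600, subtypeProps = c(1, 1, 1) / 3,
                           muUp = 2, noiseSd = 1, batchSd = 0,
                           admixture = NULL, seed = 6)
  X <- sim$cohorts[[1]]$expr
  ed <- edges(gt)
  comm <- tfCommunities(gt)
  upTargets <- unique(ed$target[comm[ed$tf] == 1 & ed$sign == 1])
  score <- colMeans(X[upTargets, , drop = FALSE])
  s1 <- sim$truth$subtype == 1
  expect_gt(sum(s1), 100); expect_gt(sum(!s1), 100)
  tt <- t.test(score[s1], score[!s1], alternative = "greater")
  expect_lt(tt$p.value, 1e-6)
})

test_that("perturbation has the right design and a calibrated null", {
  gt <- generateGroundTruth(6, 10, 3, 0.5, 4, seed = 8)
  pe <- simulatePerturbation(gt, effect = 3, nReps = 6, seed = 8)
  expect_equal(ncol(pe$expr), 12)
  expect_equal(as.integer(table(pe$condition)), c(6L, 6L))
  expect_identical(simulatePerturbation(gt, 3, 6, seed = 8)$expr, pe$expr)

  # effect = 0: conditions exchangeable, per-gene p-values uniform
  pe0 <- simulatePerturbation(gt, effect = 0, nReps = 6, seed = 9)
  sig0 <- moderatedTTest(pe0$expr, pe0$condition, ref = "control")
  expect_gt(ks.test(sig0$p, "punif")$p.value, 0.01)
})

test_that("perturbed targets of planted MRs respond detectably", {
  # Monte-Carlo: private (single-parent) targets of planted MRs carry
  # |t| above the 5% critical value in the vast majority of reruns
  set.seed(42)
  hit <- replicate(20, {
    sd0 <- sample.int(1e6, 1)
    gt <- generateGroundTruth(6, 10, 3, 0.5, 4, seed = sd0)
    pe <- simulatePerturbation(gt, effect = 3, nReps = 6, seed = sd0 + 1)
    ed <- edges(gt)
    priv <- names(which(table(ed$target) == 1))
    ptg <- ed$target[ed$tf %in% plantedMrs(gt)$tf & ed$target %in% priv]
    isCase <- pe$condition == "case"
    tt <- apply(pe$expr[ptg, , drop = FALSE], 1, function(x)
      abs(t.test(x[isCase], x[!isCase], var.equal = TRUE)$statistic))
    mean(tt > qt(0.975, df = 10))
  })
  expect_gt(min(hit), 0.85)
})

test_that("clinical and mutation simulation respects its contracts", {
  gt <- generateGroundTruth(6, 10, 3, 0.5, 4, seed = 10)
  sim <- simulateCohortSet(gt, 240, seed = 10)
  panel <- sprintf("KG%02d", 1:39)
  cm <- simulateClinicalMutations(sim$truth, panel = panel, seed = 10)
  cl <- cm$clinical
  expect_true(all(cl$time > 0))
  expect_true(all(cl$event %in% c(0, 1)))
  expect_equal(nrow(cl), 240)
  mu <- cm$mutations
  expect_lte(nrow(mu), 39 * 240)
  expect_true(all(mu$impact %in% c("HIGH", "MODERATE", "LOW", "NONE")))
  expect_true(all(mu$gene %in% panel))
  expect_error(simulateClinicalMutations(sim$truth, panel = character(0)),
               "panel")
})

test_that("null hazards give uniform log-rank p-values over reruns", {
  ps <- vapply(1:20, function(i) {
    truth <- data.frame(sample = sprintf("s%03d", 1:150),
                        subtype = rep(1:3, each = 50))
    cm <- simulateClinicalMutations(truth, hazardRatios = c(1, 1, 1),
                                    panel = "G1", seed = 400 + i)
    compareSurvival(cm$clinical, truth)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("planted burden gradients are recovered from the mutation tables", {
  ok <- vapply(1:50, function(i) {
    truth <- data.frame(sample = sprintf("s%03d", 1:240),
                        subtype = rep(1:3, each = 80))
    cm <- simulateClinicalMutations(truth,
                                    burdenRates = c(0.094, 0.046, 0.032),
                                    panel = sprintf("KG%02d", 1:39),
                                    seed = 600 + i)
    br <- mutationBurden(cm$mutations, truth, sprintf("KG%02d", 1:39))
    m <- br$subtypeMeans
    m[["1"]] > m[["2"]] && m[["1"]] > m[["3"]]
  }, logical(1))
  expect_gte(sum(ok), 48)
})

test_that("simulateStudy assembles a valid study object", {
  st <- smallStudy(seed = 4)
  expect_s4_class(st, "SyntheticStudy")
  expect_equal(length(cohorts(st)), 3)
  expect_equal(nrow(truthTable(st)), 80 + 60 + 50)
  expect_equal(ncol(perturbation(st)$expr), 12)
  expect_true(validObject(st))
})
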