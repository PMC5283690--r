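#' Generate a planted regulator-target network
#'
#' Builds a ground-truth regulatory network: TFs are partitioned evenly into
#' communities, and each community co-regulates a shared target program. The
#' program pool is sized so that any two community members share a
#' `targetOverlap` Jaccard fraction of their regulons; every pool target is
#' regulated by `coRegSize` community TFs (drawn balanced-at-random), the
#' rest of each regulon being private targets. Edge signs (mode of
#' regulation) are Bernoulli(0.5) mapped to -1/+1 and weights are
#' Uniform(0.5, 1). A subset of TFs is planted as master regulators spread
#' evenly across communities; each community carries a coherent activation
#' direction (the biological processes respond as units, some activated and
#' some repressed), individual planted MRs flipping against their community
#' with probability `dirFlipProb`.
#'
#' @param nTfs number of transcription factors.
#' @param targetsPerTf regulon size of every TF.
#' @param nCommunities number of TF communities.
#' @param targetOverlap pairwise regulon overlap (Jaccard) between TFs of
#'   the same community, in [0, 1).
#' @param nPlantedMrs number of TFs planted as perturbation-responsive master
#'   regulators (<= `nTfs`).
#' @param coRegSize number of community TFs co-regulating each shared
#'   program target (default 6, capped at the community size).
#' @param dirFlipProb probability a planted MR's direction opposes its
#'   community's (default 0.15).
#' @param seed integer seed; identical seeds give identical networks.
#' @return A [GroundTruthNetwork-class].
#' @examples
#' gt <- generateGroundTruth(6, 10, 3, 0, 3, seed = 1)
#' gt
#' @export
generateGroundTruth <- function(nTfs, targetsPerTf, nCommunities,
                                targetOverlap, nPlantedMrs, coRegSize = 6,
                                dirFlipProb = 0.15, seed = 1) {
  nTfs <- .checkCount(nTfs, "nTfs")
  targetsPerTf <- .checkCount(targetsPerTf, "targetsPerTf")
  nCommunities <- .checkCount(nCommunities, "nCommunities")
  nPlantedMrs <- .checkCount(nPlantedMrs, "nPlantedMrs", min = 0L)
  targetOverlap <- .checkFraction(targetOverlap, "targetOverlap")
  if (nPlantedMrs > nTfs) stop("nPlantedMrs must not exceed nTfs")
  if (nCommunities > nTfs) stop("nCommunities must not exceed nTfs")
  coRegSize <- .checkCount(coRegSize, "coRegSize", min = 2L)
  set.seed(seed)

  tfIds <- sprintf("TF%03d", seq_len(nTfs))
  community <- rep(seq_len(nCommunities), length.out = nTfs)
  names(community) <- tfIds

  # per-TF shared quota giving pairwise Jaccard = targetOverlap when two
  # members both draw from the community program
  nShared <- round(2 * targetsPerTf * targetOverlap / (1 + targetOverlap))

  nextId <- 0L
  newTargets <- function(k) {
    ids <- sprintf("G%05d", nextId + seq_len(k))
    nextId <<- nextId + k
    ids
  }
  edgeTf <- character(0)
  edgeTg <- character(0)
  for (cc in seq_len(nCommunities)) {
    ms <- tfIds[community == cc]
    k <- length(ms)
    mu <- min(coRegSize, k)
    quota <- stats::setNames(rep(nShared, k), ms)
    if (k >= 2 && nShared > 0) {
      poolSize <- round(k * nShared / mu)
      for (b in seq_len(poolSize)) {
        open <- names(quota)[quota > 0]
        if (length(open) < 2) break
        mTake <- min(mu, length(open))
        # balanced at random: favour TFs with the most remaining quota
        pick <- open[order(-quota[open], stats::runif(length(open)))][seq_len(mTake)]
        tg <- newTargets(1L)
        edgeTf <- c(edgeTf, pick)
        edgeTg <- c(edgeTg, rep(tg, mTake))
        quota[pick] <- quota[pick] - 1L
      }
    }
    for (m in ms) {
      nOwn <- targetsPerTf - (nShared - quota[m])
      if (nOwn > 0) {
        tg <- newTargets(nOwn)
        edgeTf <- c(edgeTf, rep(m, nOwn))
        edgeTg <- c(edgeTg, tg)
      }
    }
  }
  ed <- data.frame(
    tf = edgeTf, target = edgeTg,
    sign = sample(c(-1, 1), length(edgeTf), replace = TRUE),
    weight = stats::runif(length(edgeTf), 0.5, 1),
    stringsAsFactors = FALSE
  )
  ed <- ed[order(match(ed$tf, tfIds), ed$target), , drop = FALSE]
  rownames(ed) <- NULL

  # spread planted MRs evenly over communities (round-robin over community order)
  byComm <- split(tfIds, community)
  picked <- character(0)
  ci <- 1L
  while (length(picked) < nPlantedMrs) {
    pool <- setdiff(byComm[[ci]], picked)
    if (length(pool)) picked <- c(picked, pool[1L])
    ci <- if (ci == length(byComm)) 1L else ci + 1L
    if (length(picked) == nTfs) break
  }
  commDir <- sample(c(-1, 1), nCommunities, replace = TRUE)
  dir <- commDir[community[picked]]
  flip <- stats::runif(length(picked)) < dirFlipProb
  planted <- data.frame(
    tf = picked,
    direction = ifelse(flip, -dir, dir),
    stringsAsFactors = FALSE
  )

  methods::new("GroundTruthNetwork",
    tfIds = tfIds,
    targetIds = unique(ed$target),
    edges = ed,
    communityOfTf = community,
    plantedMrs = planted,
    params = list(
      nTfs = nTfs, targetsPerTf = targetsPerTf, nCommunities = nCommunities,
      targetOverlap = targetOverlap, nPlantedMrs = nPlantedMrs, seed = seed
    )
  )
}

#' Default admixture configuration for [simulateCohortSet()]
#'
#' Stromal and immune contamination is modelled as convex addition of two
#' fixed marker-gene profiles. Fractions respond to the tumour's regulatory
#' state: the logit of each fraction is a linear function of the per-sample
#' mean TF activity of each community (plus Gaussian noise), calibrated so
#' that the expected fraction in samples of subtype s is
#' `stromalMean[s]` / `immuneMean[s]`. By default the first
#' (cell-cycle-like) subtype carries the least stroma and immune
#' infiltrate and the third (Notch-like) the most immune infiltrate.
#'
#' @param nStromalGenes,nImmuneGenes number of dedicated marker genes.
#' @param stromalMean,immuneMean per-subtype mean fractions (recycled to the
#'   number of communities).
#' @param fracNoiseSd sd of the fraction noise (fraction scale).
#' @param profileScale expression units added per unit fraction on marker
#'   genes.
#' @return A list of admixture parameters.
#' @export
admixtureConfig <- function(nStromalGenes = 50, nImmuneGenes = 50,
                            stromalMean = c(0.10, 0.40, 0.35),
                            immuneMean = c(0.05, 0.15, 0.30),
                            fracNoiseSd = 0.08, profileScale = 3) {
  list(
    nStromalGenes = .checkCount(nStromalGenes, "nStromalGenes"),
    nImmuneGenes = .checkCount(nImmuneGenes, "nImmuneGenes"),
    stromalMean = stromalMean, immuneMean = immuneMean,
    fracNoiseSd = fracNoiseSd, profileScale = profileScale
  )
}

# Activity-driven admixture fractions: f = c0 + sum_c gamma_c * Abar_c +
# noise, clipped to [0, 1], with gamma calibrated so E[f | subtype s] ~=
# targetMean[s]. Linear response keeps the microenvironment a downstream
# readout of the regulatory state rather than an independent confounder.
.admixFractions <- function(A, commOfTf, targetMean, muUp, fracNoiseSd) {
  nC <- max(commOfTf)
  targetMean <- pmin(pmax(rep_len(targetMean, nC), 1e-3), 1 - 1e-3)
  Abar <- t(vapply(seq_len(nC), function(cc)
    colMeans(A[commOfTf == cc, , drop = FALSE]), numeric(ncol(A))))
  base <- min(targetMean)
  gamma <- (targetMean - base) / muUp
  lin <- base + as.vector(crossprod(Abar, gamma)) +
    stats::rnorm(ncol(A), sd = fracNoiseSd)
  pmin(pmax(lin, 0), 1)
}

# Target loading matrix (targets x TFs) of sign * weight.
.loadingMatrix <- function(gt) {
  W <- matrix(0, length(gt@targetIds), length(gt@tfIds),
              dimnames = list(gt@targetIds, gt@tfIds))
  ed <- gt@edges
  W[cbind(match(ed$target, gt@targetIds), match(ed$tf, gt@tfIds))] <-
    ed$sign * ed$weight
  W
}

#' Simulate a set of expression cohorts with planted subtypes and admixture
#'
#' For each sample a subtype is drawn from `subtypeProps`; TF activities are
#' Normal(muUp * I\[community(tf) == subtype\], 1); TF expression is the
#' activity plus Normal(0, noiseSd) readout noise; each target's expression
#' is the signed, weighted sum of its regulators' activities plus noise.
#' Per-batch gene-wise offsets Normal(0, batchSd) model batch effects, and
#' stromal/immune admixture adds fraction-scaled marker profiles.
#'
#' @param gt a [GroundTruthNetwork-class].
#' @param cohortSizes integer vector of per-cohort sample counts.
#' @param subtypeProps simplex over communities (must sum to 1 within 1e-9).
#' @param batchSd sd of gene-wise batch offsets (>= 0).
#' @param noiseSd sd of expression noise (> 0).
#' @param muUp subtype activation shift of community TF activities.
#' @param admixture list from [admixtureConfig()], or `NULL` to disable.
#' @param batchesPerCohort number of batches per cohort (recycled).
#' @param cohortNames optional cohort names.
#' @param seed integer seed.
#' @return list with `cohorts` (list of `list(expr, batch, name)`), `truth`
#'   (data.frame `sample`, `cohort`, `subtype`, `f_stromal`, `f_immune`),
#'   `geneSets` (stromal/immune marker sets) and `params`.
#' @export
simulateCohortSet <- function(gt, cohortSizes, subtypeProps = NULL,
                              batchSd = 1, noiseSd = 0.25, muUp = 2,
                              admixture = admixtureConfig(),
                              batchesPerCohort = 1, cohortNames = NULL,
                              seed = 1) {
  stopifnot(is(gt, "GroundTruthNetwork"))
  if (length(cohortSizes) < 1) stop("cohortSizes must be nonempty")
  cohortSizes <- vapply(cohortSizes, .checkCount, integer(1), name = "cohort size")
  nC <- max(gt@communityOfTf)
  if (is.null(subtypeProps)) subtypeProps <- rep(1 / nC, nC)
  if (abs(sum(subtypeProps) - 1) > 1e-9)
    stop("subtypeProps must sum to 1 (within 1e-9)")
  if (length(subtypeProps) != nC)
    stop("subtypeProps must have one entry per community")
  if (noiseSd <= 0) stop("noiseSd must be positive")
  if (batchSd < 0) stop("batchSd must be nonnegative")
  set.seed(seed)

  if (is.null(cohortNames))
    cohortNames <- sprintf("cohort%02d", seq_along(cohortSizes))
  batchesPerCohort <- rep_len(as.integer(batchesPerCohort), length(cohortSizes))

  W <- .loadingMatrix(gt)
  stromalGenes <- immuneGenes <- character(0)
  if (!is.null(admixture)) {
    stromalGenes <- sprintf("STR%03d", seq_len(admixture$nStromalGenes))
    immuneGenes <- sprintf("IMM%03d", seq_len(admixture$nImmuneGenes))
  }
  universe <- c(gt@tfIds, gt@targetIds, stromalGenes, immuneGenes)

  cohortsOut <- vector("list", length(cohortSizes))
  truthList <- vector("list", length(cohortSizes))
  commOfTf <- gt@communityOfTf[gt@tfIds]

  for (i in seq_along(cohortSizes)) {
    n <- cohortSizes[i]
    subtype <- sample.int(nC, n, replace = TRUE, prob = subtypeProps)
    up <- outer(commOfTf, subtype, "==") * muUp           # nTf x n
    A <- up + matrix(stats::rnorm(length(up)), nrow(up), ncol(up))
    tfExpr <- A + matrix(stats::rnorm(length(A), sd = noiseSd), nrow(A))
    tgExpr <- W %*% A +
      matrix(stats::rnorm(nrow(W) * n, sd = noiseSd), nrow(W))
    fS <- fI <- rep(0, n)
    admExpr <- NULL
    if (!is.null(admixture)) {
      fS <- .admixFractions(A, commOfTf, admixture$stromalMean, muUp,
                            admixture$fracNoiseSd)
      fI <- .admixFractions(A, commOfTf, admixture$immuneMean, muUp,
                            admixture$fracNoiseSd)
      strExpr <- outer(rep(admixture$profileScale, length(stromalGenes)), fS) +
        matrix(stats::rnorm(length(stromalGenes) * n, sd = noiseSd),
               length(stromalGenes))
      immExpr <- outer(rep(admixture$profileScale, length(immuneGenes)), fI) +
        matrix(stats::rnorm(length(immuneGenes) * n, sd = noiseSd),
               length(immuneGenes))
      admExpr <- rbind(strExpr, immExpr)
    }
    expr <- rbind(tfExpr, tgExpr, admExpr)
    rownames(expr) <- universe
    colnames(expr) <- sprintf("%s_S%04d", cohortNames[i], seq_len(n))

    nb <- max(1L, batchesPerCohort[i])
    batch <- factor(rep(seq_len(nb), length.out = n))
    if (batchSd > 0) {
      for (b in seq_len(nb)) {
        off <- stats::rnorm(nrow(expr), sd = batchSd)
        expr[, batch == b] <- expr[, batch == b] + off
      }
    }
    cohortsOut[[i]] <- list(expr = expr, batch = batch, name = cohortNames[i])
    truthList[[i]] <- data.frame(
      sample = colnames(expr), cohort = cohortNames[i], subtype = subtype,
      f_stromal = fS, f_immune = fI, stringsAsFactors = FALSE
    )
  }

  list(
    cohorts = cohortsOut,
    truth = do.call(rbind, truthList),
    geneSets = list(stromal = stromalGenes, immune = immuneGenes),
    params = list(cohortSizes = cohortSizes, subtypeProps = subtypeProps,
                  batchSd = batchSd, noiseSd = noiseSd, muUp = muUp,
                  admixture = admixture, seed = seed)
  )
}

#' Simulate the two-condition perturbation experiment
#'
#' The experiment emulates replicate cultures of a clonal cell line under
#' controlled conditions: TF activities are fixed by condition (baseline in
#' controls; each planted master regulator shifted by its recorded direction
#' times `effect` in cases), the shift propagates to targets through the
#' network edges, and replicates differ by expression measurement noise
#' (plus optional replicate-level biological activity noise `bioSd`). Genes
#' not downstream of a planted MR are unshifted in expectation; with
#' `bioSd = 0` their statistics are exactly exchangeable between conditions.
#'
#' @param gt a [GroundTruthNetwork-class].
#' @param effect positive activity shift applied to planted MRs (0 allowed
#'   for null experiments).
#' @param nReps replicates per condition (>= 2).
#' @param noiseSd sd of expression noise.
#' @param bioSd sd of replicate-level TF-activity noise (default 0: clonal
#'   line, condition fixes the regulatory state).
#' @param extraGenes optional extra gene IDs appended as pure-noise rows so
#'   the matrix can share a cohort set's gene universe.
#' @param seed integer seed.
#' @return list with `expr` (gene-by-array matrix, 2 * nReps columns) and
#'   `condition` (factor, levels control/case).
#' @export
simulatePerturbation <- function(gt, effect = 3, nReps = 6, noiseSd = 0.25,
                                 bioSd = 0, extraGenes = character(0),
                                 seed = 1) {
  stopifnot(is(gt, "GroundTruthNetwork"))
  nReps <- .checkCount(nReps, "nReps", min = 2L)
  if (effect < 0) stop("effect must be nonnegative")
  set.seed(seed)

  W <- .loadingMatrix(gt)
  nTf <- length(gt@tfIds)
  shift <- stats::setNames(rep(0, nTf), gt@tfIds)
  if (nrow(gt@plantedMrs) > 0)
    shift[gt@plantedMrs$tf] <- gt@plantedMrs$direction * effect

  n <- 2L * nReps
  condition <- factor(rep(c("control", "case"), each = nReps),
                      levels = c("control", "case"))
  A <- matrix(stats::rnorm(nTf * n, sd = bioSd), nTf, n,
              dimnames = list(gt@tfIds, NULL))
  A[, condition == "case"] <- A[, condition == "case"] + shift
  nGenes <- nTf + nrow(W) + length(extraGenes)
  # per-gene measurement noise scales (arrays are heteroskedastic gene-wise)
  sg <- noiseSd * exp(stats::rnorm(nGenes, sd = 0.3))
  noise <- matrix(stats::rnorm(nGenes * n), nGenes, n) * sg
  tfExpr <- A + noise[seq_len(nTf), , drop = FALSE]
  tgExpr <- W %*% A + noise[nTf + seq_len(nrow(W)), , drop = FALSE]
  extra <- NULL
  if (length(extraGenes))
    extra <- matrix(noise[nTf + nrow(W) + seq_along(extraGenes), ,
                          drop = FALSE],
                    length(extraGenes), n, dimnames = list(extraGenes, NULL))
  expr <- rbind(tfExpr, tgExpr, extra)
  colnames(expr) <- sprintf("%s_%d", ifelse(condition == "case", "case", "ctrl"),
                            c(seq_len(nReps), seq_len(nReps)))
  list(expr = expr, condition = condition,
       params = list(effect = effect, nReps = nReps, noiseSd = noiseSd,
                     bioSd = bioSd, seed = seed))
}

#' Simulate clinical outcomes and a mutation/CNV table
#'
#' Survival times are exponential with rate `baselineHazard * HR(subtype)`;
#' censoring is independent exponential calibrated so roughly `censorRate` of
#' subjects are censored. For each panel gene and sample an alteration is
#' drawn Bernoulli with the subtype's burden rate and assigned a random type
#' consistent with the burden filter vocabulary: HIGH/MODERATE-impact SNVs,
#' copy losses (copy_number <= -1) or amplifications (copy_number > 5).
#' Non-counting rows (LOW-impact SNVs, modest gains) are emitted at a low
#' rate to exercise the filters.
#'
#' @param truth data.frame with columns `sample` and `subtype` (from
#'   [simulateCohortSet()]).
#' @param hazardRatios per-subtype hazard ratios (> 0), recycled.
#' @param baselineHazard baseline exponential event rate per day.
#' @param censorRate target censoring fraction in [0, 1).
#' @param burdenRates per-subtype per-gene alteration probabilities, recycled.
#' @param panel character vector of panel genes (nonempty).
#' @param seed integer seed.
#' @return list with `clinical` (data.frame `sample`, `time` (days), `event`,
#'   `age`, `gender`, `stage`, `treated`) and `mutations` (data.frame
#'   `sample`, `gene`, `impact`, `copy_number`).
#' @export
simulateClinicalMutations <- function(truth,
                                      hazardRatios = c(1, 1.73, 0.62),
                                      baselineHazard = 1 / 500,
                                      censorRate = 0.3,
                                      burdenRates = c(0.094, 0.046, 0.032),
                                      panel = sprintf("KG%02d", 1:39),
                                      seed = 1) {
  stopifnot(is.data.frame(truth), all(c("sample", "subtype") %in% names(truth)))
  if (length(panel) == 0) stop("panel must be nonempty")
  if (any(hazardRatios <= 0)) stop("hazardRatios must be positive")
  if (baselineHazard <= 0) stop("baselineHazard must be positive")
  censorRate <- .checkFraction(censorRate, "censorRate")
  set.seed(seed)

  n <- nrow(truth)
  nC <- max(truth$subtype)
  hr <- rep_len(hazardRatios, nC)
  br <- rep_len(burdenRates, nC)

  rate <- baselineHazard * hr[truth$subtype]
  tEvent <- stats::rexp(n, rate)
  if (censorRate > 0) {
    tCens <- stats::rexp(n, rate * censorRate / (1 - censorRate))
    time <- pmin(tEvent, tCens)
    event <- as.integer(tEvent <= tCens)
  } else {
    time <- tEvent
    event <- rep(1L, n)
  }
  clinical <- data.frame(
    sample = truth$sample,
    time = time,
    event = event,
    age = round(stats::rnorm(n, 65, 10), 1),
    gender = sample(c("F", "M"), n, replace = TRUE),
    stage = sample(1:4, n, replace = TRUE, prob = c(0.1, 0.5, 0.3, 0.1)),
    treated = stats::rbinom(n, 1, 0.5),
    stringsAsFactors = FALSE
  )

  grid <- expand.grid(sampleIdx = seq_len(n), gene = panel,
                      stringsAsFactors = FALSE)
  pAlt <- br[truth$subtype[grid$sampleIdx]]
  altered <- stats::runif(nrow(grid)) < pAlt
  type <- character(nrow(grid))
  type[altered] <- sample(c("snv_high", "snv_moderate", "loss", "amp"),
                          sum(altered), replace = TRUE)
  # sparse non-counting noise rows on unaltered pairs
  noiseRow <- !altered & stats::runif(nrow(grid)) < 0.05
  type[noiseRow] <- sample(c("snv_low", "modest_gain"), sum(noiseRow),
                           replace = TRUE)
  keep <- type != ""
  grid <- grid[keep, , drop = FALSE]
  type <- type[keep]
  impact <- c(snv_high = "HIGH", snv_moderate = "MODERATE", loss = "NONE",
              amp = "NONE", snv_low = "LOW", modest_gain = "NONE")[type]
  cn <- integer(length(type))
  cn[type == "loss"] <- sample(c(-1L, -2L), sum(type == "loss"), replace = TRUE)
  cn[type == "amp"] <- sample(6:8, sum(type == "amp"), replace = TRUE)
  cn[type == "modest_gain"] <- sample(3:5, sum(type == "modest_gain"),
                                      replace = TRUE)
  mutations <- data.frame(
    sample = truth$sample[grid$sampleIdx],
    gene = grid$gene,
    impact = unname(impact),
    copy_number = cn,
    stringsAsFactors = FALSE
  )
  rownames(mutations) <- NULL
  list(clinical = clinical, mutations = mutations,
       params = list(hazardRatios = hr, baselineHazard = baselineHazard,
                     censorRate = censorRate, burdenRates = br,
                     panel = panel, seed = seed))
}

#' Simulate a complete study
#'
#' Convenience wrapper chaining [generateGroundTruth()],
#' [simulateCohortSet()], [simulatePerturbation()] and
#' [simulateClinicalMutations()] into one [SyntheticStudy-class]. Sub-seeds
#' are derived deterministically from `seed`.
#'
#' @param nTfs,targetsPerTf,nCommunities,targetOverlap,nPlantedMrs see
#'   [generateGroundTruth()].
#' @param cohortSizes,subtypeProps,batchSd,noiseSd,muUp,admixture see
#'   [simulateCohortSet()].
#' @param effect,nReps see [simulatePerturbation()].
#' @param hazardRatios,baselineHazard,censorRate,burdenRates,panel see
#'   [simulateClinicalMutations()].
#' @param seed integer master seed.
#' @return A [SyntheticStudy-class].
#' @export
simulateStudy <- function(nTfs = 55, targetsPerTf = 40, nCommunities = 3,
                          targetOverlap = 0.5, nPlantedMrs = 27,
                          coRegSize = 6,
                          cohortSizes = c(242, 178, 36, 36, 26, 25, 17),
                          subtypeProps = NULL, batchSd = 1, noiseSd = 0.25,
                          muUp = 2, admixture = admixtureConfig(),
                          effect = 3, nReps = 6,
                          hazardRatios = c(1, 1.73, 0.62),
                          baselineHazard = 1 / 500, censorRate = 0.3,
                          burdenRates = c(0.094, 0.046, 0.032),
                          panel = sprintf("KG%02d", 1:39), seed = 1) {
  gt <- generateGroundTruth(nTfs, targetsPerTf, nCommunities, targetOverlap,
                            nPlantedMrs, coRegSize = coRegSize, seed = seed)
  sim <- simulateCohortSet(gt, cohortSizes, subtypeProps, batchSd, noiseSd,
                           muUp, admixture, seed = seed + 1L)
  extra <- unlist(sim$geneSets, use.names = FALSE)
  pert <- simulatePerturbation(gt, effect, nReps, noiseSd,
                               extraGenes = extra, seed = seed + 2L)
  cm <- simulateClinicalMutations(sim$truth, hazardRatios, baselineHazard,
                                  censorRate, burdenRates, panel,
                                  seed = seed + 3L)
  methods::new("SyntheticStudy",
    network = gt, cohorts = sim$cohorts, perturbation = pert,
    clinical = cm$clinical, mutations = cm$mutations, truth = sim$truth,
    geneSets = sim$geneSets,
    params = list(seed = seed, cohort = sim$params, perturbation = pert$params,
                  clinical = cm$params)
  )
}
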