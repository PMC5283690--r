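#' Run the full master-regulator pipeline on a synthetic study
#'
#' End-to-end driver: derives the perturbation signature
#' ([moderatedTTest()]), infers a per-cohort network
#' ([preprocessCohort()], [shrinkagePartialCorrelation()],
#' [edgeSignificance()]), fuses the cohorts ([stoufferFuse()],
#' [integratedRegulons()]), calls master regulators
#' ([regulonEnrichment()]), groups them into core processes
#' ([buildRegulatoryGraph()], [detectCommunities()],
#' [coreMasterRegulators()]), and assigns per-sample subtypes from
#' single-sample activities ([singleSampleActivity()],
#' [signatureDistance()], [clusterSubtypes()]).
#'
#' @param study a [SyntheticStudy-class], or `NULL` to simulate one from the
#'   remaining arguments via [simulateStudy()].
#' @param qMax edge/regulon FDR cutoff (default 0.05).
#' @param minCohorts minimum cohorts per fused edge (default 4, capped at
#'   the number of cohorts).
#' @param pMr master-regulator p cutoff (default 0.01).
#' @param minSize minimum signature-covered regulon size (default 10).
#' @param k number of subtypes (default 3).
#' @param seed master seed, used only when `study` is `NULL`.
#' @param ... passed to [simulateStudy()] when `study` is `NULL`.
#' @return list with components `study`, `signature`, `edgeTables`,
#'   `fused`, `regulons`, `mrTable`, `graph`, `communities`, `coreMrs`,
#'   `activity`, `distance`, `subtypes`.
#' @export
runPipeline <- function(study = NULL, qMax = 0.05, minCohorts = 4,
                        pMr = 0.01, minSize = 10, k = 3, seed = 1, ...) {
  if (is.null(study)) study <- simulateStudy(seed = seed, ...)
  stopifnot(is(study, "SyntheticStudy"))
  gt <- studyNetwork(study)
  pe <- perturbation(study)

  sig <- moderatedTTest(pe$expr, pe$condition, ref = "control")

  pre <- lapply(cohorts(study), function(co)
    preprocessCohort(co$expr, co$batch))
  edgeTables <- vector("list", length(pre))
  for (i in seq_along(pre)) {
    et <- shrinkagePartialCorrelation(pre[[i]], tfIds(gt),
                                      cohort = cohorts(study)[[i]]$name)
    edgeTables[[i]] <- edgeSignificance(et)
  }

  fused <- stoufferFuse(edgeTables, minCohorts = minCohorts)
  regs <- integratedRegulons(fused, qMax = qMax)

  mrTable <- regulonEnrichment(sig, regs, minSize = minSize, pMr = pMr)
  g <- buildRegulatoryGraph(mrTable, regs)
  comm <- detectCommunities(g)
  coreMrs <- coreMasterRegulators(comm, nCore = k)

  actList <- lapply(pre, function(x) singleSampleActivity(x, regs, coreMrs))
  act <- do.call(cbind, actList)
  d <- signatureDistance(act)
  subtypes <- clusterSubtypes(d, k = k)

  list(study = study, signature = sig, edgeTables = edgeTables,
       fused = fused, regulons = regs, mrTable = mrTable, graph = g,
       communities = comm, coreMrs = coreMrs, activity = act,
       distance = d, subtypes = subtypes)
}

#' Evaluate pipeline recovery against the planted ground truth
#'
#' Compares the pipeline's output with the simulated truth: how many planted
#' master regulators were flagged, how many flagged TFs were not planted,
#' the adjusted Rand index between detected and planted TF communities, and
#' the ARI between the sample-subtype assignment and the planted subtype
#' labels. The community ARI is evaluated over the core master regulators
#' (the MRs the pipeline assigns to the three major processes, which define
#' the subtypes); `communityAriAllFlagged` additionally reports it over
#' every flagged MR in the graph, including those left in peripheral
#' singleton communities.
#'
#' @param res result list from [runPipeline()].
#' @return list with `recovered`, `nPlanted`, `falsePositives`,
#'   `communityAri`, `communityAriAllFlagged`, `subtypeAri`, `flaggedMrs`.
#' @export
evaluateRecovery <- function(res) {
  gt <- studyNetwork(res$study)
  planted <- plantedMrs(gt)$tf
  flagged <- res$mrTable$tf[res$mrTable$is_mr]
  mm <- res$communities$mrMembership
  commAri <- mclust::adjustedRandIndex(
    mm[res$coreMrs], tfCommunities(gt)[res$coreMrs])
  commAriAll <- mclust::adjustedRandIndex(
    mm, tfCommunities(gt)[names(mm)])
  truth <- truthTable(res$study)
  idx <- match(res$subtypes$sample, truth$sample)
  subAri <- mclust::adjustedRandIndex(res$subtypes$subtype,
                                      truth$subtype[idx])
  list(
    recovered = length(intersect(flagged, planted)),
    nPlanted = length(planted),
    falsePositives = length(setdiff(flagged, planted)),
    communityAri = commAri,
    communityAriAllFlagged = commAriAll,
    subtypeAri = subAri,
    flaggedMrs = flagged
  )
}

#' Map discovered subtype clusters onto planted subtype labels
#'
#' Majority-vote matching: each discovered cluster is relabelled with the
#' planted subtype most common among its samples. Useful to compare
#' per-subtype planted parameters (hazard ratios, burden rates) with
#' estimates computed on the discovered clusters.
#'
#' @param subtypes data.frame from [clusterSubtypes()].
#' @param truth truth data.frame with `sample` and `subtype`.
#' @return data.frame `sample`, `subtype` with subtype in truth labels.
#' @export
matchSubtypesToTruth <- function(subtypes, truth) {
  idx <- match(subtypes$sample, truth$sample)
  if (anyNA(idx)) stop("truth is missing some samples")
  mapping <- vapply(split(truth$subtype[idx], subtypes$subtype), function(v)
    as.integer(names(sort(table(v), decreasing = TRUE))[1]), integer(1))
  data.frame(sample = subtypes$sample,
             subtype = mapping[as.character(subtypes$subtype)],
             stringsAsFactors = FALSE, row.names = NULL)
}
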