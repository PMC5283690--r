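# Accessor and show methods for the S4 containers.

#' @rdname accessors
setMethod("edges", "GroundTruthNetwork", function(x, ...) x@edges)
#' @rdname accessors
setMethod("edges", "EdgeTable", function(x, ...) x@edges)
#' @rdname accessors
setMethod("edges", "FusedEdgeTable", function(x, ...) x@edges)

#' @rdname accessors
setMethod("tfIds", "GroundTruthNetwork", function(x, ...) x@tfIds)
#' @rdname accessors
setMethod("tfIds", "RegulonSet", function(x, ...) x@tfIds)

#' @rdname accessors
setMethod("targetIds", "GroundTruthNetwork", function(x, ...) x@targetIds)

#' @rdname accessors
setMethod("plantedMrs", "GroundTruthNetwork", function(x, ...) x@plantedMrs)

#' @rdname accessors
setMethod("tfCommunities", "GroundTruthNetwork", function(x, ...) x@communityOfTf)

#' @rdname accessors
setMethod("cohortName", "EdgeTable", function(x, ...) x@cohort)

#' @rdname accessors
setMethod("nSamples", "EdgeTable", function(x, ...) x@nSamples)

#' @rdname accessors
setMethod("shrinkageLambda", "EdgeTable", function(x, ...) x@lambda)

#' @rdname accessors
setMethod("nullScale", "EdgeTable", function(x, ...) x@sigma0)

#' @rdname accessors
setMethod("cohortSizes", "FusedEdgeTable", function(x, ...) x@cohortSizes)

#' @rdname accessors
setMethod("regulonTable", "RegulonSet", function(x, ...) x@table)

#' @rdname accessors
setMethod("regulonSizes", "RegulonSet", function(x, ...) {
  sz <- table(factor(x@table$tf, levels = x@tfIds))
  stats::setNames(as.integer(sz), names(sz))
})

#' @rdname accessors
setMethod("regulonOf", "RegulonSet", function(x, tf, ...) {
  stopifnot(length(tf) == 1L)
  if (!tf %in% x@tfIds) stop("unknown TF: ", tf)
  x@table[x@table$tf == tf, c("target", "mode", "likelihood"), drop = FALSE]
})

#' @rdname accessors
setMethod("cohorts", "SyntheticStudy", function(x, ...) x@cohorts)
#' @rdname accessors
setMethod("perturbation", "SyntheticStudy", function(x, ...) x@perturbation)
#' @rdname accessors
setMethod("clinicalTable", "SyntheticStudy", function(x, ...) x@clinical)
#' @rdname accessors
setMethod("mutationTable", "SyntheticStudy", function(x, ...) x@mutations)
#' @rdname accessors
setMethod("truthTable", "SyntheticStudy", function(x, ...) x@truth)
#' @rdname accessors
setMethod("studyGeneSets", "SyntheticStudy", function(x, ...) x@geneSets)
#' @rdname accessors
setMethod("studyNetwork", "SyntheticStudy", function(x, ...) x@network)

setMethod("show", "GroundTruthNetwork", function(object) {
  cat("GroundTruthNetwork:", length(object@tfIds), "TFs,",
      length(object@targetIds), "targets,", nrow(object@edges), "edges\n")
  cat("  communities:", length(unique(object@communityOfTf)),
      " planted MRs:", nrow(object@plantedMrs), "\n")
})

setMethod("show", "SyntheticStudy", function(object) {
  ns <- vapply(object@cohorts, function(co) ncol(co$expr), integer(1))
  cat("SyntheticStudy:", length(object@cohorts), "cohorts (n =",
      paste(ns, collapse = ", "), ")\n")
  if (length(object@perturbation))
    cat("  perturbation:", ncol(object@perturbation$expr), "arrays\n")
  cat("  clinical rows:", nrow(object@clinical),
      " mutation rows:", nrow(object@mutations), "\n")
})

setMethod("show", "EdgeTable", function(object) {
  cat("EdgeTable [", object@cohort, "]: ", nrow(object@edges), " edges, n = ",
      object@nSamples, ", lambda = ", signif(object@lambda, 4), sep = "")
  if (!is.na(object@sigma0)) cat(", sigma0 =", signif(object@sigma0, 4))
  cat("\n")
})

setMethod("show", "FusedEdgeTable", function(object) {
  cat("FusedEdgeTable:", nrow(object@edges), "edges fused from",
      length(object@cohortSizes), "cohorts (min", object@minCohorts, ")\n")
})

setMethod("show", "RegulonSet", function(object) {
  sz <- regulonSizes(object)
  cat("RegulonSet:", length(object@tfIds), "TFs,", nrow(object@table),
      "regulon entries (", sum(sz == 0), "empty regulons )\n")
})
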