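#' @import methods
NULL

#' GroundTruthNetwork: a planted transcription-factor regulatory network
#'
#' Container for a simulated regulator-target network with known structure:
#' which genes are transcription factors (TFs), which targets each TF
#' regulates (with a sign, the mode of regulation, and a weight), how TFs
#' group into communities, and which TFs are planted master regulators
#' responsive to the perturbation.
#'
#' @slot tfIds character vector of TF gene identifiers.
#' @slot targetIds character vector of target gene identifiers (disjoint from
#'   `tfIds`).
#' @slot edges data.frame with columns `tf`, `target`, `sign` (-1/+1) and
#'   `weight` (in (0,1]).
#' @slot communityOfTf named integer vector mapping each TF to its community.
#' @slot plantedMrs data.frame with columns `tf` and `direction` (-1/+1), the
#'   regulators whose activity shifts under the perturbation.
#' @slot params list of generator parameters (for provenance).
#'
#' @aliases GroundTruthNetwork-class
#' @exportClass GroundTruthNetwork
setClass("GroundTruthNetwork",
  representation(
    tfIds = "character",
    targetIds = "character",
    edges = "data.frame",
    communityOfTf = "integer",
    plantedMrs = "data.frame",
    params = "list"
  )
)

setValidity("GroundTruthNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  need <- c("tf", "target", "sign", "weight")
  if (!all(need %in% names(ed))) {
    msg <- c(msg, "edges must have columns tf, target, sign, weight")
  } else {
    if (!all(ed$tf %in% object@tfIds)) msg <- c(msg, "every edge tf must be in tfIds")
    if (!all(ed$target %in% object@targetIds)) msg <- c(msg, "every edge target must be in targetIds")
    if (!all(ed$sign %in% c(-1, 1))) msg <- c(msg, "edge signs must be -1 or +1")
    if (any(ed$weight <= 0 | ed$weight > 1)) msg <- c(msg, "edge weights must lie in (0, 1]")
  }
  if (length(intersect(object@tfIds, object@targetIds)) > 0)
    msg <- c(msg, "tfIds and targetIds must be disjoint")
  if (!all(object@tfIds %in% names(object@communityOfTf)))
    msg <- c(msg, "every TF needs a community label")
  if (nrow(object@plantedMrs) > 0) {
    if (!all(c("tf", "direction") %in% names(object@plantedMrs)))
      msg <- c(msg, "plantedMrs must have columns tf, direction")
    else if (!all(object@plantedMrs$tf %in% object@tfIds))
      msg <- c(msg, "planted master regulators must be TFs")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticStudy: a full simulated multi-cohort study
#'
#' Bundles everything a synthetic study generates: the ground-truth network,
#' the expression cohorts (with batch labels), the two-condition perturbation
#' experiment, clinical and mutation tables, per-sample truth (subtype and
#' admixture fractions) and the stromal/immune marker gene sets.
#'
#' @slot network a [GroundTruthNetwork-class].
#' @slot cohorts list; each element a list with `expr` (gene-by-sample
#'   matrix), `batch` (factor) and `name`.
#' @slot perturbation list with `expr` (gene-by-sample matrix) and
#'   `condition` (factor with levels control/case).
#' @slot clinical data.frame (`sample`, `time`, `event`, `age`, `gender`,
#'   `stage`, `treated`).
#' @slot mutations data.frame (`sample`, `gene`, `impact`, `copy_number`).
#' @slot truth data.frame (`sample`, `cohort`, `subtype`, `f_stromal`,
#'   `f_immune`).
#' @slot geneSets list of character vectors (stromal and immune marker sets).
#' @slot params list of simulation parameters and seeds.
#'
#' @aliases SyntheticStudy-class
#' @exportClass SyntheticStudy
setClass("SyntheticStudy",
  representation(
    network = "GroundTruthNetwork",
    cohorts = "list",
    perturbation = "list",
    clinical = "data.frame",
    mutations = "data.frame",
    truth = "data.frame",
    geneSets = "list",
    params = "list"
  )
)

setValidity("SyntheticStudy", function(object) {
  msg <- character()
  for (co in object@cohorts) {
    if (!all(c("expr", "batch", "name") %in% names(co))) {
      msg <- c(msg, "each cohort must be a list with expr, batch, name")
      break
    }
    if (ncol(co$expr) != length(co$batch))
      msg <- c(msg, sprintf("cohort %s: batch labels must match sample count", co$name))
  }
  if (length(object@cohorts) > 1) {
    rn <- lapply(object@cohorts, function(co) rownames(co$expr))
    if (!all(vapply(rn[-1], identical, logical(1), y = rn[[1]])))
      msg <- c(msg, "all cohorts must share the same gene universe")
  }
  if (nrow(object@truth) > 0) {
    samples <- unlist(lapply(object@cohorts, function(co) colnames(co$expr)))
    if (!setequal(object@truth$sample, samples))
      msg <- c(msg, "truth table must cover exactly the cohort samples")
    fr <- c(object@truth$f_stromal, object@truth$f_immune)
    if (any(fr < 0 | fr > 1)) msg <- c(msg, "admixture fractions must lie in [0, 1]")
  }
  if (nrow(object@clinical) > 0) {
    if (any(object@clinical$time <= 0)) msg <- c(msg, "survival times must be positive")
    if (!all(object@clinical$event %in% c(0, 1))) msg <- c(msg, "events must be 0/1")
  }
  if (length(msg)) msg else TRUE
})

#' EdgeTable: per-cohort TF-target edge statistics
#'
#' Result of shrinkage partial-correlation network inference on one cohort.
#' Rows are regulator-target pairs with the partial correlation, Fisher-z
#' score, and empirical-null p/q values once [edgeSignificance()] has run.
#'
#' @slot edges data.frame with columns `tf`, `target`, `pcor`, `z`, `p`, `q`.
#' @slot cohort cohort identifier.
#' @slot nSamples number of samples the network was inferred from.
#' @slot lambda shrinkage intensity lambda* in [0, 1].
#' @slot sigma0 empirical null scale on the Fisher-z axis (NA before
#'   [edgeSignificance()]).
#'
#' @aliases EdgeTable-class
#' @exportClass EdgeTable
setClass("EdgeTable",
  representation(
    edges = "data.frame",
    cohort = "character",
    nSamples = "integer",
    lambda = "numeric",
    sigma0 = "numeric"
  )
)

setValidity("EdgeTable", function(object) {
  msg <- character()
  ed <- object@edges
  if (!all(c("tf", "target", "pcor") %in% names(ed)))
    msg <- c(msg, "edges must have columns tf, target, pcor")
  else {
    if (anyDuplicated(paste(ed$tf, ed$target)))
      msg <- c(msg, "(tf, target) pairs must be unique")
    if (any(abs(ed$pcor) > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "|pcor| must be <= 1")
  }
  if (length(object@lambda) == 1 && !is.na(object@lambda) &&
      (object@lambda < 0 || object@lambda > 1))
    msg <- c(msg, "lambda must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' FusedEdgeTable: Stouffer-fused multi-cohort edge statistics
#'
#' @slot edges data.frame with columns `tf`, `target`, per-cohort signed
#'   z-scores (`z.<cohort>`), `Z` (combined), `p`, `q` and
#'   `n_cohorts` (cohorts in which the edge was measured).
#' @slot cohortSizes named numeric vector of per-cohort sample sizes.
#' @slot minCohorts minimum number of cohorts an edge had to be measured in.
#'
#' @aliases FusedEdgeTable-class
#' @exportClass FusedEdgeTable
setClass("FusedEdgeTable",
  representation(
    edges = "data.frame",
    cohortSizes = "numeric",
    minCohorts = "integer"
  )
)

setValidity("FusedEdgeTable", function(object) {
  msg <- character()
  ed <- object@edges
  if (!all(c("tf", "target", "Z", "p", "q", "n_cohorts") %in% names(ed)))
    msg <- c(msg, "edges must have columns tf, target, Z, p, q, n_cohorts")
  else {
    if (any(!is.finite(ed$Z))) msg <- c(msg, "combined Z must be finite")
    if (nrow(ed) > 0 && any(ed$n_cohorts < object@minCohorts))
      msg <- c(msg, "edges present in fewer than minCohorts cohorts must be dropped")
  }
  if (length(msg)) msg else TRUE
})

#' RegulonSet: per-TF target lists with mode and likelihood
#'
#' The regulon of a transcription factor is the set of its inferred targets;
#' each target carries a mode of regulation (the sign of the generating
#' statistic) and a likelihood weight in (0, 1]. TFs whose regulons came out
#' empty are retained in `tfIds` so downstream code can report them.
#'
#' @slot table data.frame with columns `tf`, `target`, `mode`, `likelihood`.
#' @slot tfIds all TFs considered, including those with empty regulons.
#' @slot params list (provenance: thresholds, source).
#'
#' @aliases RegulonSet-class
#' @exportClass RegulonSet
setClass("RegulonSet",
  representation(
    table = "data.frame",
    tfIds = "character",
    params = "list"
  )
)

setValidity("RegulonSet", function(object) {
  msg <- character()
  tb <- object@table
  if (!all(c("tf", "target", "mode", "likelihood") %in% names(tb)))
    msg <- c(msg, "table must have columns tf, target, mode, likelihood")
  else if (nrow(tb) > 0) {
    if (any(tb$tf == tb$target)) msg <- c(msg, "self-loops are not allowed")
    if (!all(tb$mode %in% c(-1, 1))) msg <- c(msg, "modes must be -1 or +1")
    if (any(tb$likelihood <= 0 | tb$likelihood > 1))
      msg <- c(msg, "likelihoods must lie in (0, 1]")
    if (!all(tb$tf %in% object@tfIds))
      msg <- c(msg, "every regulon TF must appear in tfIds")
  }
  if (length(msg)) msg else TRUE
})
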