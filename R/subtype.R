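#' Build the master-regulator regulatory graph
#'
#' Undirected simple graph whose nodes are the flagged master regulators
#' plus the targets in their (integrated) regulons, with one edge per
#' regulon entry (parallel edges collapsed).
#'
#' @param mrTable data.frame from [regulonEnrichment()] (uses the `is_mr`
#'   flag).
#' @param regs a [RegulonSet-class].
#' @return An [igraph::igraph] with logical vertex attribute `isMr`.
#' @export
buildRegulatoryGraph <- function(mrTable, regs) {
  stopifnot(is.data.frame(mrTable), is(regs, "RegulonSet"))
  mrs <- mrTable$tf[mrTable$is_mr]
  if (length(mrs) == 0) stop("no flagged master regulators")
  tb <- regs@table[regs@table$tf %in% mrs, c("tf", "target"), drop = FALSE]
  g <- igraph::graph_from_data_frame(tb, directed = FALSE,
                                     vertices = unique(c(mrs, tb$target)))
  g <- igraph::simplify(g)
  igraph::V(g)$isMr <- igraph::V(g)$name %in% mrs
  g
}

#' Greedy-modularity community detection
#'
#' Clauset-Newman-Moore fast greedy modularity optimization (via igraph):
#' starting from singleton communities, the merge with maximal modularity
#' gain is applied repeatedly and the partition with maximal Q is returned.
#' Target nodes participate in modularity alongside the regulators. A graph
#' with no edges yields the singleton partition with Q = 0.
#'
#' @param g an undirected [igraph::igraph] (multi-edges/self-loops are
#'   collapsed first).
#' @return list with `membership` (named integer vector), `modularity`
#'   (numeric Q) and `mrMembership` (membership restricted to nodes flagged
#'   `isMr`, when the attribute exists).
#' @export
detectCommunities <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0) stop("graph is empty")
  g <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  if (igraph::ecount(g) == 0) {
    memb <- stats::setNames(seq_len(igraph::vcount(g)), igraph::V(g)$name)
    q <- 0
  } else {
    cl <- igraph::cluster_fast_greedy(g)
    memb <- stats::setNames(as.integer(igraph::membership(cl)),
                            igraph::V(g)$name)
    q <- max(cl$modularity)
  }
  mrMemb <- NULL
  if ("isMr" %in% igraph::vertex_attr_names(g))
    mrMemb <- memb[igraph::V(g)$name[igraph::V(g)$isMr]]
  list(membership = memb, modularity = q, mrMembership = mrMemb)
}

#' Hypergeometric annotation of communities against gene sets
#'
#' For every community x gene set pair, the upper-tail hypergeometric
#' probability P(X >= k) of the observed overlap, with the graph's node set
#' as the population. Benjamini-Hochberg runs across the whole table and
#' rows at FDR < `fdrMax` are flagged.
#'
#' @param partition list from [detectCommunities()].
#' @param sets named list of character vectors (e.g. from [readGmt()]).
#' @param fdrMax FDR flag threshold (default 0.01).
#' @return data.frame `community`, `set`, `overlap`, `community_size`,
#'   `set_size`, `universe`, `p`, `fdr`, `significant`.
#' @export
annotateCommunities <- function(partition, sets, fdrMax = 0.01) {
  if (length(sets) == 0) stop("gene-set collection is empty")
  memb <- partition$membership
  universe <- names(memb)
  N <- length(universe)
  rows <- list()
  for (cm in sort(unique(memb))) {
    commGenes <- universe[memb == cm]
    for (sn in names(sets)) {
      setGenes <- intersect(sets[[sn]], universe)
      k <- length(intersect(setGenes, commGenes))
      p <- if (length(setGenes) == 0) 1 else
        stats::phyper(k - 1, length(setGenes), N - length(setGenes),
                      length(commGenes), lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        community = cm, set = sn, overlap = k,
        community_size = length(commGenes), set_size = length(setGenes),
        universe = N, p = p, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$fdr < fdrMax
  out
}

#' Signature distance between samples on regulator activity profiles
#'
#' d(a, b) = 1 - cor(activity_a, activity_b), Pearson by default (Spearman
#' behind the `method` flag); symmetric with zero diagonal, range [0, 2].
#'
#' @param act regulator-by-sample activity matrix (>= 2 samples and >= 2
#'   regulators).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return sample-by-sample distance matrix.
#' @export
signatureDistance <- function(act, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  act <- as.matrix(act)
  if (ncol(act) < 2 || nrow(act) < 2)
    stop("need >= 2 samples and >= 2 regulators")
  sds <- apply(act, 2, stats::sd)
  if (any(sds == 0))
    stop("constant activity profile for sample(s): ",
         paste(utils::head(colnames(act)[sds == 0], 5), collapse = ", "))
  d <- 1 - stats::cor(act, method = method)
  diag(d) <- 0
  d
}

#' Subtype assignment by average-linkage hierarchical clustering
#'
#' Agglomerative average-linkage clustering of the signature-distance
#' matrix, cut into `k` clusters. Deterministic given the distance matrix.
#'
#' @param d sample-by-sample distance matrix (e.g. [signatureDistance()]).
#' @param k number of subtypes (default 3; must be <= number of samples).
#' @return data.frame `sample`, `subtype` (integer 1..k), with attributes
#'   `k` and `linkage`.
#' @export
clusterSubtypes <- function(d, k = 3) {
  d <- as.matrix(d)
  k <- .checkCount(k, "k", min = 2L)
  if (k > ncol(d)) stop("k must not exceed the number of samples")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ct <- stats::cutree(hc, k = k)
  out <- data.frame(sample = names(ct), subtype = as.integer(ct),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "k") <- k
  attr(out, "linkage") <- "average"
  out
}

#' Master regulators of the core disease processes
#'
#' Default rule selecting which flagged MRs define the per-sample subtyping:
#' the MRs belonging to the `nCore` communities with the most MR members
#' (ties broken by smaller community label).
#'
#' @param partition list from [detectCommunities()] (needs `mrMembership`).
#' @param nCore number of core communities to keep (default 3).
#' @return character vector of MR ids, with the kept community labels as
#'   attribute `communities`.
#' @export
coreMasterRegulators <- function(partition, nCore = 3) {
  mm <- partition$mrMembership
  if (is.null(mm) || length(mm) == 0) stop("partition carries no MR membership")
  counts <- sort(table(mm), decreasing = TRUE)
  keep <- as.integer(names(counts))[seq_len(min(nCore, length(counts)))]
  out <- names(mm)[mm %in% keep]
  attr(out, "communities") <- keep
  out
}
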