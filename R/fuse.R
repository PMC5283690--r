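#' Fuse per-cohort edge tables by size-weighted Stouffer meta-analysis
#'
#' Each cohort's edge p-value is converted to a signed z-score,
#' z_i = sign(pcor_i) * qnorm(1 - p_i/2), and edges are combined with
#' weights w_i = sqrt(n_i) over the cohorts in which the edge's genes were
#' measured: Z = sum(w_i z_i) / sqrt(sum(w_i^2)). Absent measurements are
#' skipped (weight set reduced), not imputed as zero. Edges measured in
#' fewer than `minCohorts` cohorts are dropped; Benjamini-Hochberg runs once
#' over the surviving fused edges.
#'
#' @param tables list of [EdgeTable-class] objects (after
#'   [edgeSignificance()]).
#' @param minCohorts minimum number of cohorts an edge must be measured in
#'   (default 4).
#' @return A [FusedEdgeTable-class].
#' @export
stoufferFuse <- function(tables, minCohorts = 4L) {
  if (length(tables) < 1) stop("need at least one edge table")
  stopifnot(all(vapply(tables, is, logical(1), "EdgeTable")))
  minCohorts <- .checkCount(minCohorts, "minCohorts")
  minCohorts <- min(minCohorts, length(tables))
  nms <- vapply(tables, cohortName, character(1))
  if (anyDuplicated(nms)) nms <- make.unique(nms)
  sizes <- stats::setNames(vapply(tables, nSamples, integer(1)), nms)

  keys <- lapply(tables, function(et) {
    ed <- edges(et)
    k <- paste(ed$tf, ed$target, sep = "\r")
    if (anyDuplicated(k))
      stop("cohort ", cohortName(et), " has duplicate edges")
    k
  })
  allKeys <- unique(unlist(keys, use.names = FALSE))
  zMat <- matrix(NA_real_, length(allKeys), length(tables),
                 dimnames = list(NULL, nms))
  for (i in seq_along(tables)) {
    ed <- edges(tables[[i]])
    zMat[match(keys[[i]], allKeys), i] <- .signedZ(ed$p, sign(ed$pcor))
  }
  present <- !is.na(zMat)
  w <- sqrt(sizes)
  W <- matrix(w, length(allKeys), length(tables), byrow = TRUE)
  W[!present] <- 0
  zs <- zMat
  zs[!present] <- 0
  Z <- rowSums(W * zs) / sqrt(rowSums(W^2))
  nPresent <- rowSums(present)

  keep <- nPresent >= minCohorts
  parts <- strsplit(allKeys[keep], "\r", fixed = TRUE)
  out <- data.frame(
    tf = vapply(parts, `[[`, character(1), 1L),
    target = vapply(parts, `[[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  zdf <- as.data.frame(zMat[keep, , drop = FALSE])
  names(zdf) <- paste0("z.", nms)
  out <- cbind(out, zdf)
  out$Z <- Z[keep]
  out$p <- 2 * stats::pnorm(abs(out$Z), lower.tail = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$n_cohorts <- nPresent[keep]
  rownames(out) <- NULL
  methods::new("FusedEdgeTable", edges = out, cohortSizes = as.numeric(sizes),
               minCohorts = as.integer(minCohorts))
}

#' Integrated regulons from the fused network
#'
#' Per TF, targets with fused q < `qMax` (strict); mode is the sign of the
#' combined Z and likelihood is 1 - q. Sign-discordant edges whose cohort
#' z-scores cancel to Z = 0 are never significant and drop out naturally.
#'
#' @param fet a [FusedEdgeTable-class].
#' @param qMax FDR cutoff (default 0.05).
#' @return A [RegulonSet-class].
#' @export
integratedRegulons <- function(fet, qMax = 0.05) {
  stopifnot(is(fet, "FusedEdgeTable"))
  ed <- fet@edges
  sel <- ed$q < qMax & ed$Z != 0
  tb <- data.frame(
    tf = ed$tf[sel], target = ed$target[sel],
    mode = sign(ed$Z[sel]),
    likelihood = 1 - ed$q[sel],
    stringsAsFactors = FALSE
  )
  rownames(tb) <- NULL
  methods::new("RegulonSet", table = tb, tfIds = unique(ed$tf),
               params = list(qMax = qMax, source = "fused"))
}

#' Cross-cohort regulon conservation diagnostics
#'
#' For every cohort pair: the Pearson correlation of edge z-scores over the
#' shared edges (all shared edges, and the subset significant at q < `qMax`
#' in both cohorts), and a per-TF hypergeometric overlap test of the two
#' significant regulons against the TF's shared target universe.
#'
#' @param tables list of >= 2 [EdgeTable-class] objects (after
#'   [edgeSignificance()]).
#' @param qMax FDR cutoff defining a significant edge (default 0.05).
#' @return list with `edgeCor` (data.frame `cohort1`, `cohort2`, `r_all`,
#'   `n_all`, `r_significant`, `n_significant`) and `regulonOverlap`
#'   (data.frame `cohort1`, `cohort2`, `tf`, `overlap`, `size1`, `size2`,
#'   `universe`, `p`).
#' @export
regulonConservation <- function(tables, qMax = 0.05) {
  if (length(tables) < 2) stop("need at least two edge tables")
  stopifnot(all(vapply(tables, is, logical(1), "EdgeTable")))
  nms <- vapply(tables, cohortName, character(1))
  if (anyDuplicated(nms)) nms <- make.unique(nms)
  eds <- lapply(tables, edges)
  keys <- lapply(eds, function(ed) paste(ed$tf, ed$target, sep = "\r"))

  corRows <- list()
  ovRows <- list()
  for (i in seq_len(length(tables) - 1)) {
    for (j in seq(i + 1, length(tables))) {
      shared <- intersect(keys[[i]], keys[[j]])
      if (length(shared) == 0)
        stop("cohorts ", nms[i], " and ", nms[j], " share no edges")
      ii <- match(shared, keys[[i]])
      jj <- match(shared, keys[[j]])
      zi <- eds[[i]]$z[ii]; zj <- eds[[j]]$z[jj]
      qi <- eds[[i]]$q[ii]; qj <- eds[[j]]$q[jj]
      both <- qi < qMax & qj < qMax
      safeCor <- function(a, b) {
        if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0)
          return(NA_real_)
        stats::cor(a, b)
      }
      rAll <- safeCor(zi, zj)
      rSig <- safeCor(zi[both], zj[both])
      corRows[[length(corRows) + 1L]] <- data.frame(
        cohort1 = nms[i], cohort2 = nms[j], r_all = rAll,
        n_all = length(shared), r_significant = rSig,
        n_significant = sum(both), stringsAsFactors = FALSE
      )
      tfShared <- eds[[i]]$tf[ii]
      tgShared <- eds[[i]]$target[ii]
      for (tf in unique(tfShared)) {
        rows <- tfShared == tf
        uni <- tgShared[rows]
        a <- tgShared[rows & qi < qMax]
        b <- tgShared[rows & qj < qMax]
        k <- length(intersect(a, b))
        pOv <- if (length(a) == 0 || length(b) == 0) 1 else
          stats::phyper(k - 1, length(a), length(uni) - length(a),
                        length(b), lower.tail = FALSE)
        ovRows[[length(ovRows) + 1L]] <- data.frame(
          cohort1 = nms[i], cohort2 = nms[j], tf = tf, overlap = k,
          size1 = length(a), size2 = length(b), universe = length(uni),
          p = pOv, stringsAsFactors = FALSE
        )
      }
    }
  }
  list(edgeCor = do.call(rbind, corRows),
       regulonOverlap = do.call(rbind, ovRows))
}
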