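#' Regulon enrichment and master-regulator calling
#'
#' aREA-style directed enrichment of each regulon in a ranked
#' differential-expression signature. Signature genes are ranked by
#' moderated t (ascending, average ties) and mapped to normal quantile
#' scores q_g = qnorm(rank / (N + 1)). For a regulon with targets j, modes
#' m_j and likelihood weights w_j, the enrichment score is
#' ES = sum(w_j m_j q_j) / sqrt(sum(w_j^2)), which is standard normal under
#' the null of unrelated targets, so NES = ES and the two-sided p follows
#' directly. A TF is flagged a master regulator when p < `pMr` and at least
#' `minSize` of its targets are covered by the signature.
#'
#' @param sig signature data.frame from [moderatedTTest()].
#' @param regs a [RegulonSet-class].
#' @param minSize minimum signature-covered regulon size (default 10);
#'   smaller regulons are skipped with a message.
#' @param pMr master-regulator p-value threshold (default 0.01, strict `<`).
#' @return data.frame with one row per tested TF: `tf`, `nes`, `p`, `q`,
#'   `size`, `is_mr`. Skipped TFs are reported in attribute `skipped`.
#' @export
regulonEnrichment <- function(sig, regs, minSize = 10, pMr = 0.01) {
  stopifnot(is.data.frame(sig), is(regs, "RegulonSet"))
  minSize <- .checkCount(minSize, "minSize")
  qs <- stats::setNames(.quantileScores(sig$t), sig$gene)
  tb <- regs@table
  tb <- tb[tb$target %in% names(qs), , drop = FALSE]
  sizes <- table(factor(tb$tf, levels = regs@tfIds))
  tested <- names(sizes)[sizes >= minSize]
  skipped <- setdiff(regs@tfIds, tested)
  if (length(skipped))
    message(length(skipped), " regulon(s) below minSize skipped")
  if (length(tested) == 0) stop("no regulon covered by >= minSize signature genes")
  es <- vapply(tested, function(tf) {
    rr <- tb[tb$tf == tf, , drop = FALSE]
    sum(rr$likelihood * rr$mode * qs[rr$target]) /
      sqrt(sum(rr$likelihood^2))
  }, numeric(1))
  p <- 2 * stats::pnorm(abs(es), lower.tail = FALSE)
  out <- data.frame(
    tf = tested, nes = unname(es), p = unname(p),
    q = stats::p.adjust(p, method = "BH"),
    size = as.integer(sizes[tested]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$is_mr <- out$p < pMr
  out <- out[order(out$p, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "pMr") <- pMr
  attr(out, "minSize") <- minSize
  out
}

#' Permutation null for the regulon-enrichment statistic
#'
#' Independent oracle for the analytic null of [regulonEnrichment()]: the
#' signature's gene labels are permuted `nPerm` times and the two-sided
#' empirical p-value is (1 + #\{|ES_perm| >= |ES_obs|\}) / (nPerm + 1).
#'
#' @param sig signature data.frame from [moderatedTTest()].
#' @param regulon data.frame with columns `target`, `mode`, `likelihood`
#'   (e.g. from [regulonOf()]).
#' @param nPerm number of permutations (>= 1000 recommended; >= 1 enforced).
#' @param seed integer seed.
#' @return list with `es` (observed), `p` (empirical), `esPerm` (numeric
#'   vector of permuted scores).
#' @export
permutationNull <- function(sig, regulon, nPerm = 1000, seed = 1) {
  stopifnot(is.data.frame(sig), is.data.frame(regulon))
  nPerm <- .checkCount(nPerm, "nPerm")
  set.seed(seed)
  qs <- stats::setNames(.quantileScores(sig$t), sig$gene)
  regulon <- regulon[regulon$target %in% names(qs), , drop = FALSE]
  if (nrow(regulon) == 0) stop("regulon shares no genes with the signature")
  wm <- regulon$likelihood * regulon$mode
  denom <- sqrt(sum(regulon$likelihood^2))
  esObs <- sum(wm * qs[regulon$target]) / denom
  N <- length(qs)
  k <- nrow(regulon)
  esPerm <- vapply(seq_len(nPerm), function(b) {
    sum(wm * qs[sample.int(N, k)]) / denom
  }, numeric(1))
  list(es = esObs,
       p = (1 + sum(abs(esPerm) >= abs(esObs))) / (nPerm + 1),
       esPerm = esPerm)
}

#' Single-sample regulator activity inference
#'
#' Each sample's signature is its gene-wise z-score across the cohort
#' ((x - mean) / sd per gene); the regulon-enrichment score formula of
#' [regulonEnrichment()] is then applied per sample and per regulon, giving
#' an MR-by-sample activity matrix. A sample equal to the cohort gene-wise
#' mean therefore has activity 0 for every regulator.
#'
#' @param expr gene-by-sample matrix (>= 10 samples recommended for stable
#'   scaling).
#' @param regs a [RegulonSet-class].
#' @param mrSubset TFs to score (default: all TFs of `regs` with nonempty
#'   regulons). Must be a subset of the regulon TFs.
#' @param scaling `"zscore"` (default) or `"mad"` (median/MAD) gene scaling.
#' @return numeric matrix, regulators by samples.
#' @export
singleSampleActivity <- function(expr, regs, mrSubset = NULL,
                                 scaling = c("zscore", "mad")) {
  stopifnot(is(regs, "RegulonSet"))
  scaling <- match.arg(scaling)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expr must have gene rownames")
  tb <- regs@table
  if (is.null(mrSubset)) mrSubset <- unique(tb$tf)
  if (!all(mrSubset %in% regs@tfIds))
    stop("mrSubset must be a subset of the regulon TFs")

  if (scaling == "zscore") {
    mu <- rowMeans(expr)
    sdv <- apply(expr, 1, stats::sd)
  } else {
    mu <- apply(expr, 1, stats::median)
    sdv <- apply(expr, 1, stats::mad)
  }
  zero <- sdv == 0
  if (any(zero)) {
    message("dropping ", sum(zero), " zero-variance gene(s)")
    expr <- expr[!zero, , drop = FALSE]
    mu <- mu[!zero]; sdv <- sdv[!zero]
  }
  Zs <- (expr - mu) / sdv
  N <- nrow(Zs)
  Q <- apply(Zs, 2, function(col)
    stats::qnorm(rank(col, ties.method = "average") / (N + 1)))
  rownames(Q) <- rownames(Zs)

  act <- matrix(NA_real_, length(mrSubset), ncol(expr),
                dimnames = list(mrSubset, colnames(expr)))
  for (tf in mrSubset) {
    rr <- tb[tb$tf == tf & tb$target %in% rownames(Q), , drop = FALSE]
    if (nrow(rr) == 0) {
      act[tf, ] <- 0
      next
    }
    wm <- rr$likelihood * rr$mode
    act[tf, ] <- as.vector(wm %*% Q[rr$target, , drop = FALSE]) /
      sqrt(sum(rr$likelihood^2))
  }
  act
}
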