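#' Moderated t-test differential expression signature
#'
#' Computes a per-gene two-condition differential expression signature with
#' empirical-Bayes variance moderation. Per gene the pooled variance s_g^2
#' carries d_g = n1 + n2 - 2 residual degrees of freedom; a scaled
#' inverse-chi-square prior (d0, s0^2) is estimated by moment-matching the
#' log sample variances (digamma/trigamma inversion), the posterior variance
#' is s~^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g), and the moderated t is the
#' log2 fold-change over s~ * sqrt(1/n1 + 1/n2), referred to a t
#' distribution with d0 + d_g degrees of freedom. Q-values are
#' Benjamini-Hochberg.
#'
#' @param expr gene-by-sample matrix on a log2-like scale.
#' @param labels factor or character of length `ncol(expr)` with exactly two
#'   levels.
#' @param ref the reference (control) level; log2 fold-changes are
#'   case minus reference. Defaults to the first factor level.
#' @param d0 optional fixed prior degrees of freedom, bypassing estimation
#'   (0 = no shrinkage, `Inf` = full shrinkage to the common variance).
#' @return data.frame with one row per gene: `gene`, `log2fc`, `t`, `p`,
#'   `q`, `df_total`; the estimated prior is attached as attributes `d0` and
#'   `s02`.
#' @examples
#' gt <- generateGroundTruth(4, 8, 2, 0, 2, seed = 1)
#' pe <- simulatePerturbation(gt, effect = 2, nReps = 4, seed = 1)
#' sig <- moderatedTTest(pe$expr, pe$condition)
#' head(sig)
#' @export
moderatedTTest <- function(expr, labels, ref = NULL, d0 = NULL) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expr must have gene rownames")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene IDs in expr")
  if (!all(is.finite(expr))) stop("expr must be finite")
  labels <- as.factor(labels)
  if (length(labels) != ncol(expr)) stop("labels must match ncol(expr)")
  lev <- levels(droplevels(labels))
  if (length(lev) != 2) stop("labels must have exactly two levels")
  if (is.null(ref)) ref <- lev[1]
  if (!ref %in% lev) stop("ref must be one of the label levels")
  caseLev <- setdiff(lev, ref)
  i1 <- which(labels == ref)
  i2 <- which(labels == caseLev)
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2) stop("need >= 2 replicates per condition")

  m1 <- rowMeans(expr[, i1, drop = FALSE])
  m2 <- rowMeans(expr[, i2, drop = FALSE])
  lfc <- m2 - m1
  rss <- rowSums((expr[, i1, drop = FALSE] - m1)^2) +
    rowSums((expr[, i2, drop = FALSE] - m2)^2)
  dg <- n1 + n2 - 2
  s2 <- rss / dg
  zeroVar <- s2 <= 0
  if (any(zeroVar))
    stop("zero-variance genes, cannot moderate: ",
         paste(utils::head(rownames(expr)[zeroVar], 5), collapse = ", "),
         if (sum(zeroVar) > 5) " ..." else "")

  if (is.null(d0)) {
    # moment-matching on the log-variance scale
    e <- log(s2) - digamma(dg / 2) + log(dg / 2)
    emean <- mean(e)
    evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(dg / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigammaInverse(evar)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      warning("prior df estimation failed; falling back to d0 = Inf")
      d0 <- Inf
      s02 <- exp(emean)
    }
  } else {
    if (length(d0) != 1 || d0 < 0) stop("d0 must be a single nonnegative value")
    e <- log(s2) - digamma(dg / 2) + log(dg / 2)
    s02 <- if (is.finite(d0) && d0 > 0)
      exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)) else exp(mean(e))
  }

  s2post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + dg * s2) / (d0 + dg)
  tstat <- lfc / sqrt(s2post * (1 / n1 + 1 / n2))
  dfTotal <- d0 + dg
  p <- 2 * stats::pt(-abs(tstat), df = dfTotal)
  out <- data.frame(
    gene = rownames(expr), log2fc = lfc, t = tstat, p = p,
    q = stats::p.adjust(p, method = "BH"), df_total = dfTotal,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

#' Map a signature across species through an ortholog table
#'
#' Genes without an ortholog are dropped. When several source genes map to
#' the same target gene, the row with the smallest p-value is kept (ties
#' broken by lexicographic source gene ID). Output gene IDs are in the
#' target namespace; the original ID is kept in `source_gene`.
#'
#' @param sig signature data.frame from [moderatedTTest()].
#' @param map data.frame whose first two columns are source and target IDs.
#' @return The mapped signature data.frame.
#' @export
mapOrthologs <- function(sig, map) {
  stopifnot(is.data.frame(sig), "gene" %in% names(sig))
  map <- as.data.frame(map)[, 1:2]
  names(map) <- c("source", "target")
  if (anyDuplicated(map$source)) stop("ortholog map has duplicate source IDs")
  idx <- match(sig$gene, map$source)
  keep <- !is.na(idx)
  if (!any(keep)) stop("signature and ortholog map share no genes")
  out <- sig[keep, , drop = FALSE]
  out$source_gene <- out$gene
  out$gene <- map$target[idx[keep]]
  out <- out[order(out$gene, out$p, out$source_gene), , drop = FALSE]
  out <- out[!duplicated(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Threshold a signature into a differentially-expressed gene list
#'
#' Keeps genes with p < `pMax` and |log2 fold-change| > `lfcMin`, ordered by
#' decreasing |moderated t| (ties by gene ID).
#'
#' @param sig signature data.frame from [moderatedTTest()].
#' @param pMax p-value cutoff (default 0.05).
#' @param lfcMin absolute log2 fold-change cutoff (default 1).
#' @return Character vector of gene IDs.
#' @export
thresholdSignature <- function(sig, pMax = 0.05, lfcMin = 1) {
  stopifnot(pMax > 0, lfcMin > 0)
  hit <- sig$p < pMax & abs(sig$log2fc) > lfcMin
  hits <- sig[hit, , drop = FALSE]
  hits$gene[order(-abs(hits$t), hits$gene)]
}
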