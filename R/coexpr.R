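#' Batch-correct and standardize a cohort expression matrix
#'
#' Gene-wise per-batch mean-centering followed by pooled-scale
#' standardization (one scale per gene across all batches, with the batch
#' means removed). This removes the location component of additive batch
#' effects. Zero-variance genes are dropped with a message.
#'
#' @param expr gene-by-sample matrix.
#' @param batch optional factor of batch labels (one per sample); `NULL`
#'   treats the cohort as a single batch. Every batch needs >= 3 samples.
#' @return The standardized matrix (possibly with fewer rows).
#' @export
preprocessCohort <- function(expr, batch = NULL) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expr must have gene rownames")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene IDs in expr")
  n <- ncol(expr)
  if (is.null(batch)) batch <- factor(rep(1L, n))
  batch <- droplevels(as.factor(batch))
  if (length(batch) != n) stop("batch labels must match sample count")
  sizes <- table(batch)
  if (any(sizes < 3))
    stop("each batch needs >= 3 samples; too small: ",
         paste(names(sizes)[sizes < 3], collapse = ", "))

  centred <- expr
  for (b in levels(batch)) {
    idx <- batch == b
    centred[, idx] <- expr[, idx] - rowMeans(expr[, idx, drop = FALSE])
  }
  # pooled scale: residual sd after removing batch means
  df <- n - nlevels(batch)
  s <- sqrt(rowSums(centred^2) / df)
  zero <- s <= .Machine$double.eps * 10
  if (any(zero)) {
    message("dropping ", sum(zero), " zero-variance gene(s): ",
            paste(utils::head(rownames(expr)[zero], 5), collapse = ", "))
    centred <- centred[!zero, , drop = FALSE]
    s <- s[!zero]
  }
  centred / s
}

#' Shrinkage partial correlations between regulators and targets
#'
#' Schafer-Strimmer shrinkage of the sample correlation matrix toward the
#' identity: the analytic intensity is
#' lambda* = sum of estimated variances of the off-diagonal correlations
#' over the sum of their squares, clipped to [0, 1]. Partial correlations
#' come from the inverse of the shrunk correlation matrix,
#' pcor_ij = -omega_ij / sqrt(omega_ii * omega_jj). Only regulator rows are
#' emitted (TF x non-TF pairs), keeping the table at O(|TF| * G).
#'
#' @param expr gene-by-sample matrix (>= 4 samples, >= 2 genes).
#' @param tfs character vector of regulator gene IDs.
#' @param lambda optional fixed shrinkage intensity in [0, 1]; `NULL`
#'   (default) uses the analytic estimate.
#' @param cohort cohort identifier stored in the result.
#' @return An [EdgeTable-class] with `pcor` filled and `z`, `p`, `q` set to
#'   `NA` until [edgeSignificance()].
#' @export
shrinkagePartialCorrelation <- function(expr, tfs, lambda = NULL,
                                        cohort = "cohort") {
  expr <- as.matrix(expr)
  if (!all(is.finite(expr))) stop("expr must be finite")
  if (is.null(rownames(expr))) stop("expr must have gene rownames")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene IDs in expr")
  n <- ncol(expr)
  p <- nrow(expr)
  if (n < 4) stop("need >= 4 samples")
  if (p < 2) stop("need >= 2 genes")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    message("dropping ", sum(sds == 0), " zero-variance gene(s)")
    expr <- expr[sds > 0, , drop = FALSE]
    p <- nrow(expr)
  }
  tfs <- intersect(tfs, rownames(expr))
  if (length(tfs) == 0) stop("no TF present in the expression matrix")

  X <- scale(t(expr))                       # n x p, unit sd (denominator n-1)
  S1 <- crossprod(X)                        # sum_k x_ki x_kj
  R <- S1 / (n - 1)
  if (is.null(lambda)) {
    S2 <- crossprod(X^2)                    # sum_k (x_ki x_kj)^2
    varR <- n / (n - 1)^3 * (S2 - S1^2 / n)
    diag(varR) <- 0
    R2 <- R^2
    diag(R2) <- 0
    denom <- sum(R2)
    lambda <- if (denom > 0) min(1, max(0, sum(varR) / denom)) else 1
  } else {
    if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  }
  Rstar <- (1 - lambda) * R
  diag(Rstar) <- 1
  Omega <- tryCatch(solve(Rstar), error = function(e)
    stop("shrunk correlation matrix is singular: ", conditionMessage(e)))
  d <- sqrt(diag(Omega))
  P <- -Omega / tcrossprod(d)
  diag(P) <- 1

  genes <- rownames(expr)
  if (length(genes) <= length(tfs)) stop("no non-TF target genes in expr")
  sub <- P[tfs, , drop = FALSE]
  ed <- data.frame(
    tf = rep(tfs, times = length(genes)),
    target = rep(genes, each = length(tfs)),
    pcor = as.vector(sub),
    z = NA_real_, p = NA_real_, q = NA_real_,
    stringsAsFactors = FALSE
  )
  # regulator-centric table: a TF's regulon may contain other TFs, but not itself
  ed <- ed[ed$tf != ed$target, , drop = FALSE]
  rownames(ed) <- NULL
  methods::new("EdgeTable", edges = ed, cohort = as.character(cohort),
               nSamples = as.integer(n), lambda = as.numeric(lambda),
               sigma0 = NA_real_)
}

#' Empirical-null edge significance
#'
#' Partial correlations are mapped to the Fisher-z axis (atanh); the null
#' width sigma0 is estimated robustly as MAD(z)/0.6745 over all edges, so a
#' minority of true edges does not inflate it. Two-sided p-values come from
#' the Normal(0, sigma0) null and q-values from Benjamini-Hochberg.
#'
#' @param et an [EdgeTable-class] with `pcor` filled.
#' @return The [EdgeTable-class] with `z`, `p`, `q` and `sigma0` filled.
#' @export
edgeSignificance <- function(et) {
  stopifnot(is(et, "EdgeTable"))
  ed <- et@edges
  if (nrow(ed) < 100)
    warning("fewer than 100 edges; null scale estimate may be unstable")
  pc <- pmin(pmax(ed$pcor, -1 + 1e-15), 1 - 1e-15)
  z <- atanh(pc)
  if (all(ed$pcor == 0)) {
    # fully shrunk network (lambda* = 1, e.g. under a global null): no
    # evidence for any edge
    warning("all partial correlations are zero (fully shrunk); ",
            "assigning p = 1 to every edge")
    ed$z <- z
    ed$p <- rep(1, nrow(ed))
    ed$q <- rep(1, nrow(ed))
    return(methods::initialize(et, edges = ed, sigma0 = NA_real_))
  }
  sigma0 <- stats::mad(z, center = 0)  # MAD / 0.6745, centred at the null
  if (sigma0 == 0) stop("null scale sigma0 is zero; cannot calibrate edges")
  ed$z <- z
  ed$p <- 2 * stats::pnorm(abs(z) / sigma0, lower.tail = FALSE)
  ed$q <- stats::p.adjust(ed$p, method = "BH")
  methods::initialize(et, edges = ed, sigma0 = sigma0)
}

#' Extract regulons from a significance-annotated edge table
#'
#' Per TF, targets with q < `qMax` (strict); mode is the sign of the partial
#' correlation and likelihood is 1 - q. TFs with no significant target are
#' retained as empty regulons.
#'
#' @param et an [EdgeTable-class] after [edgeSignificance()].
#' @param qMax FDR cutoff (default 0.05, strict `<`).
#' @return A [RegulonSet-class].
#' @export
extractRegulons <- function(et, qMax = 0.05) {
  stopifnot(is(et, "EdgeTable"))
  ed <- et@edges
  if (all(is.na(ed$q))) stop("run edgeSignificance() first")
  sel <- ed$q < qMax
  tb <- data.frame(
    tf = ed$tf[sel], target = ed$target[sel],
    mode = sign(ed$pcor[sel]),
    likelihood = 1 - ed$q[sel],
    stringsAsFactors = FALSE
  )
  # a q of exactly 0 would give likelihood 1 (allowed); guard mode 0
  tb <- tb[tb$mode != 0, , drop = FALSE]
  rownames(tb) <- NULL
  methods::new("RegulonSet", table = tb, tfIds = unique(ed$tf),
               params = list(qMax = qMax, cohort = et@cohort))
}
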