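#' Kaplan-Meier curves and log-rank comparison of subtypes
#'
#' Product-limit survival estimate per subtype and the k-group log-rank
#' statistic referred to a chi-square with k - 1 degrees of freedom.
#'
#' @param clinical data.frame with columns `sample`, `time` (> 0), `event`
#'   (0/1).
#' @param subtypes data.frame with columns `sample`, `subtype` (from
#'   [clusterSubtypes()]) or a named vector.
#' @return list with `km` (data.frame `subtype`, `time`, `surv`, `n_risk`,
#'   `n_event`), `chisq`, `df`, `p`.
#' @export
compareSurvival <- function(clinical, subtypes) {
  df <- .joinSubtypes(clinical, subtypes)
  if (any(df$time <= 0)) stop("survival times must be positive")
  if (!all(df$event %in% c(0, 1))) stop("events must be 0/1")
  if (any(table(df$subtype) == 0)) stop("every subtype needs >= 1 sample")
  df$subtype <- factor(df$subtype)
  fit <- survival::survfit(survival::Surv(time, event) ~ subtype, data = df)
  st <- summary(fit)
  strata <- if (is.null(st$strata)) factor(rep(levels(df$subtype)[1],
                                               length(st$time)))
            else sub("^subtype=", "", st$strata)
  km <- data.frame(subtype = as.character(strata), time = st$time,
                   surv = st$surv, n_risk = st$n.risk, n_event = st$n.event,
                   stringsAsFactors = FALSE)
  k <- nlevels(df$subtype)
  if (k >= 2) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ subtype, data = df)
    chisq <- unname(sd$chisq)
    p <- stats::pchisq(chisq, df = k - 1, lower.tail = FALSE)
  } else {
    chisq <- NA_real_; p <- NA_real_
  }
  list(km = km, chisq = chisq, df = k - 1, p = p)
}

#' Cox proportional-hazards comparison of subtypes
#'
#' Multivariate Cox model of subtype against survival with Efron handling of
#' ties, adjusted for the requested covariates. Hazard ratios are reported
#' per subtype level against the reference subtype, with Wald 95\% CIs and
#' p-values.
#'
#' @param clinical data.frame with `sample`, `time`, `event` and any
#'   covariate columns.
#' @param subtypes subtype assignment (see [compareSurvival()]).
#' @param covariates character vector of covariate column names (default
#'   `age`, `gender`, `stage`).
#' @param ref reference subtype level (default: first level).
#' @param interaction optional name of a binary treatment column to interact
#'   with subtype (`NULL` to omit).
#' @return list with `table` (data.frame `subtype`, `hr`, `ci_lower`,
#'   `ci_upper`, `p`) and `fit` (the coxph object).
#' @export
coxPH <- function(clinical, subtypes, covariates = c("age", "gender", "stage"),
                  ref = NULL, interaction = NULL) {
  df <- .joinSubtypes(clinical, subtypes)
  covariates <- covariates[covariates %in% names(df)]
  for (cv in covariates)
    if (length(unique(df[[cv]])) < 2)
      stop("covariate with zero variance: ", cv)
  df$subtype <- factor(df$subtype)
  if (!is.null(ref)) df$subtype <- stats::relevel(df$subtype, ref = as.character(ref))
  terms <- c("subtype", covariates)
  if (!is.null(interaction)) terms <- c(terms, paste0("subtype:", interaction))
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(terms, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "efron",
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w)))
        stop("Cox fit failed: ", conditionMessage(w))
      suppressWarnings(survival::coxph(fml, data = df, ties = "efron"))
    }
  )
  sm <- summary(fit)
  rows <- grepl("^subtype", rownames(sm$coefficients)) &
    !grepl(":", rownames(sm$coefficients))
  co <- sm$coefficients[rows, , drop = FALSE]
  ci <- sm$conf.int[rows, , drop = FALSE]
  tab <- data.frame(
    subtype = sub("^subtype", "", rownames(co)),
    hr = unname(co[, "exp(coef)"]),
    ci_lower = unname(ci[, "lower .95"]),
    ci_upper = unname(ci[, "upper .95"]),
    p = unname(co[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(table = tab, fit = fit)
}

.joinSubtypes <- function(clinical, subtypes) {
  stopifnot(is.data.frame(clinical), "sample" %in% names(clinical))
  if (is.data.frame(subtypes)) {
    stopifnot(all(c("sample", "subtype") %in% names(subtypes)))
    idx <- match(clinical$sample, subtypes$sample)
  } else {
    idx <- match(clinical$sample, names(subtypes))
    subtypes <- data.frame(sample = names(subtypes),
                           subtype = as.vector(subtypes))
  }
  if (anyNA(idx)) stop("subtype assignment missing for some samples")
  cbind(clinical, subtype = subtypes$subtype[idx])
}

#' Mutational burden by subtype over a gene panel
#'
#' A sample counts as altered for a panel gene when any of its records has a
#' HIGH or MODERATE impact SNV, a copy loss (`copy_number <= -1`) or an
#' amplification to more than five copies (`copy_number > 5`). Reported are
#' the per-subtype per-gene altered-sample fractions, the per-subtype mean
#' fraction, and a one-way ANOVA of the per-gene fractions across subtypes
#' (the panel genes are the unit of replication).
#'
#' @param mutations data.frame `sample`, `gene`, `impact`, `copy_number`.
#' @param subtypes subtype assignment covering all mutation samples.
#' @param panel nonempty character vector of panel genes.
#' @return list with `fractions` (gene-by-subtype matrix), `subtypeMeans`,
#'   `anovaF`, `anovaP`.
#' @export
mutationBurden <- function(mutations, subtypes, panel) {
  if (length(panel) == 0) stop("panel must be nonempty")
  stopifnot(all(c("sample", "gene", "impact", "copy_number") %in%
                  names(mutations)))
  known <- c("HIGH", "MODERATE", "LOW", "NONE")
  bad <- setdiff(unique(mutations$impact), known)
  if (length(bad))
    stop("unknown impact class(es): ", paste(bad, collapse = ", "),
         " (seen classes: ", paste(unique(mutations$impact), collapse = ", "), ")")
  if (is.data.frame(subtypes)) {
    st <- stats::setNames(subtypes$subtype, subtypes$sample)
  } else st <- subtypes
  samples <- names(st)
  mutations <- mutations[mutations$gene %in% panel &
                           mutations$sample %in% samples, , drop = FALSE]
  altered <- mutations$impact %in% c("HIGH", "MODERATE") |
    mutations$copy_number <= -1 | mutations$copy_number > 5
  mutations <- mutations[altered, , drop = FALSE]
  hitKey <- unique(paste(mutations$sample, mutations$gene, sep = "\r"))

  levs <- sort(unique(st))
  frac <- matrix(0, length(panel), length(levs),
                 dimnames = list(panel, as.character(levs)))
  nBy <- table(factor(st, levels = levs))
  if (length(hitKey)) {
    parts <- strsplit(hitKey, "\r", fixed = TRUE)
    hs <- vapply(parts, `[[`, character(1), 1L)
    hg <- vapply(parts, `[[`, character(1), 2L)
    tab <- table(factor(hg, levels = panel),
                 factor(st[hs], levels = levs))
    frac <- sweep(tab, 2, as.numeric(nBy), "/")
    frac <- matrix(as.numeric(frac), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  }
  long <- data.frame(
    fraction = as.vector(frac),
    subtype = factor(rep(colnames(frac), each = nrow(frac))),
    stringsAsFactors = FALSE
  )
  if (nlevels(long$subtype) >= 2) {
    av <- stats::anova(stats::aov(fraction ~ subtype, data = long))
    fstat <- av[["F value"]][1]
    pval <- av[["Pr(>F)"]][1]
  } else {
    fstat <- NA_real_; pval <- NA_real_
  }
  list(fractions = frac, subtypeMeans = colMeans(frac),
       anovaF = fstat, anovaP = pval)
}

#' Single-sample gene-set enrichment (ssGSEA)
#'
#' Per sample, genes are ranked by expression (descending, average ties);
#' walking down that list the score accumulates the difference between the
#' weighted in-set empirical CDF (weights |rank score|^alpha) and the
#' unweighted out-of-set CDF, summed over all positions. Scores depend only
#' on within-sample ranks, so they are invariant to monotone transforms of
#' a sample's expression.
#'
#' @param expr gene-by-sample matrix.
#' @param sets named list of character vectors; sets with no gene in the
#'   matrix are skipped with a message.
#' @param alpha rank-weight exponent (default 0.25).
#' @param normalize if `TRUE`, divide all scores by the overall max - min
#'   spread (cohort-wide normalization).
#' @return gene-set by sample matrix of enrichment scores.
#' @export
ssgsea <- function(expr, sets, alpha = 0.25, normalize = FALSE) {
  expr <- as.matrix(expr)
  if (length(sets) == 0) stop("gene-set collection is empty")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  genes <- rownames(expr)
  N <- length(genes)
  inSet <- lapply(sets, function(s) genes %in% s)
  m <- vapply(inSet, sum, integer(1))
  if (any(m >= N))
    stop("gene set covering all genes: ",
         paste(names(sets)[m >= N], collapse = ", "))
  usable <- m >= 1
  if (any(!usable))
    message("skipping ", sum(!usable), " set(s) with no gene in the matrix")
  sets <- sets[usable]; inSet <- inSet[usable]; m <- m[usable]
  if (length(sets) == 0) stop("no usable gene set")

  scores <- matrix(NA_real_, length(sets), ncol(expr),
                   dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    rk <- rank(x, ties.method = "average")     # high expression = high rank
    ordIdx <- order(x, decreasing = TRUE)
    w <- abs(rk[ordIdx])^alpha
    for (i in seq_along(sets)) {
      ins <- inSet[[i]][ordIdx]
      wIn <- w * ins
      pin <- cumsum(wIn) / sum(wIn)
      pout <- cumsum(!ins) / (N - m[i])
      scores[i, j] <- sum(pin - pout)
    }
  }
  if (normalize) {
    spread <- max(scores) - min(scores)
    if (spread > 0) scores <- scores / spread
  }
  scores
}

#' Stromal and immune admixture scores with subtype comparisons
#'
#' ssGSEA scores of the stromal and immune marker sets per sample, plus
#' pairwise two-sided Wilcoxon rank-sum comparisons of each score across
#' subtypes (normal approximation with tie correction).
#'
#' @param expr gene-by-sample matrix.
#' @param stromalSet,immuneSet character vectors of marker genes.
#' @param subtypes optional subtype assignment; when given, pairwise tests
#'   are run.
#' @param alpha ssGSEA exponent passed through.
#' @return list with `scores` (2 x samples matrix, rows stromal/immune) and
#'   `tests` (data.frame `score`, `subtype1`, `subtype2`, `p`; `NULL`
#'   without subtypes).
#' @export
admixtureScores <- function(expr, stromalSet, immuneSet, subtypes = NULL,
                            alpha = 0.25) {
  genes <- rownames(expr)
  if (!length(intersect(stromalSet, genes)) ||
      !length(intersect(immuneSet, genes)))
    stop("stromal and immune sets must be present in the expression universe")
  scores <- ssgsea(expr, list(stromal = stromalSet, immune = immuneSet),
                   alpha = alpha)
  tests <- NULL
  if (!is.null(subtypes)) {
    if (is.data.frame(subtypes))
      subtypes <- stats::setNames(subtypes$subtype, subtypes$sample)
    st <- subtypes[colnames(expr)]
    levs <- sort(unique(st))
    rows <- list()
    for (sc in rownames(scores)) {
      for (i in seq_len(length(levs) - 1)) for (j in seq(i + 1, length(levs))) {
        pv <- stats::wilcox.test(scores[sc, st == levs[i]],
                                 scores[sc, st == levs[j]],
                                 exact = FALSE)$p.value
        rows[[length(rows) + 1L]] <- data.frame(
          score = sc, subtype1 = levs[i], subtype2 = levs[j], p = pv,
          stringsAsFactors = FALSE)
      }
    }
    tests <- do.call(rbind, rows)
  }
  list(scores = scores, tests = tests)
}

#' Signature-matrix deconvolution by non-negative least squares
#'
#' Per sample, cell-type fractions are the non-negative least-squares
#' coefficients of the sample on the signature matrix, renormalized to the
#' simplex. Goodness of fit is the Pearson correlation R between fitted
#' mixture and observed expression over the signature genes; significance
#' is a gene-label permutation test: p = (1 + #\{R_perm >= R\}) /
#' (nPerm + 1).
#'
#' @param expr gene-by-sample matrix.
#' @param signatureMatrix gene-by-cell-type reference matrix (full column
#'   rank on the shared genes; >= 50 shared genes required).
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @return data.frame with one row per sample: the cell-type fractions,
#'   `R` and `p`.
#' @export
deconvolve <- function(expr, signatureMatrix, nPerm = 1000, seed = 1) {
  expr <- as.matrix(expr)
  S <- as.matrix(signatureMatrix)
  shared <- intersect(rownames(expr), rownames(S))
  if (length(shared) < 50) stop("fewer than 50 shared genes with the signature matrix")
  S <- S[shared, , drop = FALSE]
  if (qr(S)$rank < ncol(S))
    stop("signature matrix is rank deficient on the shared genes")
  nPerm <- .checkCount(nPerm, "nPerm")
  set.seed(seed)
  nG <- length(shared)
  permIdx <- replicate(nPerm, sample.int(nG))

  fitOne <- function(y) {
    b <- pracma::lsqnonneg(S, y)$x
    fitted <- as.vector(S %*% b)
    r <- if (stats::sd(fitted) == 0) 0 else stats::cor(fitted, y)
    list(b = b, r = r)
  }
  out <- lapply(colnames(expr), function(sm) {
    y <- expr[shared, sm]
    obs <- fitOne(y)
    rPerm <- vapply(seq_len(nPerm), function(b)
      fitOne(y[permIdx[, b]])$r, numeric(1))
    p <- (1 + sum(rPerm >= obs$r)) / (nPerm + 1)
    fr <- if (sum(obs$b) > 0) obs$b / sum(obs$b) else
      rep(1 / ncol(S), ncol(S))
    c(fr, R = obs$r, p = p)
  })
  res <- as.data.frame(do.call(rbind, out))
  names(res) <- c(colnames(S), "R", "p")
  res <- cbind(sample = colnames(expr), res)
  rownames(res) <- NULL
  res
}

#' First-order partial correlation with Bonferroni-by-multiplication
#'
#' r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)); the test
#' statistic is t = r sqrt((n - 3) / (1 - r^2)) with n - 3 degrees of
#' freedom. The family-wise correction multiplies the p-value by `nTests`,
#' capped at 1.
#'
#' @param x,y,z numeric vectors of equal length n >= 4.
#' @param nTests number of tests in the family (default 1).
#' @return list with `estimate`, `statistic`, `df`, `p`, `pAdjusted`.
#' @export
firstOrderPartialCorrelation <- function(x, y, z, nTests = 1) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("x, y, z must have equal length")
  if (n < 4) stop("need n >= 4")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("degenerate conditioning: |cor with z| = 1")
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- min(1, max(-1, r))
  tt <- r * sqrt((n - 3) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 3)
  list(estimate = r, statistic = tt, df = n - 3, p = p,
       pAdjusted = min(1, p * nTests))
}

#' Hypergeometric overlap between two sample labelings
#'
#' For each label pair (a, b), the upper-tail hypergeometric probability of
#' the observed overlap given the shared sample universe: population n,
#' successes |a|, draws |b|.
#'
#' @param labelsA,labelsB named vectors (or factors) over the same samples.
#' @return matrix of p-values, labels of A by labels of B.
#' @export
overlapEnrichment <- function(labelsA, labelsB) {
  if (!is.null(names(labelsA)) && !is.null(names(labelsB))) {
    if (!setequal(names(labelsA), names(labelsB)))
      stop("labelings must cover the same sample universe")
    labelsB <- labelsB[names(labelsA)]
  } else if (length(labelsA) != length(labelsB)) {
    stop("labelings must cover the same sample universe")
  }
  a <- as.character(labelsA); b <- as.character(labelsB)
  N <- length(a)
  la <- sort(unique(a)); lb <- sort(unique(b))
  out <- matrix(NA_real_, length(la), length(lb), dimnames = list(la, lb))
  for (i in seq_along(la)) for (j in seq_along(lb)) {
    K <- sum(a == la[i]); nb <- sum(b == lb[j])
    k <- sum(a == la[i] & b == lb[j])
    out[i, j] <- stats::phyper(k - 1, K, N - K, nb, lower.tail = FALSE)
  }
  out
}
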