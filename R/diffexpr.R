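## Differential expression: low-count filter, log-CPM, covariate
## residualisation, vectorised Welch test, BH correction, thresholding.

#' Remove low-count genes
#'
#' Drops genes whose mean count across all samples is at or below
#' `threshold` (inclusive, so a gene with mean exactly 5 is removed under
#' the default). The alternative reading of the filter — total count per
#' gene at or below the threshold — is available via `stat = "sum"`.
#'
#' @param x count matrix or [StressCountSet-class].
#' @param threshold non-negative cutoff (default 5).
#' @param stat `"mean"` (default) or `"sum"`.
#' @return The input with low-count genes removed; warns if nothing
#'   survives.
#' @examples
#' m <- rbind(lo = c(0, 0, 0, 0), mid = c(5, 5, 5, 5), hi = c(6, 6, 6, 6))
#' rownames(filterLowCounts(m))
#' @export
filterLowCounts <- function(x, threshold = 5, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  assert_scalar_number(threshold, "threshold", lower = 0)
  cnt <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else x
  v <- if (stat == "mean") rowMeans(cnt) else rowSums(cnt)
  keep <- v > threshold
  if (!any(keep)) warning("no genes pass the low-count filter")
  x[keep, , drop = FALSE]
}

#' log2 counts-per-million normalisation
#'
#' `log2(1e6 * count / libsize + pseudocount)` with library sizes computed
#' as column sums of the (already filtered) matrix.
#'
#' @param x count matrix or [StressCountSet-class].
#' @param pseudocount added inside the log (default 1, so a zero count maps
#'   to 0).
#' @return A numeric matrix of the same shape.
#' @examples
#' m <- rbind(g1 = c(100, 0), g2 = c(1e6 - 100, 1e6))
#' normalizeLogCPM(m)["g1", ]  # log2(101) and 0
#' @export
normalizeLogCPM <- function(x, pseudocount = 1) {
  cnt <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else x
  libsize <- colSums(cnt)
  if (any(libsize == 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(cnt)[libsize == 0], collapse = ", "))
  }
  log2(sweep(cnt, 2, libsize, "/") * 1e6 + pseudocount)
}

#' Residualise expression on nuisance covariates
#'
#' Replaces each gene's profile by the residuals of an ordinary
#' least-squares fit on an intercept plus the supplied covariates. The
#' group label must NOT be part of `covariates`: the contrast of interest
#' is tested afterwards on the residuals.
#'
#' @param X genes-by-samples numeric matrix.
#' @param covariates data.frame of per-sample covariates (numeric or
#'   factor), rows aligned with `colnames(X)`; `NULL` or zero columns
#'   returns `X` unchanged.
#' @return Matrix of residuals (same dimnames as `X`).
#' @examples
#' X <- matrix(rnorm(40), 4, 10)
#' age <- rnorm(10)
#' Xa <- covariateAdjust(X, data.frame(age = age))
#' max(abs(cor(t(Xa), age)))  # ~0 by OLS orthogonality
#' @export
covariateAdjust <- function(X, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0L) return(X)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != ncol(X)) {
    stop("covariates must have one row per sample")
  }
  mm <- model.matrix(~ ., data = covariates)
  qx <- qr(mm)
  if (qx$rank < ncol(mm)) {
    bad <- colnames(mm)[qx$pivot[(qx$rank + 1L):ncol(mm)]]
    stop("covariate design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  res <- t(qr.resid(qx, t(X)))
  dimnames(res) <- dimnames(X)
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR correction with monotonicity enforcement, delegated to
#' [stats::p.adjust()] behind a validating wrapper.
#'
#' @param p numeric vector of p-values in `[0, 1]` (no NAs).
#' @return q-values in `[0, 1]`, same order as `p`.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no NAs")
  }
  p.adjust(p, method = "BH")
}

#' Per-gene Welch test on adjusted log-CPM values
#'
#' Desk-scale stand-in for a count-model differential-expression fit: a
#' two-sided Welch two-sample t-test per gene on (covariate-adjusted)
#' log2-CPM values, with `log2FC = mean(case) - mean(control)` and BH
#' q-values. Externally computed tables (e.g. from DESeq2 on real data)
#' can be substituted anywhere downstream via [readDETable()].
#'
#' Degenerate zero-variance genes: if the group means differ, p is set to
#' the smallest representable double (with one warning per call);
#' identical constant groups get p = 1.
#'
#' @param X genes-by-samples matrix of adjusted log2-CPM values.
#' @param groups factor/character per sample with two levels including
#'   `"control"`; the other level is the case.
#' @param mode threshold rule used to fill the `direction` column; see
#'   [selectSignificant()].
#' @param alpha significance threshold for `direction` (default 0.05).
#' @return A DETable: data.frame with `gene`, `log2FC`, `p`, `q`,
#'   `direction` (`"up"`, `"down"` or `"ns"`).
#' @examples
#' X <- rbind(null = rnorm(8), up = c(rnorm(4), rnorm(4) + 3))
#' g <- rep(c("control", "stress"), each = 4)
#' deTest(X, g)
#' @export
deTest <- function(X, groups, mode = c("q_threshold", "p_threshold"),
                   alpha = 0.05) {
  mode <- match.arg(mode)
  groups <- as.character(groups)
  if (!"control" %in% groups || length(unique(groups)) != 2L) {
    stop("groups must have two levels including 'control'")
  }
  ctl <- groups == "control"
  if (sum(ctl) < 2L || sum(!ctl) < 2L) {
    stop("each group needs at least 2 samples")
  }
  X <- as.matrix(X)
  n1 <- sum(!ctl); n0 <- sum(ctl)
  m1 <- rowMeans(X[, !ctl, drop = FALSE])
  m0 <- rowMeans(X[, ctl, drop = FALSE])
  v1 <- rowSums((X[, !ctl, drop = FALSE] - m1)^2) / (n1 - 1)
  v0 <- rowSums((X[, ctl, drop = FALSE] - m0)^2) / (n0 - 1)
  lfc <- m1 - m0

  se2 <- v1 / n1 + v0 / n0
  tstat <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * pt(-abs(tstat), df)

  degen <- se2 == 0
  if (any(degen)) {
    p[degen & lfc != 0] <- .Machine$double.xmin
    p[degen & lfc == 0] <- 1
    warning(sum(degen), " zero-variance gene(s); p set to 1 or the ",
            "smallest representable double")
  }
  q <- bhAdjust(p)
  crit <- if (mode == "q_threshold") q else p
  direction <- ifelse(crit < alpha & lfc > 0, "up",
                      ifelse(crit < alpha & lfc < 0, "down", "ns"))
  data.frame(gene = rownames(X) %||% as.character(seq_len(nrow(X))),
             log2FC = unname(lfc), p = unname(p), q = unname(q),
             direction = unname(direction), stringsAsFactors = FALSE)
}

#' Select significant up/down gene sets from a DETable
#'
#' `p_threshold` mode uses raw `p < alpha` (the rule applied to MDD-style
#' contrasts); `q_threshold` uses BH `q < alpha` (the rule for chronic
#' stress contrasts). Genes with `log2FC == 0` belong to neither set.
#'
#' @param de DETable from [deTest()] or [readDETable()].
#' @param mode `"p_threshold"` or `"q_threshold"`.
#' @param alpha threshold (default 0.05).
#' @return List with character vectors `up` and `down`.
#' @examples
#' de <- data.frame(gene = c("a", "b"), log2FC = c(1, -1),
#'                  p = c(0.049, 0.2), q = c(0.2, 0.9))
#' selectSignificant(de, "p_threshold")
#' @export
selectSignificant <- function(de, mode = c("q_threshold", "p_threshold"),
                              alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(all(c("gene", "log2FC", "p", "q") %in% colnames(de)))
  crit <- if (mode == "q_threshold") de$q else de$p
  sel <- crit < alpha & de$log2FC != 0
  list(up = de$gene[sel & de$log2FC > 0],
       down = de$gene[sel & de$log2FC < 0])
}

#' One-call differential expression on a StressCountSet
#'
#' Convenience chain: [filterLowCounts()] -> [normalizeLogCPM()] ->
#' [covariateAdjust()] -> [deTest()].
#'
#' @param se a [StressCountSet-class].
#' @param covariates character vector of `colData` columns to residualise
#'   on (ignored if absent), or `NULL`.
#' @param mode,alpha passed to [deTest()].
#' @param filter_threshold passed to [filterLowCounts()].
#' @param pseudocount passed to [normalizeLogCPM()].
#' @return A DETable (see [deTest()]).
#' @export
deAnalysis <- function(se, covariates = NULL,
                       mode = c("q_threshold", "p_threshold"),
                       alpha = 0.05, filter_threshold = 5,
                       pseudocount = 1) {
  mode <- match.arg(mode)
  stopifnot(is(se, "StressCountSet"))
  se <- filterLowCounts(se, threshold = filter_threshold)
  X <- normalizeLogCPM(se, pseudocount = pseudocount)
  cov_df <- NULL
  if (!is.null(covariates)) {
    covariates <- intersect(covariates, colnames(colData(se)))
    if (length(covariates)) {
      cov_df <- as.data.frame(colData(se)[, covariates, drop = FALSE])
    }
  }
  X <- covariateAdjust(X, cov_df)
  deTest(X, colData(se)$group, mode = mode, alpha = alpha)
}
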