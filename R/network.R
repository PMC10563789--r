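## Seeded signed Spearman co-expression networks per condition stratum.

#' Spearman correlation test for one gene pair
#'
#' Tie-corrected (average-rank) Spearman rho with a two-sided p-value from
#' [stats::cor.test()]: exact for small tie-free samples, asymptotic
#' otherwise — matching standard practice of computing both r and P with
#' `cor.test()`.
#'
#' @param x,y numeric vectors, length >= 4, neither constant.
#' @return List with `rho` and `p`.
#' @examples
#' x <- rnorm(20)
#' spearmanTest(x, exp(x))$rho  # rank invariance: exactly 1
#' @export
spearmanTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4L) stop("need at least 4 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

## Vectorised tie-corrected Spearman of each row of X against each row of
## seeds' expression; p from the t approximation (fast path used by the
## network stage; see spearmanTest for the exact small-n route).
spearman_matrix <- function(X, seed_rows) {
  R <- t(apply(X, 1L, rank))
  n <- ncol(X)
  rho <- cor(t(R[seed_rows, , drop = FALSE]), t(R))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  p[abs(rho) >= 1] <- .Machine$double.xmin
  list(rho = rho, p = p)
}

#' Split samples into (species, sex, group) strata
#'
#' @param metadata data.frame with one row per sample and columns among
#'   `species`, `sex`, `group` (missing columns are treated as a single
#'   level); rownames or a `sample_id` column identify samples.
#' @param min_n strata with fewer samples are skipped with a message
#'   (default 4, the minimum for a Spearman test).
#' @return Named list of character vectors of sample ids; the strata are
#'   pairwise disjoint and their union is every sample in an eligible
#'   stratum.
#' @examples
#' md <- data.frame(sample_id = paste0("s", 1:8),
#'                  species = "mouse", sex = rep(c("F", "M"), each = 4),
#'                  group = rep(c("control", "stress"), 4))
#' names(stratifySamples(md))
#' @export
stratifySamples <- function(metadata, min_n = 4L) {
  metadata <- as.data.frame(metadata)
  ids <- metadata$sample_id %||% rownames(metadata)
  keys <- intersect(c("species", "sex", "group"), colnames(metadata))
  if (length(keys) == 0L) stop("metadata has no stratification columns")
  lab <- do.call(paste, c(lapply(keys, function(k) metadata[[k]]),
                          sep = "."))
  out <- split(ids, lab)
  small <- lengths(out) < min_n
  if (any(small)) {
    message("skipping ", sum(small), " stratum/strata with fewer than ",
            min_n, " samples: ", paste(names(out)[small], collapse = ", "))
    out <- out[!small]
  }
  out
}

#' Seeded signed Spearman correlate lists for one stratum
#'
#' Treats each seed gene as a network hub: every other gene in the matrix
#' is tested for Spearman correlation with the seed across the stratum's
#' samples, and genes passing the raw p threshold are split by correlation
#' sign. No multiple-testing correction is applied at this stage (the
#' enrichment downstream is FDR-corrected); the threshold is on raw
#' P < 0.05 by default.
#'
#' @param X genes-by-samples matrix of normalised (optionally
#'   covariate-adjusted) expression, already subset to one stratum.
#' @param seeds character vector of seed genes; seeds absent from the
#'   matrix are reported and skipped, and an error is raised if none
#'   remain.
#' @param stratum label stored in the output (default `""`).
#' @param p_threshold raw p-value cutoff (default 0.05).
#' @return data.frame with columns `stratum`, `seed`, `gene`, `rho`, `p`,
#'   `sign` (`"positive"`/`"negative"`); a seed never lists itself.
#' @examples
#' X <- matrix(rnorm(200), 10, 20,
#'             dimnames = list(paste0("g", 1:10), NULL))
#' X["g2", ] <- X["g1", ]  # duplicate profile
#' sn <- seededCorrelations(X, "g1")
#' sn[sn$gene == "g2", c("rho", "sign")]
#' @export
seededCorrelations <- function(X, seeds, stratum = "",
                               p_threshold = 0.05) {
  X <- as.matrix(X)
  if (ncol(X) < 4L) stop("stratum must contain at least 4 samples")
  absent <- setdiff(seeds, rownames(X))
  if (length(absent)) {
    message("skipping ", length(absent), " seed(s) absent from the ",
            "matrix: ", paste(absent, collapse = ", "))
  }
  seeds <- intersect(seeds, rownames(X))
  if (length(seeds) == 0L) stop("no seed genes present in the matrix")
  ## constant rows have undefined correlations; drop them up front
  keep <- apply(X, 1L, function(r) sd(r) > 0)
  if (!all(keep[seeds])) {
    message("dropping constant seed(s): ",
            paste(seeds[!keep[seeds]], collapse = ", "))
    seeds <- seeds[keep[seeds]]
    if (length(seeds) == 0L) stop("no seed genes present in the matrix")
  }
  X <- X[keep, , drop = FALSE]

  sm <- spearman_matrix(X, seeds)
  out <- do.call(rbind, lapply(seeds, function(s) {
    rho <- sm$rho[s, ]
    p <- sm$p[s, ]
    sel <- names(rho)[p < p_threshold & names(rho) != s]
    if (length(sel) == 0L) return(NULL)
    data.frame(stratum = stratum, seed = s, gene = sel,
               rho = unname(rho[sel]), p = unname(p[sel]),
               sign = ifelse(rho[sel] > 0, "positive", "negative"),
               stringsAsFactors = FALSE)
  }))
  out %||% data.frame(stratum = character(0), seed = character(0),
                      gene = character(0), rho = numeric(0),
                      p = numeric(0), sign = character(0))
}

#' Seeded networks across all condition strata
#'
#' Applies [stratifySamples()] to the metadata and
#' [seededCorrelations()] within each stratum.
#'
#' @param X genes-by-samples matrix (all samples).
#' @param metadata per-sample data.frame (see [stratifySamples()]).
#' @param seeds seed genes.
#' @param p_threshold raw p cutoff (default 0.05).
#' @param min_n minimum stratum size (default 4).
#' @return Long data.frame as in [seededCorrelations()], one block per
#'   stratum.
#' @export
seededNetworks <- function(X, metadata, seeds, p_threshold = 0.05,
                           min_n = 4L) {
  strata <- stratifySamples(metadata, min_n = min_n)
  out <- lapply(names(strata), function(nm) {
    seededCorrelations(X[, strata[[nm]], drop = FALSE], seeds,
                       stratum = nm, p_threshold = p_threshold)
  })
  do.call(rbind, out)
}
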