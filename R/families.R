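## Ortholog harmonisation, pseudogene suffix handling and hypergeometric
## gene-family overlap enrichment.

#' Strip the species pseudogene suffix from a symbol
#'
#' Mouse RP pseudogenes carry a terminal `-ps` plus optional digits
#' (`Rpl7a-ps3`), human ones a terminal `AS` plus optional digits
#' (`RPL36AAS1`). Stripping recovers the parent symbol. Because a genuine
#' human symbol can end in `AS`, stripping can optionally be restricted to
#' symbols listed in `known_pseudogenes`; without such a list the pattern
#' alone decides.
#'
#' @param symbols character vector of gene symbols.
#' @param species `"mouse"` or `"human"`.
#' @param known_pseudogenes optional character vector; when given, only
#'   these symbols are eligible for stripping.
#' @return data.frame with `symbol`, `parent_symbol`, `is_pseudogene`.
#' @examples
#' stripPseudogeneSuffix(c("Rpl7a-ps3", "Rpl13a"), "mouse")
#' stripPseudogeneSuffix(c("RPL36AAS1", "RPL13A"), "human")
#' @export
stripPseudogeneSuffix <- function(symbols, species = c("mouse", "human"),
                                  known_pseudogenes = NULL) {
  species <- match.arg(species)
  if (any(!nzchar(symbols))) stop("empty symbol")
  pat <- if (species == "mouse") "-ps[0-9]*$" else "AS[0-9]*$"
  hit <- grepl(pat, symbols)
  if (!is.null(known_pseudogenes)) hit <- hit & symbols %in% known_pseudogenes
  parent <- ifelse(hit, sub(pat, "", symbols), symbols)
  data.frame(symbol = symbols, parent_symbol = parent, is_pseudogene = hit,
             stringsAsFactors = FALSE)
}

## validate a 1:1 ortholog map; returns it with character columns
validate_ortholog_map <- function(map) {
  if (is.null(map) || nrow(map) == 0L) {
    return(data.frame(mouse_symbol = character(0),
                      human_symbol = character(0)))
  }
  stopifnot(all(c("mouse_symbol", "human_symbol") %in% colnames(map)))
  dup_m <- unique(map$mouse_symbol[duplicated(map$mouse_symbol)])
  dup_h <- unique(map$human_symbol[duplicated(map$human_symbol)])
  if (length(dup_m) || length(dup_h)) {
    stop("ortholog map must be 1:1; offending symbols: ",
         paste(c(dup_m, dup_h), collapse = ", "))
  }
  map
}

#' Harmonise gene symbols between mouse and human
#'
#' An explicit 1:1 ortholog map takes precedence; remaining symbols are
#' mapped by the case convention (mouse title-case to human upper-case and
#' back). If a target `universe` is supplied, mapped symbols absent from it
#' are dropped with a message reporting the count.
#'
#' @param symbols character vector in the source species' namespace.
#' @param from source species, `"mouse"` or `"human"`.
#' @param map optional data.frame with columns `mouse_symbol`,
#'   `human_symbol`; many-to-many rows are rejected.
#' @param universe optional character vector of valid target symbols.
#' @return Character vector of harmonised symbols (unnamed, order of
#'   input, dropped symbols removed).
#' @examples
#' harmonizeSymbols(c("Rps29", "Rpl9"), from = "mouse")
#' @export
harmonizeSymbols <- function(symbols, from = c("mouse", "human"),
                             map = NULL, universe = NULL) {
  from <- match.arg(from)
  map <- validate_ortholog_map(map)
  src <- if (from == "mouse") map$mouse_symbol else map$human_symbol
  dst <- if (from == "mouse") map$human_symbol else map$mouse_symbol
  i <- match(symbols, src)
  out <- dst[i]
  miss <- is.na(i)
  if (any(miss)) {
    out[miss] <- if (from == "mouse") {
      toupper(symbols[miss])
    } else {
      paste0(toupper(substr(symbols[miss], 1, 1)),
             tolower(substr(symbols[miss], 2, nchar(symbols[miss]))))
    }
  }
  if (!is.null(universe)) {
    drop <- !(out %in% universe)
    if (any(drop)) {
      message(sum(drop), " symbol(s) not mappable into the target ",
              "universe; dropped")
      out <- out[!drop]
    }
  }
  unname(out)
}

#' Hypergeometric overlap test between a DE set and a gene family
#'
#' Upper-tail probability of observing at least `k` family members in a DE
#' set of size `n` drawn from a universe of `N` genes containing `K`
#' family members — equivalently the one-sided Fisher exact test on the
#' 2x2 table. The default universe size (21,196) is the genomic background
#' used by GeneOverlap-style enrichment; synthetic runs override it with
#' the simulated universe size.
#'
#' @param de_set character vector of DE genes (or an integer count if
#'   `overlap` is supplied).
#' @param family character vector of family member symbols.
#' @param universe_size total genes in the background (default 21196).
#' @param universe optional character vector; when supplied, both sets are
#'   intersected with it and `universe_size` is its length.
#' @return One-row data.frame: `k`, `K`, `n`, `N`, `p`, `odds_ratio`
#'   (sample OR; `Inf` when the complement cell is empty).
#' @examples
#' familyOverlapTest(letters[1:5], letters[1:5], universe_size = 10)$p
#' # = 1 / choose(10, 5)
#' @export
familyOverlapTest <- function(de_set, family, universe_size = 21196,
                              universe = NULL) {
  if (!is.null(universe)) {
    de_set <- intersect(de_set, universe)
    family <- intersect(family, universe)
    universe_size <- length(universe)
  }
  de_set <- unique(de_set)
  family <- unique(family)
  k <- length(intersect(de_set, family))
  K <- length(family)
  n <- length(de_set)
  N <- universe_size
  N <- as.integer(N)
  if (N < max(K, n)) stop("universe smaller than a tested set")
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  odds <- (k * (N - K - n + k)) / ((K - k) * (n - k))
  data.frame(k = k, K = K, n = n, N = N, p = p, odds_ratio = odds)
}

#' Family enrichment across many families for one DE direction
#'
#' Runs [familyOverlapTest()] for every family and BH-adjusts across the
#' families tested in the same call.
#'
#' @param de_set character vector of DE genes for one (contrast,
#'   direction).
#' @param families named list of family member vectors.
#' @param universe_size,universe see [familyOverlapTest()].
#' @return data.frame with one row per family: `family`, `k`, `K`, `n`,
#'   `N`, `p`, `odds_ratio`, `q`.
#' @export
familyEnrichment <- function(de_set, families, universe_size = 21196,
                             universe = NULL) {
  stopifnot(length(families) > 0, !is.null(names(families)))
  rows <- do.call(rbind, lapply(families, function(fam) {
    familyOverlapTest(de_set, fam, universe_size, universe)
  }))
  rows <- cbind(family = names(families), rows)
  rownames(rows) <- NULL
  rows$q <- bhAdjust(rows$p)
  rows
}

#' Matrix of -log10(q) enrichment scores across contrasts and families
#'
#' Rows are (contrast, direction) pairs, columns families; entries are
#' `-log10(q)` capped at `cap` for display (a q of exactly 0 is capped
#' with a warning). Entries are monotone decreasing in q.
#'
#' @param enrichments named list of [familyEnrichment()] tables, one per
#'   (contrast, direction); names become row names.
#' @param cap display cap for `-log10(q)` (default 10).
#' @return Numeric matrix.
#' @export
enrichmentScoreMatrix <- function(enrichments, cap = 10) {
  stopifnot(length(enrichments) > 0, !is.null(names(enrichments)))
  fams <- unique(unlist(lapply(enrichments, `[[`, "family")))
  mat <- matrix(0, nrow = length(enrichments), ncol = length(fams),
                dimnames = list(names(enrichments), fams))
  warned <- FALSE
  for (nm in names(enrichments)) {
    e <- enrichments[[nm]]
    if (any(e$q == 0) && !warned) {
      warning("q-value of 0 capped at ", cap)
      warned <- TRUE
    }
    mat[nm, e$family] <- pmin(-log10(pmax(e$q, 10^(-cap))), cap)
  }
  mat
}

#' Cross-species intersection of significant gene sets
#'
#' Harmonises the mouse set into the human namespace (explicit map first,
#' case convention otherwise) and intersects it with the human set. Output
#' order follows the mouse set.
#'
#' @param set_mouse,set_human character vectors of significant genes.
#' @param map optional ortholog map (see [harmonizeSymbols()]).
#' @return Character vector of common genes in the human namespace.
#' @examples
#' crossSpeciesCommon(c("Rps29", "Rpl9"), c("RPL9", "RPS5"))
#' @export
crossSpeciesCommon <- function(set_mouse, set_human, map = NULL) {
  harmonised <- harmonizeSymbols(set_mouse, from = "mouse", map = map)
  harmonised[harmonised %in% set_human]
}
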