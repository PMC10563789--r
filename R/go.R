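## GO DAG construction, ancestor closure, over-representation, theme
## assignment and pathway-set overlap.

#' Construct a GODag from term, edge and annotation tables
#'
#' Computes the transitive ancestor closure (failing on cyclic edge sets)
#' and propagates annotations upwards: a gene annotated to a term is
#' annotated to all of its ancestors.
#'
#' @param terms data.frame with columns `id`, `name` and optionally
#'   `namespace`.
#' @param parents named list mapping a term id to its `is_a` parent ids.
#' @param annotations data.frame with columns `gene`, `term` (direct
#'   annotations), or `NULL`.
#' @return A [GODag-class].
#' @examples
#' terms <- data.frame(id = c("T1", "T2"), name = c("child", "root"))
#' dag <- goDag(terms, list(T1 = "T2"),
#'              data.frame(gene = "g1", term = "T1"))
#' goAncestors(dag, "T1")
#' @export
goDag <- function(terms, parents = list(), annotations = NULL) {
  terms <- as.data.frame(terms)
  if (!"namespace" %in% colnames(terms)) terms$namespace <- "unspecified"
  ids <- terms$id
  parents <- parents[intersect(names(parents), ids)]
  if (!all(unlist(parents) %in% ids)) {
    stop("is_a edges reference unknown terms: ",
         paste(setdiff(unlist(parents), ids), collapse = ", "))
  }

  ## Kahn topological sort; detects cycles.
  full_parents <- setNames(vector("list", length(ids)), ids)
  full_parents[names(parents)] <- parents
  indeg <- lengths(full_parents)
  children <- split(
    rep(names(full_parents), lengths(full_parents)),
    unlist(full_parents)
  )
  order <- character(0)
  queue <- ids[indeg == 0]
  indeg <- setNames(as.integer(indeg), ids)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]] %||% character(0)) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) != length(ids)) {
    stop("cyclic is_a edges: the term graph is not a DAG")
  }

  ## ancestors in topological order (parents are earlier in `order`)
  ancestors <- setNames(vector("list", length(ids)), ids)
  for (v in order) {
    ps <- full_parents[[v]] %||% character(0)
    ancestors[[v]] <- unique(c(ps, unlist(ancestors[ps])))
  }

  ann_list <- list()
  term2genes <- setNames(vector("list", length(ids)), ids)
  if (!is.null(annotations) && nrow(annotations)) {
    stopifnot(all(c("gene", "term") %in% colnames(annotations)))
    if (!all(annotations$term %in% ids)) {
      stop("annotations reference unknown terms: ",
           paste(setdiff(annotations$term, ids), collapse = ", "))
    }
    ann_list <- lapply(split(annotations$term, annotations$gene), unique)
    closure <- lapply(ann_list, function(tt) {
      unique(c(tt, unlist(ancestors[tt])))
    })
    long <- data.frame(
      gene = rep(names(closure), lengths(closure)),
      term = unlist(closure, use.names = FALSE)
    )
    t2g <- lapply(split(long$gene, long$term), unique)
    term2genes[names(t2g)] <- t2g
  }

  new("GODag", terms = terms, parents = full_parents,
      ancestors = ancestors, annotations = ann_list,
      term2genes = term2genes)
}

#' Ancestors of a GO term
#'
#' Transitive closure over `is_a` edges, excluding the term itself. The
#' root has an empty ancestor set.
#'
#' @param dag a [GODag-class].
#' @param term term id.
#' @return Character vector of ancestor ids.
#' @export
goAncestors <- function(dag, term) {
  stopifnot(is(dag, "GODag"))
  if (!term %in% dag@terms$id) stop("unknown term: ", term)
  dag@ancestors[[term]]
}

#' GO over-representation analysis with ancestor propagation
#'
#' Hypergeometric upper-tail test (the same machinery as
#' [familyOverlapTest()]) of the gene list against every term with at
#' least one list gene after annotation propagation, BH-corrected across
#' the tested terms. By default only rows with `q < q_threshold` are
#' retained, the FDR rule applied to pathway lists.
#'
#' @param genes character vector of query genes.
#' @param dag a [GODag-class] carrying annotations.
#' @param universe background gene set; defaults to every annotated gene.
#' @param q_threshold retention cutoff (default 0.05); `NULL` keeps all
#'   tested terms.
#' @return data.frame with `term`, `name`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   ordered by p. Empty (with a warning) for an empty gene list.
#' @export
goEnrichment <- function(genes, dag, universe = NULL, q_threshold = 0.05) {
  stopifnot(is(dag, "GODag"))
  universe <- universe %||% annotatedGenes(dag)
  genes <- intersect(unique(genes), universe)
  empty <- data.frame(term = character(0), name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), q = numeric(0))
  if (length(genes) == 0L) {
    warning("empty gene list after restriction to the universe")
    return(empty)
  }
  t2g <- lapply(dag@term2genes, intersect, universe)
  k <- vapply(t2g, function(g) length(intersect(g, genes)), integer(1))
  tested <- names(t2g)[k > 0 & lengths(t2g) > 0]
  if (length(tested) == 0L) return(empty)
  rows <- do.call(rbind, lapply(tested, function(tid) {
    familyOverlapTest(genes, t2g[[tid]], universe_size = length(universe))
  }))
  rows <- cbind(
    term = tested,
    name = dag@terms$name[match(tested, dag@terms$id)],
    rows[, c("k", "K", "n", "N", "p")]
  )
  rows$q <- bhAdjust(rows$p)
  rows <- rows[order(rows$p, rows$term), ]
  rownames(rows) <- NULL
  if (!is.null(q_threshold)) rows <- rows[rows$q < q_threshold, ]
  rows
}

#' Assign biological themes to a GO term
#'
#' A theme matches a term if any of its keywords is a case-insensitive
#' substring of the term name (the text-search route) or if the term is
#' the anchor or a descendant of any anchor term (the parent-child route).
#' All matching themes are returned; a term matching none is labelled
#' `"unclassified"`.
#'
#' @param term term id.
#' @param dag a [GODag-class].
#' @param theme_map named list: theme -> list(keywords, anchor_terms).
#' @return Character vector of theme names (at least `"unclassified"`).
#' @export
assignThemes <- function(term, dag, theme_map) {
  stopifnot(is(dag, "GODag"))
  if (!term %in% dag@terms$id) stop("unknown term: ", term)
  nm <- tolower(dag@terms$name[match(term, dag@terms$id)])
  anc <- dag@ancestors[[term]]
  hits <- vapply(theme_map, function(th) {
    kw <- tolower(th$keywords %||% character(0))
    if (any(vapply(kw, function(k) grepl(k, nm, fixed = TRUE),
                   logical(1)))) {
      return(TRUE)
    }
    any((th$anchor_terms %||% character(0)) %in% c(term, anc))
  }, logical(1))
  if (any(hits)) names(theme_map)[hits] else "unclassified"
}

#' Signed condition-by-pathway theme matrix from seeded networks
#'
#' For every (stratum, sign) the positively / negatively correlated genes
#' of all seeds are pooled and tested with [goEnrichment()]; a retained
#' term's `contributing_seeds` is the number of individual seeds whose own
#' correlate list yields `q < q_threshold` for that term (terms with no
#' per-seed support are dropped). Themes are attached with
#' [assignThemes()]. The wide matrix mirrors the signed figure layout:
#' rows are terms, columns (stratum, sign) pairs, entries `-log10(q)`
#' with negative sign encoding the negative lists.
#'
#' @param networks long data.frame from [seededNetworks()].
#' @param dag a [GODag-class].
#' @param theme_map theme map (see [assignThemes()]).
#' @param universe background for enrichment (default: annotated genes).
#' @param q_threshold FDR cutoff (default 0.05).
#' @param cap display cap for `-log10(q)` (default 10).
#' @return List with `table` (long ThemedEnrichment data.frame: `stratum`,
#'   `sign`, `term`, `name`, `p`, `q`, `themes`, `contributing_seeds`) and
#'   `matrix` (signed wide matrix).
#' @export
signedThemeMatrix <- function(networks, dag, theme_map, universe = NULL,
                              q_threshold = 0.05, cap = 10) {
  stopifnot(all(c("stratum", "seed", "gene", "sign") %in%
                  colnames(networks)))
  groups <- split(networks, list(networks$stratum, networks$sign),
                  drop = TRUE)
  rows <- list()
  for (g in groups) {
    stratum <- g$stratum[1]; sgn <- g$sign[1]
    enr <- suppressWarnings(
      goEnrichment(unique(g$gene), dag, universe, q_threshold)
    )
    if (nrow(enr) == 0L) next
    per_seed <- lapply(split(g$gene, g$seed), function(gl) {
      suppressWarnings(goEnrichment(gl, dag, universe, q_threshold)$term)
    })
    contrib <- vapply(enr$term, function(tid) {
      sum(vapply(per_seed, function(tt) tid %in% tt, logical(1)))
    }, integer(1))
    keep <- contrib >= 1L
    if (!any(keep)) next
    enr <- enr[keep, , drop = FALSE]
    themes <- vapply(enr$term, function(tid) {
      paste(assignThemes(tid, dag, theme_map), collapse = ";")
    }, character(1))
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = stratum, sign = sgn, term = enr$term, name = enr$name,
      p = enr$p, q = enr$q, themes = themes,
      contributing_seeds = unname(contrib[keep]),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows) %||% data.frame(
    stratum = character(0), sign = character(0), term = character(0),
    name = character(0), p = numeric(0), q = numeric(0),
    themes = character(0), contributing_seeds = integer(0)
  )

  terms <- unique(tab$term)
  cols <- unique(paste(tab$stratum, tab$sign, sep = "|"))
  mat <- matrix(0, nrow = length(terms), ncol = length(cols),
                dimnames = list(terms, cols))
  if (nrow(tab)) {
    score <- pmin(-log10(pmax(tab$q, 10^(-cap))), cap)
    score <- ifelse(tab$sign == "negative", -score, score)
    mat[cbind(tab$term, paste(tab$stratum, tab$sign, sep = "|"))] <- score
  }
  list(table = tab, matrix = mat)
}

#' Overlap between two q-filtered pathway tables
#'
#' Exact term-id set operations between, e.g., the pathways associated
#' with down-regulated RPGs and those associated with up-regulated RP
#' pseudogenes; shared terms are the candidates for pseudogene-linked
#' regulation. Each side's enrichment strength is preserved as
#' `-log10(q)`.
#'
#' @param enrich_a,enrich_b data.frames with columns `term` and `q`
#'   (already FDR-filtered), e.g. from [goEnrichment()].
#' @return List with data.frames `shared` (`term`, `neglog_q_a`,
#'   `neglog_q_b`), `only_a` and `only_b` (`term`, `neglog_q`).
#' @export
pathwayOverlap <- function(enrich_a, enrich_b) {
  stopifnot(all(c("term", "q") %in% colnames(enrich_a)),
            all(c("term", "q") %in% colnames(enrich_b)))
  shared <- intersect(enrich_a$term, enrich_b$term)
  nl <- function(q) -log10(pmax(q, .Machine$double.xmin))
  list(
    shared = data.frame(
      term = shared,
      neglog_q_a = nl(enrich_a$q[match(shared, enrich_a$term)]),
      neglog_q_b = nl(enrich_b$q[match(shared, enrich_b$term)])
    ),
    only_a = {
      oa <- setdiff(enrich_a$term, enrich_b$term)
      data.frame(term = oa,
                 neglog_q = nl(enrich_a$q[match(oa, enrich_a$term)]))
    },
    only_b = {
      ob <- setdiff(enrich_b$term, enrich_a$term)
      data.frame(term = ob,
                 neglog_q = nl(enrich_b$q[match(ob, enrich_b$term)]))
    }
  )
}
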