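## S4 classes for the composite reference, its exact-match index, the
## count container, the simulation design and the GO DAG.

#' CompositeReference: contigs plus annotated loci with divergence truth
#'
#' A composite reference holds genomic-style contigs together with spliced
#' parent mRNA sequences as standalone contigs, and a set of loci (parent
#' mRNAs, pseudogene copies embedded in decoy contigs, and pure decoys).
#' For synthetic references the exact substituted positions of every
#' pseudogene relative to its parent are recorded as ground truth.
#'
#' @slot contigs [Biostrings::DNAStringSet] named contig sequences.
#' @slot loci [GenomicRanges::GRanges] with metadata columns `locus_id`,
#'   `class` (one of `"parent"`, `"pseudogene"`, `"decoy"`) and
#'   `parent_of` (parent `locus_id` for pseudogenes, `NA` otherwise).
#'   Coordinates are 1-based closed intervals within their contig (the
#'   on-disk interchange format is 0-based half-open; see
#'   [writeLociTable()]).
#' @slot truthDivergence named list mapping pseudogene `locus_id` to the
#'   integer positions (1-based, locus coordinates) substituted relative to
#'   the parent mRNA. Empty for references read from files.
#'
#' @seealso [generateCompositeReference()], [buildCompositeIndex()]
#' @exportClass CompositeReference
setClass(
  "CompositeReference",
  slots = c(
    contigs = "DNAStringSet",
    loci = "GRanges",
    truthDivergence = "list"
  )
)

setValidity("CompositeReference", function(object) {
  msgs <- character(0)
  mc <- mcols(object@loci)
  need <- c("locus_id", "class", "parent_of")
  if (!all(need %in% colnames(mc))) {
    return(paste("loci must carry metadata columns:",
                 paste(need, collapse = ", ")))
  }
  if (anyDuplicated(mc$locus_id)) msgs <- c(msgs, "duplicate locus_id")
  if (!all(mc$class %in% c("parent", "pseudogene", "decoy"))) {
    msgs <- c(msgs, "locus class must be parent, pseudogene or decoy")
  }
  ps <- mc$class == "pseudogene"
  if (any(ps & is.na(mc$parent_of))) {
    msgs <- c(msgs, "every pseudogene needs parent_of")
  }
  if (any(!is.na(mc$parent_of[ps]) &
          !(mc$parent_of[ps] %in% mc$locus_id[mc$class == "parent"]))) {
    msgs <- c(msgs, "parent_of must name a parent locus")
  }
  cn <- names(object@contigs)
  sq <- as.character(seqnames(object@loci))
  if (!all(sq %in% cn)) {
    msgs <- c(msgs, "loci reference unknown contigs")
  } else {
    w <- width(object@contigs)[match(sq, cn)]
    if (any(start(object@loci) < 1L) || any(end(object@loci) > w)) {
      msgs <- c(msgs, "locus coordinates outside contig bounds")
    }
  }
  if (length(object@truthDivergence) &&
      !all(names(object@truthDivergence) %in% mc$locus_id[ps])) {
    msgs <- c(msgs, "truthDivergence names must be pseudogene loci")
  }
  af <- alphabetFrequency(object@contigs, baseOnly = TRUE)
  if (any(af[, "other"] > 0)) msgs <- c(msgs, "contigs contain non-ACGT bases")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn CompositeReference-class contig sequences.
#' @param object,x a `CompositeReference`.
#' @export
setGeneric("refContigs", function(x) standardGeneric("refContigs"))

#' @export
setMethod("refContigs", "CompositeReference", function(x) x@contigs)

#' @describeIn CompositeReference-class locus annotations as a `GRanges`.
#' @export
setGeneric("refLoci", function(x) standardGeneric("refLoci"))

#' @export
setMethod("refLoci", "CompositeReference", function(x) x@loci)

#' @describeIn CompositeReference-class ground-truth substituted positions.
#' @export
setGeneric("truthDivergence", function(x) standardGeneric("truthDivergence"))

#' @export
setMethod("truthDivergence", "CompositeReference",
          function(x) x@truthDivergence)

#' @describeIn CompositeReference-class extract the (strand-resolved)
#'   sequence of every locus as a named `DNAStringSet`.
#' @export
setGeneric("lociSeqs", function(x) standardGeneric("lociSeqs"))

#' @export
setMethod("lociSeqs", "CompositeReference", function(x) {
  gr <- x@loci
  seqs <- subseq(
    x@contigs[match(as.character(seqnames(gr)), names(x@contigs))],
    start = start(gr), end = end(gr)
  )
  minus <- as.character(strand(gr)) == "-"
  if (any(minus)) seqs[minus] <- reverseComplement(seqs[minus])
  names(seqs) <- mcols(gr)$locus_id
  seqs
})

setMethod("show", "CompositeReference", function(object) {
  mc <- mcols(object@loci)
  cat("CompositeReference with", length(object@contigs), "contigs and",
      length(object@loci), "loci\n")
  cat("  classes:",
      paste(sprintf("%s=%d", names(table(mc$class)), table(mc$class)),
            collapse = ", "), "\n")
  cat("  total contig length:", sum(width(object@contigs)), "bp\n")
})

#' CompositeIndex: exact-occurrence lookup over locus sequences
#'
#' Supports exact full-length queries of a read (and its reverse
#' complement) against every locus of a [CompositeReference-class]. No
#' mismatches are tolerated, mirroring an alignment protocol that maps
#' without mismatches and discards multi-locus reads.
#'
#' @slot seqs named `DNAStringSet` of locus sequences (forward strand).
#' @slot classes named character vector of locus classes.
#'
#' @seealso [buildCompositeIndex()], [assignRead()], [assignReads()]
#' @exportClass CompositeIndex
setClass(
  "CompositeIndex",
  slots = c(seqs = "DNAStringSet", classes = "character")
)

setValidity("CompositeIndex", function(object) {
  if (length(object@seqs) == 0L) return("empty index")
  if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs))) {
    return("locus sequences must have unique names")
  }
  if (!identical(names(object@seqs), names(object@classes))) {
    return("classes must be named like seqs")
  }
  TRUE
})

setMethod("show", "CompositeIndex", function(object) {
  cat("CompositeIndex over", length(object@seqs), "loci (",
      sum(width(object@seqs)), "bp )\n")
})

#' StressCountSet: gene-by-sample counts with stress-design metadata
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass whose
#' `counts` assay holds non-negative integer counts and whose `colData`
#' carries at least a two-level `group` factor (reference level
#' `"control"`), plus optional `species`, `sex` and numeric covariates.
#'
#' @seealso [simulateCounts()], [filterLowCounts()], [deTest()]
#' @exportClass StressCountSet
setClass("StressCountSet", contains = "SummarizedExperiment")

setValidity("StressCountSet", function(object) {
  msgs <- character(0)
  if (!"counts" %in% assayNames(object)) {
    return("assay 'counts' is required")
  }
  cnt <- assay(object, "counts")
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    msgs <- c(msgs, "counts must be non-negative integers")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
    msgs <- c(msgs, "gene symbols (rownames) must be unique")
  }
  cd <- colData(object)
  if (!"group" %in% colnames(cd)) {
    msgs <- c(msgs, "colData must contain 'group'")
  } else {
    g <- cd$group
    if (any(is.na(g))) msgs <- c(msgs, "every sample needs a group label")
    if (!"control" %in% unique(as.character(g))) {
      msgs <- c(msgs, "group must include the reference level 'control'")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a StressCountSet
#'
#' @param counts integer matrix, genes in rows (rownames = symbols),
#'   samples in columns.
#' @param colData data.frame or DataFrame of per-sample metadata; must
#'   contain `group` with reference level `"control"`.
#' @return A [StressCountSet-class].
#' @examples
#' cnt <- matrix(rpois(20, 10), 4, 5,
#'               dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' meta <- data.frame(group = c("control", "control", "stress", "stress",
#'                              "stress"))
#' StressCountSet(cnt, meta)
#' @export
StressCountSet <- function(counts, colData) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  cd <- as(as.data.frame(colData), "DataFrame")
  rownames(cd) <- colnames(counts)
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
  new("StressCountSet", se)
}

#' SimDesign: parameters of the negative-binomial count simulation
#'
#' Encodes the "stated world" of one synthetic species: sample layout
#' (sexes x groups x n per group), planted log2 fold changes applied to the
#' stress group, co-expression modules driven by shared Gaussian latent
#' factors, NB dispersion, library-size range and nuisance covariates.
#'
#' @slot species single species label (e.g. `"mouse"`).
#' @slot genes character vector, the simulated gene universe.
#' @slot nPerGroup samples per (sex, group) cell; `>= 2`.
#' @slot sexes,groups factor levels of the design; `groups[1]` is control.
#' @slot planted named numeric of log2 fold changes (stress vs control);
#'   genes not named are null.
#' @slot modules list of module specs: each a list with `seeds`, `members`,
#'   `sign` (+1/-1, loading sign of members relative to seeds), `magnitude`
#'   (log2-scale loading) and `latent` (id; modules sharing a `latent` id
#'   share the factor, which is how pseudogene blocks anti-correlate with
#'   their parent RPG module).
#' @slot dispersion NB dispersion phi (`var = mu + phi mu^2`); 0 = Poisson.
#' @slot libSizeRange two library sizes; samples draw log-uniformly between.
#' @slot covariates named numeric; per-covariate SD of gene-level log2
#'   coefficients (covariate values are standard normal per sample).
#' @slot baseMeanLog meanlog/sdlog of the log-normal base-mean draw
#'   (expected counts at library size 1e6).
#' @slot seed RNG seed making the simulation a pure function of the design.
#'
#' @seealso [simDesign()], [simulateCounts()], [demoDesign()]
#' @exportClass SimDesign
setClass(
  "SimDesign",
  slots = c(
    species = "character",
    genes = "character",
    nPerGroup = "integer",
    sexes = "character",
    groups = "character",
    planted = "numeric",
    modules = "list",
    dispersion = "numeric",
    libSizeRange = "numeric",
    covariates = "numeric",
    baseMeanLog = "numeric",
    seed = "integer"
  )
)

setValidity("SimDesign", function(object) {
  msgs <- character(0)
  if (object@nPerGroup < 2L) msgs <- c(msgs, "nPerGroup must be >= 2")
  if (object@dispersion < 0) msgs <- c(msgs, "dispersion must be >= 0")
  if (length(object@groups) != 2L || object@groups[1] != "control") {
    msgs <- c(msgs, "groups must be c('control', <case>)")
  }
  if (anyDuplicated(object@genes)) msgs <- c(msgs, "duplicate gene symbols")
  if (!all(names(object@planted) %in% object@genes)) {
    msgs <- c(msgs, "planted genes must be in the gene universe")
  }
  for (m in object@modules) {
    if (!all(c("seeds", "members", "sign", "magnitude", "latent") %in%
             names(m))) {
      msgs <- c(msgs, "module spec needs seeds/members/sign/magnitude/latent")
      break
    }
    if (!all(c(m$seeds, m$members) %in% object@genes)) {
      msgs <- c(msgs, "module genes must be in the gene universe")
    }
    if (!m$sign %in% c(-1, 1)) msgs <- c(msgs, "module sign must be +/-1")
  }
  if (length(object@libSizeRange) != 2L || any(object@libSizeRange <= 0)) {
    msgs <- c(msgs, "libSizeRange must be two positive numbers")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SimDesign", function(object) {
  cat("SimDesign:", object@species, "-", length(object@genes), "genes,",
      object@nPerGroup, "per (sex x group) cell,",
      length(object@sexes) * length(object@groups) * object@nPerGroup,
      "samples\n")
  cat("  planted effects:", length(object@planted),
      "| modules:", length(object@modules),
      "| dispersion:", object@dispersion, "\n")
})

#' GODag: a minimal Gene Ontology DAG with gene annotations
#'
#' Stores term descriptions, `is_a` parent edges, direct gene annotations
#' and the precomputed transitive structures used by enrichment: ancestor
#' sets and the annotation closure (a gene annotated to a term is annotated
#' to all of its ancestors). Construction fails on cyclic edge sets.
#'
#' @slot terms data.frame with columns `id`, `name`, `namespace`.
#' @slot parents named list, term id -> character vector of parent ids.
#' @slot ancestors named list, term id -> all ancestors (excluding itself).
#' @slot annotations named list, gene -> direct term ids.
#' @slot term2genes named list, term id -> genes annotated after closure.
#'
#' @seealso [goDag()], [readOBO()], [goEnrichment()]
#' @exportClass GODag
setClass(
  "GODag",
  slots = c(
    terms = "data.frame",
    parents = "list",
    ancestors = "list",
    annotations = "list",
    term2genes = "list"
  )
)

setValidity("GODag", function(object) {
  msgs <- character(0)
  ids <- object@terms$id
  if (anyDuplicated(ids)) msgs <- c(msgs, "duplicate term ids")
  if (!all(unlist(object@parents) %in% ids)) {
    msgs <- c(msgs, "is_a edges point to unknown terms")
  }
  if (!all(unlist(object@annotations) %in% ids)) {
    msgs <- c(msgs, "annotations reference unknown terms")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GODag", function(object) {
  cat("GODag with", nrow(object@terms), "terms,",
      sum(lengths(object@parents) > 0), "child terms and",
      length(object@annotations), "annotated genes\n")
})

#' @describeIn GODag-class genes with at least one (direct) annotation —
#'   the default enrichment universe.
#' @param x a `GODag`.
#' @export
setGeneric("annotatedGenes", function(x) standardGeneric("annotatedGenes"))

#' @export
setMethod("annotatedGenes", "GODag", function(x) names(x@annotations))

#' @describeIn GODag-class term descriptions (`id`, `name`, `namespace`).
#' @export
setGeneric("goTerms", function(x) standardGeneric("goTerms"))

#' @export
setMethod("goTerms", "GODag", function(x) x@terms)
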