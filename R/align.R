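## Pseudogene-aware read assignment: exact full-length matching against a
## composite reference, discarding reads matching more than one locus.

#' Build an exact-occurrence index over the loci of a composite reference
#'
#' The index answers exact substring queries (both strands, no mismatches)
#' against every locus sequence. Parent mRNAs are standalone loci alongside
#' pseudogene and decoy loci.
#'
#' @param ref a [CompositeReference-class].
#' @return A [CompositeIndex-class].
#' @examples
#' ref <- generateCompositeReference(n_parents = 2, seed = 1)
#' idx <- buildCompositeIndex(ref)
#' idx
#' @export
buildCompositeIndex <- function(ref) {
  stopifnot(is(ref, "CompositeReference"))
  if (length(refLoci(ref)) == 0L) stop("reference has no loci")
  seqs <- lociSeqs(ref)
  check_acgt(seqs, what = "locus")
  cls <- setNames(mcols(refLoci(ref))$class, names(seqs))
  new("CompositeIndex", seqs = seqs, classes = cls)
}

## Distinct loci containing `query` exactly (forward or reverse
## complement). Multiple offsets within one locus count once.
query_loci <- function(query, index) {
  q <- DNAString(query)
  fwd <- vcountPattern(q, index@seqs, fixed = TRUE)
  rev <- vcountPattern(reverseComplement(q), index@seqs, fixed = TRUE)
  names(index@seqs)[fwd + rev > 0L]
}

#' Assign a single read to a locus by exact unique matching
#'
#' A read is assigned to the one locus in which it (or its reverse
#' complement) occurs verbatim; a read occurring in two or more distinct
#' loci is discarded as multi-locus (reads from regions where a pseudogene
#' is identical to its parent can never be attributed), and a read
#' occurring nowhere is unmapped. Multiple offsets within a single locus
#' count as one locus.
#'
#' @param read character scalar or `DNAString` over `{A,C,G,T}`.
#' @param index a [CompositeIndex-class].
#' @return A one-row data.frame: `read_id` (NA here; filled by
#'   [assignReads()]), `status` (`"unique"`, `"discarded_multilocus"` or
#'   `"unmapped"`), `locus_id` (only for unique assignments) and
#'   `occurrences` (number of distinct loci matched).
#' @examples
#' ref <- generateCompositeReference(n_parents = 1, pseudos_per_parent = 1,
#'                                   divergence_rate = 0, seed = 1)
#' idx <- buildCompositeIndex(ref)
#' rd <- as.character(subseq(lociSeqs(ref)[["RP01"]], 1, 50))
#' assignRead(rd, idx)$status  # identical copies: multi-locus
#' @export
assignRead <- function(read, index) {
  stopifnot(is(index, "CompositeIndex"))
  read <- as.character(read)
  if (length(read) != 1L || is.na(read) || nchar(read) == 0L) {
    stop("read must be a single non-empty sequence")
  }
  check_acgt(setNames(read, "query"), what = "read")
  hits <- query_loci(read, index)
  n <- length(hits)
  data.frame(
    read_id = NA_character_,
    status = if (n == 1L) "unique" else if (n >= 2L) "discarded_multilocus"
             else "unmapped",
    locus_id = if (n == 1L) hits else NA_character_,
    occurrences = n,
    stringsAsFactors = FALSE
  )
}

#' Assign a set of reads by exact unique matching
#'
#' Vectorised equivalent of [assignRead()]: reads of equal length are
#' matched with a preprocessed dictionary ([Biostrings::PDict]) against
#' every locus on both strands.
#'
#' @param reads named `DNAStringSet` (or character vector) of reads.
#' @param index a [CompositeIndex-class].
#' @return A data.frame with one row per read: `read_id`, `status`,
#'   `locus_id`, `occurrences`.
#' @examples
#' ref <- generateCompositeReference(seed = 1)
#' idx <- buildCompositeIndex(ref)
#' rs <- simulateReads(ref, read_len = 75, depth_per_locus = 10, seed = 2)
#' table(assignReads(rs$reads, idx)$status)
#' @export
assignReads <- function(reads, index) {
  stopifnot(is(index, "CompositeIndex"))
  reads <- DNAStringSet(reads)
  if (length(reads) == 0L) {
    return(data.frame(read_id = character(0), status = character(0),
                      locus_id = character(0), occurrences = integer(0)))
  }
  if (any(width(reads) == 0L)) stop("empty read in input")
  check_acgt(reads, what = "read")
  if (is.null(names(reads))) {
    names(reads) <- sprintf("read%06d", seq_along(reads))
  }

  nloci <- length(index@seqs)
  hit <- matrix(FALSE, nrow = length(reads), ncol = nloci)

  for (w in unique(width(reads))) {
    sel <- which(width(reads) == w)
    pd_f <- PDict(reads[sel])
    pd_r <- PDict(reverseComplement(reads[sel]))
    for (j in seq_len(nloci)) {
      subj <- index@seqs[[j]]
      ii <- union(whichPDict(pd_f, subj), whichPDict(pd_r, subj))
      if (length(ii)) hit[sel[ii], j] <- TRUE
    }
  }

  occ <- rowSums(hit)
  status <- ifelse(occ == 1L, "unique",
                   ifelse(occ >= 2L, "discarded_multilocus", "unmapped"))
  locus <- rep(NA_character_, length(reads))
  uniq <- which(occ == 1L)
  if (length(uniq)) {
    locus[uniq] <- names(index@seqs)[max.col(hit[uniq, , drop = FALSE])]
  }
  data.frame(read_id = names(reads), status = status, locus_id = locus,
             occurrences = as.integer(occ), stringsAsFactors = FALSE)
}

#' Quantify unique-read counts per locus
#'
#' @param assignments data.frame from [assignReads()].
#' @param ref the [CompositeReference-class] (or a [CompositeIndex-class])
#'   the assignments refer to; assignments naming unknown loci raise a
#'   consistency error.
#' @return A list with `counts`, a data.frame (`locus_id`, `class`,
#'   `unique_count`) covering every locus, and `summary`, a one-row
#'   data.frame with `total`, `unique`, `discarded_multilocus`, `unmapped`.
#'   The per-locus counts plus discarded and unmapped always sum to the
#'   total.
#' @examples
#' ref <- generateCompositeReference(seed = 1)
#' idx <- buildCompositeIndex(ref)
#' rs <- simulateReads(ref, read_len = 75, depth_per_locus = 10, seed = 2)
#' q <- quantifyAssignments(assignReads(rs$reads, idx), ref)
#' q$summary
#' @export
quantifyAssignments <- function(assignments, ref) {
  if (is(ref, "CompositeReference")) {
    ids <- mcols(refLoci(ref))$locus_id
    cls <- mcols(refLoci(ref))$class
  } else if (is(ref, "CompositeIndex")) {
    ids <- names(ref@seqs)
    cls <- unname(ref@classes)
  } else {
    stop("ref must be a CompositeReference or CompositeIndex")
  }
  known <- assignments$locus_id[!is.na(assignments$locus_id)]
  if (!all(known %in% ids)) {
    stop("assignments reference unknown loci: ",
         paste(unique(setdiff(known, ids)), collapse = ", "))
  }
  uc <- table(factor(assignments$locus_id[assignments$status == "unique"],
                     levels = ids))
  counts <- data.frame(locus_id = ids, class = cls,
                       unique_count = as.integer(uc),
                       stringsAsFactors = FALSE)
  summary <- data.frame(
    total = nrow(assignments),
    unique = sum(assignments$status == "unique"),
    discarded_multilocus = sum(assignments$status ==
                                 "discarded_multilocus"),
    unmapped = sum(assignments$status == "unmapped")
  )
  stopifnot(sum(counts$unique_count) + summary$discarded_multilocus +
              summary$unmapped == summary$total)
  list(counts = counts, summary = summary)
}
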