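## Synthetic composite reference and error-free read simulation.

#' Generate a synthetic composite reference with pseudogene copies
#'
#' Builds a toy-scale composite reference emulating the parent/pseudogene
#' homology problem: each parent RPG is represented by its spliced mRNA as
#' a standalone contig-plus-locus, and each pseudogene is a copy of its
#' parent mRNA carrying i.i.d. per-base substitutions at `divergence_rate`,
#' embedded mid-contig in a random decoy contig. One pure decoy locus is
#' added. Every substituted position is recorded as ground truth.
#'
#' At `divergence_rate = 0` pseudogenes are byte-identical to their parents,
#' the limit in which no read can be uniquely assigned to either copy.
#'
#' @param n_parents number of parent genes (default 4).
#' @param pseudos_per_parent pseudogene copies per parent (default 2).
#' @param mrna_len parent mRNA length in bp (default 600); must be at least
#'   twice the read length used downstream.
#' @param divergence_rate per-base substitution probability in `[0, 1]`.
#' @param flank_len random flank added on each side of an embedded
#'   pseudogene (default 150 bp).
#' @param seed RNG seed; identical arguments give a byte-identical
#'   reference.
#' @return A [CompositeReference-class].
#' @examples
#' ref <- generateCompositeReference(n_parents = 2, divergence_rate = 0.05,
#'                                   seed = 1)
#' ref
#' lengths(truthDivergence(ref))
#' @export
generateCompositeReference <- function(n_parents = 4L,
                                       pseudos_per_parent = 2L,
                                       mrna_len = 600L,
                                       divergence_rate = 0.05,
                                       flank_len = 150L,
                                       seed = 1L) {
  assert_scalar_number(divergence_rate, "divergence_rate", 0, 1)
  if (n_parents < 1L || pseudos_per_parent < 0L || mrna_len < 20L) {
    stop("need n_parents >= 1, pseudos_per_parent >= 0, mrna_len >= 20")
  }
  with_seed(seed, {
    parent_ids <- sprintf("RP%02d", seq_len(n_parents))
    parent_seq <- random_dna(rep(mrna_len, n_parents))
    names(parent_seq) <- paste0(parent_ids, "_mRNA")

    contigs <- parent_seq
    loci <- data.frame(
      contig = names(parent_seq), start = 1L, end = mrna_len,
      strand = "+", locus_id = parent_ids, class = "parent",
      parent_of = NA_character_, stringsAsFactors = FALSE
    )
    truth <- list()

    for (i in seq_len(n_parents)) {
      for (j in seq_len(pseudos_per_parent)) {
        ps_id <- sprintf("%s-ps%d", parent_ids[i], j)
        base <- strsplit(parent_seq[[i]], "")[[1]]
        hit <- which(runif(mrna_len) < divergence_rate)
        for (pos in hit) {
          base[pos] <- sample(setdiff(DNA_BASES, base[pos]), 1L)
        }
        ps_seq <- paste(base, collapse = "")
        ctg_id <- paste0("chrD_", ps_id)
        contigs[ctg_id] <- paste0(random_dna(flank_len), ps_seq,
                                  random_dna(flank_len))
        loci <- rbind(loci, data.frame(
          contig = ctg_id, start = flank_len + 1L,
          end = flank_len + mrna_len, strand = "+", locus_id = ps_id,
          class = "pseudogene", parent_of = parent_ids[i],
          stringsAsFactors = FALSE
        ))
        truth[[ps_id]] <- as.integer(hit)
      }
    }

    decoy_len <- max(2L * mrna_len, 800L)
    contigs["chrDecoy"] <- random_dna(decoy_len)
    loci <- rbind(loci, data.frame(
      contig = "chrDecoy", start = 1L, end = decoy_len, strand = "+",
      locus_id = "decoy1", class = "decoy", parent_of = NA_character_,
      stringsAsFactors = FALSE
    ))

    gr <- GRanges(
      seqnames = loci$contig,
      ranges = IRanges(start = loci$start, end = loci$end),
      strand = loci$strand
    )
    mcols(gr)$locus_id <- loci$locus_id
    mcols(gr)$class <- loci$class
    mcols(gr)$parent_of <- loci$parent_of

    new("CompositeReference",
        contigs = DNAStringSet(contigs), loci = gr, truthDivergence = truth)
  })
}

#' Simulate error-free reads from every locus of a composite reference
#'
#' Reads are exact substrings of their origin locus sequence, drawn at
#' uniform positions on either strand. They are error-free because the
#' downstream assigner maps without allowing mismatches, so sequencing
#' errors would only add an unmapped class. FASTQ qualities are a constant
#' maximum when written with [writeReadsFastq()].
#'
#' @param ref a [CompositeReference-class].
#' @param read_len read length; must not exceed any locus length.
#' @param depth_per_locus reads drawn per locus (0 gives an empty set).
#' @param seed RNG seed.
#' @return A list with `reads` (named `DNAStringSet`) and `truth`, a
#'   data.frame with one row per read: `read_id`, `locus_id`, `start`
#'   (1-based within the locus) and `strand`.
#' @examples
#' ref <- generateCompositeReference(n_parents = 2, seed = 1)
#' rs <- simulateReads(ref, read_len = 75, depth_per_locus = 5, seed = 2)
#' length(rs$reads)
#' @export
simulateReads <- function(ref, read_len = 75L, depth_per_locus = 50L,
                          seed = 1L) {
  stopifnot(is(ref, "CompositeReference"))
  seqs <- lociSeqs(ref)
  if (read_len > min(width(seqs))) {
    stop("read_len (", read_len, ") exceeds the shortest locus (",
         min(width(seqs)), ")")
  }
  if (depth_per_locus == 0L) {
    return(list(
      reads = DNAStringSet(),
      truth = data.frame(read_id = character(0), locus_id = character(0),
                         start = integer(0), strand = character(0))
    ))
  }
  with_seed(seed, {
    per <- lapply(names(seqs), function(lid) {
      L <- width(seqs[lid])
      st <- sample.int(L - read_len + 1L, depth_per_locus, replace = TRUE)
      sr <- sample(c("+", "-"), depth_per_locus, replace = TRUE)
      data.frame(locus_id = lid, start = st, strand = sr,
                 stringsAsFactors = FALSE)
    })
    truth <- do.call(rbind, per)
    truth$read_id <- sprintf("read%06d", seq_len(nrow(truth)))
    truth <- truth[, c("read_id", "locus_id", "start", "strand")]

    reads <- subseq(seqs[truth$locus_id], start = truth$start,
                    width = read_len)
    minus <- truth$strand == "-"
    if (any(minus)) reads[minus] <- reverseComplement(reads[minus])
    names(reads) <- truth$read_id
    list(reads = reads, truth = truth)
  })
}
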