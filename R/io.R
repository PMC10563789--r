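## Readers and writers for the plain-text interchange formats: FASTA,
## FASTQ, locus tables (0-based half-open), count/metadata TSVs, DETables,
## family tables, ortholog maps, minimal OBO, annotation TSVs and theme
## maps (JSON).

#' Write contigs of a composite reference as FASTA
#'
#' @param ref a [CompositeReference-class] (or a named `DNAStringSet`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReferenceFasta <- function(ref, path) {
  seqs <- if (is(ref, "CompositeReference")) refContigs(ref) else
    DNAStringSet(ref)
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Write the locus table of a composite reference
#'
#' Tab-separated with 0-based half-open coordinates: columns `contig`,
#' `start`, `end`, `strand`, `locus_id`, `class`, `parent_of`.
#'
#' @param ref a [CompositeReference-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeLociTable <- function(ref, path) {
  gr <- refLoci(ref)
  df <- data.frame(
    contig = as.character(seqnames(gr)),
    start = start(gr) - 1L,          # 0-based half-open on disk
    end = end(gr),
    strand = as.character(strand(gr)),
    locus_id = mcols(gr)$locus_id,
    class = mcols(gr)$class,
    parent_of = ifelse(is.na(mcols(gr)$parent_of), ".",
                       mcols(gr)$parent_of),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}

#' Read a composite reference from FASTA + locus table
#'
#' Inverse of [writeReferenceFasta()] / [writeLociTable()]; the divergence
#' ground truth is not part of the interchange format and comes back
#' empty.
#'
#' @param fasta_path contig FASTA.
#' @param loci_path locus TSV (0-based half-open).
#' @return A [CompositeReference-class].
#' @export
readCompositeReference <- function(fasta_path, loci_path) {
  contigs <- readDNAStringSet(fasta_path)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  df <- read_tsv(loci_path)
  gr <- GRanges(
    seqnames = df$contig,
    ranges = IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand
  )
  mcols(gr)$locus_id <- df$locus_id
  mcols(gr)$class <- df$class
  mcols(gr)$parent_of <- ifelse(df$parent_of == ".", NA_character_,
                                df$parent_of)
  new("CompositeReference", contigs = contigs, loci = gr,
      truthDivergence = list())
}

#' Write reads as FASTQ with constant maximum quality
#'
#' @param reads named `DNAStringSet`.
#' @param path output file; qualities are a constant `"I"` (Phred+33, Q40).
#' @return `path`, invisibly.
#' @export
writeReadsFastq <- function(reads, path) {
  reads <- DNAStringSet(reads)
  qual <- BStringSet(vapply(width(reads),
                            function(w) strrep("I", w), character(1)))
  writeXStringSet(reads, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a DNAStringSet
#'
#' @param path FASTQ file.
#' @return Named `DNAStringSet` (qualities are ignored; the assigner is
#'   quality-blind by design).
#' @export
readReadsFastq <- function(path) {
  readDNAStringSet(path, format = "fastq")
}

#' Write / read a gene-by-sample count matrix TSV
#'
#' Header row = sample ids; first column `gene`.
#'
#' @param x matrix or [StressCountSet-class]; `path` the file.
#' @return `path` / integer matrix with gene rownames.
#' @export
writeCountsTable <- function(x, path) {
  cnt <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else x
  df <- data.frame(gene = rownames(cnt), cnt, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname writeCountsTable
#' @param path TSV path.
#' @export
readCountsTable <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene
  m
}

#' Write / read per-sample metadata TSV
#'
#' Columns: `sample_id`, `species`, `sex`, `group`, plus covariates.
#'
#' @param metadata data.frame; `path` the file.
#' @return `path` / data.frame.
#' @export
writeSampleMeta <- function(metadata, path) {
  write_tsv(as.data.frame(metadata), path)
}

#' @rdname writeSampleMeta
#' @param path TSV path.
#' @export
readSampleMeta <- function(path) read_tsv(path)

#' Read a StressCountSet from counts + metadata TSVs
#'
#' @param counts_path,meta_path file paths.
#' @return A [StressCountSet-class].
#' @export
readStressCountSet <- function(counts_path, meta_path) {
  cnt <- readCountsTable(counts_path)
  md <- readSampleMeta(meta_path)
  md <- md[match(colnames(cnt), md$sample_id), , drop = FALSE]
  StressCountSet(cnt, md)
}

#' Write / read a DETable TSV
#'
#' Columns `gene`, `log2FC`, `p`, `q`, `direction` — the drop-in format
#' for externally computed differential-expression results.
#'
#' @param de DETable data.frame; `path` the file.
#' @return `path` / data.frame.
#' @export
writeDETable <- function(de, path) write_tsv(de, path)

#' @rdname writeDETable
#' @param path TSV path.
#' @export
readDETable <- function(path) {
  de <- read_tsv(path)
  stopifnot(all(c("gene", "log2FC", "p", "q") %in% colnames(de)))
  de
}

#' Write / read a gene-family table TSV (`family_id`, `species`, `symbol`)
#'
#' @param families data.frame; `path` the file.
#' @return `path` / data.frame.
#' @export
writeFamilyTable <- function(families, path) write_tsv(families, path)

#' @rdname writeFamilyTable
#' @param path TSV path.
#' @export
readFamilyTable <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("family_id", "species", "symbol") %in% colnames(df)))
  df
}

#' Write / read an ortholog map TSV (`mouse_symbol`, `human_symbol`)
#'
#' @param map data.frame; `path` the file.
#' @return `path` / data.frame (validated 1:1).
#' @export
writeOrthologMap <- function(map, path) write_tsv(map, path)

#' @rdname writeOrthologMap
#' @param path TSV path.
#' @export
readOrthologMap <- function(path) validate_ortholog_map(read_tsv(path))

#' Write a GO DAG as a minimal OBO file
#'
#' Only `id`, `name`, `namespace` and `is_a` stanza lines are emitted —
#' the subset of OBO the package parses.
#'
#' @param dag a [GODag-class] (annotations are not part of OBO; see
#'   [writeAnnotations()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeOBO <- function(dag, path) {
  stopifnot(is(dag, "GODag"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(dag@terms))) {
    writeLines(c(
      "", "[Term]",
      paste0("id: ", dag@terms$id[i]),
      paste0("name: ", dag@terms$name[i]),
      paste0("namespace: ", dag@terms$namespace[i]),
      vapply(dag@parents[[dag@terms$id[i]]] %||% character(0),
             function(p) paste0("is_a: ", p), character(1))
    ), con)
  }
  invisible(path)
}

#' Read a minimal OBO file into term and edge tables
#'
#' Parses `[Term]` stanzas with `id`, `name`, `namespace` and `is_a`
#' lines; everything else is ignored.
#'
#' @param path OBO file.
#' @param annotations optional data.frame (`gene`, `term`) to attach.
#' @return A [GODag-class].
#' @export
readOBO <- function(path, annotations = NULL) {
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) stop("no [Term] stanzas in ", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- nms <- nss <- character(length(starts))
  parents <- list()
  for (i in seq_along(starts)) {
    blk <- lines[starts[i]:(bounds[i + 1L] - 1L)]
    grab <- function(key) {
      v <- sub(paste0("^", key, ": *"), "",
               grep(paste0("^", key, ": "), blk, value = TRUE))
      sub(" *!.*$", "", v)  # drop trailing OBO comments
    }
    ids[i] <- grab("id")[1]
    nms[i] <- grab("name")[1]
    ns <- grab("namespace")
    nss[i] <- if (length(ns)) ns[1] else "unspecified"
    isa <- grab("is_a")
    if (length(isa)) parents[[ids[i]]] <- isa
  }
  goDag(data.frame(id = ids, name = nms, namespace = nss,
                   stringsAsFactors = FALSE),
        parents, annotations)
}

#' Write / read gene-to-term annotations TSV (`gene`, `term`)
#'
#' @param annotations data.frame; `path` the file.
#' @return `path` / data.frame.
#' @export
writeAnnotations <- function(annotations, path) write_tsv(annotations, path)

#' @rdname writeAnnotations
#' @param path TSV path.
#' @export
readAnnotations <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("gene", "term") %in% colnames(df)))
  df
}

#' Write / read a theme map (JSON)
#'
#' JSON object: theme name -> `{keywords: [...], anchor_terms: [...]}`.
#'
#' @param themes named list; `path` the file.
#' @return `path` / named list.
#' @export
writeThemeMap <- function(themes, path) {
  write_json(themes, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeThemeMap
#' @param path JSON path.
#' @export
readThemeMap <- function(path) {
  th <- read_json(path, simplifyVector = TRUE)
  lapply(th, function(t) list(keywords = unlist(t$keywords),
                              anchor_terms = unlist(t$anchor_terms)))
}
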