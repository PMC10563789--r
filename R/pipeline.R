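## File-based pipeline orchestration: reads -> counts -> DE -> family
## enrichment -> seeded networks -> themed matrices, plus the all-synthetic
## demo. Every stage consumes files and writes files, so any stage's input
## can be replaced by externally computed tables (e.g. real DESeq2 output).

PIPELINE_STAGES <- c("align", "de", "families", "seednet", "themes",
                     "overlap")

#' Default run configuration
#'
#' @param out_dir output directory.
#' @param inputs named list of input paths (see [writeDemoInputs()] for
#'   the full set).
#' @param seed RNG seed recorded in the manifest.
#' @param stages stages to run, in dependency order; subset of
#'   `c("align", "de", "families", "seednet", "themes", "overlap")`.
#' @param filter,p,q low-count filter and significance thresholds.
#' @param universe_size family-enrichment universe; `NULL` (default) uses
#'   the number of genes in each species' count table, the synthetic
#'   override of the 21,196-gene genomic background.
#' @param de_mode per-species threshold rule: raw p for MDD-style (human)
#'   contrasts, BH q for chronic-stress (mouse) contrasts.
#' @param covariates metadata columns residualised out before testing.
#' @return RunConfig list.
#' @export
runConfig <- function(out_dir, inputs, seed = 1L,
                      stages = PIPELINE_STAGES,
                      filter = 5, p = 0.05, q = 0.05,
                      universe_size = NULL,
                      de_mode = list(mouse = "q_threshold",
                                     human = "p_threshold"),
                      covariates = c("sex", "age", "rin")) {
  stopifnot(all(stages %in% PIPELINE_STAGES),
            p > 0, p <= 1, q > 0, q <= 1, filter >= 0)
  list(out_dir = out_dir, inputs = inputs, seed = as.integer(seed),
       stages = stages,
       thresholds = list(filter = filter, p = p, q = q,
                         universe_size = universe_size),
       de_mode = de_mode, covariates = covariates,
       species = c("mouse", "human"))
}

#' Write / read a run configuration as JSON
#'
#' @param config RunConfig list; `path` the file.
#' @return `path` / RunConfig list.
#' @export
writeRunConfig <- function(config, path) {
  write_json(config, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname writeRunConfig
#' @param path JSON path.
#' @export
readRunConfig <- function(path) {
  cfg <- read_json(path, simplifyVector = TRUE)
  cfg$thresholds$universe_size <- cfg$thresholds$universe_size %||% NULL
  cfg
}

## flatten the input path list and fail on the first missing file
check_inputs <- function(config) {
  paths <- unlist(config$inputs, use.names = TRUE)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input path(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(paths)
}

out_path <- function(config, ...) file.path(config$out_dir, paste0(...))

## shared DE-stage preprocessing reused by seednet
adjusted_logcpm <- function(config, sp) {
  se <- readStressCountSet(config$inputs$counts[[sp]],
                           config$inputs$meta[[sp]])
  se <- filterLowCounts(se, threshold = config$thresholds$filter)
  X <- normalizeLogCPM(se)
  covs <- intersect(config$covariates, colnames(colData(se)))
  cov_df <- if (length(covs)) {
    as.data.frame(colData(se)[, covs, drop = FALSE])
  } else NULL
  list(X = covariateAdjust(X, cov_df), se = se,
       meta = as.data.frame(colData(se)))
}

stage_align <- function(config, log) {
  ref <- readCompositeReference(config$inputs$ref_fasta,
                                config$inputs$loci)
  reads <- readReadsFastq(config$inputs$reads)
  idx <- buildCompositeIndex(ref)
  asn <- assignReads(reads, idx)
  q <- quantifyAssignments(asn, ref)
  write_tsv(asn, out_path(config, "assignments.tsv"))
  write_tsv(q$counts, out_path(config, "locus_counts.tsv"))
  write_tsv(q$summary, out_path(config, "align_summary.tsv"))
  log(sprintf("align: %d reads, %d unique, %d multi-locus, %d unmapped",
              q$summary$total, q$summary$unique,
              q$summary$discarded_multilocus, q$summary$unmapped))
}

stage_de <- function(config, log) {
  for (sp in config$species) {
    prep <- adjusted_logcpm(config, sp)
    mode <- config$de_mode[[sp]]
    alpha <- if (mode == "q_threshold") config$thresholds$q else
      config$thresholds$p
    de <- deTest(prep$X, prep$meta$group, mode = mode, alpha = alpha)
    writeDETable(de, out_path(config, "de_", sp, ".tsv"))
    log(sprintf(
      "de[%s]: %d genes tested (filter > %g), mode=%s alpha=%g, %d up / %d down",
      sp, nrow(de), config$thresholds$filter, mode, alpha,
      sum(de$direction == "up"), sum(de$direction == "down")))
  }
}

stage_families <- function(config, log) {
  fam <- readFamilyTable(config$inputs$families)
  enr <- list()
  for (sp in config$species) {
    de <- readDETable(out_path(config, "de_", sp, ".tsv"))
    mode <- config$de_mode[[sp]]
    alpha <- if (mode == "q_threshold") config$thresholds$q else
      config$thresholds$p
    sets <- selectSignificant(de, mode, alpha)
    fam_sp <- split(fam$symbol[fam$species == sp],
                    fam$family_id[fam$species == sp])
    N <- config$thresholds$universe_size %||%
      nrow(readCountsTable(config$inputs$counts[[sp]]))
    rows <- list()
    for (dir in c("up", "down")) {
      fe <- familyEnrichment(sets[[dir]], fam_sp, universe_size = N)
      fe <- cbind(species = sp, direction = dir, fe)
      rows[[dir]] <- fe
      enr[[paste(sp, dir, sep = ".")]] <- fe
    }
    write_tsv(do.call(rbind, rows),
              out_path(config, "families_", sp, ".tsv"))
    log(sprintf("families[%s]: N=%d, DE up=%d down=%d", sp, N,
                length(sets$up), length(sets$down)))
  }
  mat <- enrichmentScoreMatrix(enr)
  write_tsv(data.frame(contrast = rownames(mat), mat,
                       check.names = FALSE),
            out_path(config, "family_score_matrix.tsv"))
}

## common down-regulated genes across species, in the human namespace
common_down_set <- function(config) {
  map <- readOrthologMap(config$inputs$orthologs)
  sets <- lapply(config$species, function(sp) {
    de <- readDETable(out_path(config, "de_", sp, ".tsv"))
    mode <- config$de_mode[[sp]]
    alpha <- if (mode == "q_threshold") config$thresholds$q else
      config$thresholds$p
    selectSignificant(de, mode, alpha)$down
  })
  names(sets) <- config$species
  list(common = crossSpeciesCommon(sets$mouse, sets$human, map),
       map = map)
}

stage_seednet <- function(config, log) {
  cd <- common_down_set(config)
  write_tsv(data.frame(gene = cd$common),
            out_path(config, "common_down.tsv"))
  log(sprintf("seednet: %d common down-regulated seed genes",
              length(cd$common)))
  for (sp in config$species) {
    seeds <- if (sp == "human") cd$common else
      harmonizeSymbols(cd$common, from = "human", map = cd$map)
    nets <- if (length(seeds) == 0L) {
      log(sprintf("seednet[%s]: no seeds; writing empty network", sp))
      data.frame(stratum = character(0), seed = character(0),
                 gene = character(0), rho = numeric(0), p = numeric(0),
                 sign = character(0))
    } else {
      prep <- adjusted_logcpm(config, sp)
      seededNetworks(prep$X, prep$meta, seeds,
                     p_threshold = config$thresholds$p)
    }
    write_tsv(nets, out_path(config, "seednet_", sp, ".tsv"))
    log(sprintf("seednet[%s]: %d strata, %d correlate rows (p < %g)", sp,
                length(unique(nets$stratum)), nrow(nets),
                config$thresholds$p))
  }
}

stage_themes <- function(config, log) {
  themes <- readThemeMap(config$inputs$themes)
  tabs <- list()
  for (sp in config$species) {
    dag <- readOBO(config$inputs$obo,
                   readAnnotations(config$inputs$annotations[[sp]]))
    nets <- read_tsv(out_path(config, "seednet_", sp, ".tsv"))
    stm <- signedThemeMatrix(nets, dag, themes,
                             q_threshold = config$thresholds$q)
    tabs[[sp]] <- data.frame(species = rep(sp, nrow(stm$table)),
                             stm$table)
    write_tsv(data.frame(term = rownames(stm$matrix), stm$matrix,
                         check.names = FALSE),
              out_path(config, "theme_matrix_", sp, ".tsv"))
  }
  long <- do.call(rbind, tabs)
  write_tsv(long, out_path(config, "themes_long.tsv"))
  log(sprintf("themes: %d themed enrichment rows (q < %g)", nrow(long),
              config$thresholds$q))
}

stage_overlap <- function(config, log) {
  for (sp in config$species) {
    dag <- readOBO(config$inputs$obo,
                   readAnnotations(config$inputs$annotations[[sp]]))
    de <- readDETable(out_path(config, "de_", sp, ".tsv"))
    mode <- config$de_mode[[sp]]
    alpha <- if (mode == "q_threshold") config$thresholds$q else
      config$thresholds$p
    sets <- selectSignificant(de, mode, alpha)
    up_stripped <- unique(
      stripPseudogeneSuffix(sets$up, sp)$parent_symbol
    )
    ea <- suppressWarnings(goEnrichment(sets$down, dag,
                                        q_threshold = config$thresholds$q))
    eb <- suppressWarnings(goEnrichment(up_stripped, dag,
                                        q_threshold = config$thresholds$q))
    ov <- pathwayOverlap(ea, eb)
    write_tsv(ov$shared, out_path(config, "overlap_", sp, "_shared.tsv"))
    write_tsv(ov$only_a,
              out_path(config, "overlap_", sp, "_down_only.tsv"))
    write_tsv(ov$only_b, out_path(config, "overlap_", sp, "_up_only.tsv"))
    log(sprintf("overlap[%s]: %d shared, %d down-only, %d up-only terms",
                sp, nrow(ov$shared), nrow(ov$only_a), nrow(ov$only_b)))
  }
}

#' Run the configured pipeline
#'
#' Validates that every referenced input path exists, then executes the
#' enabled stages in dependency order, writing per-stage TSVs, a run log
#' and a JSON manifest (package version, seed, thresholds, input
#' checksums, stage timings). The run is a pure function of (config,
#' inputs): identical inputs give byte-identical TSV outputs.
#'
#' @param config a RunConfig from [runConfig()] or [readRunConfig()].
#' @return The manifest, invisibly.
#' @seealso [makeDemo()] for the all-synthetic end-to-end run.
#' @export
runPipeline <- function(config) {
  paths <- check_inputs(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  log(sprintf("thresholds: filter=%g p=%g q=%g",
              config$thresholds$filter, config$thresholds$p,
              config$thresholds$q))
  runners <- list(align = stage_align, de = stage_de,
                  families = stage_families, seednet = stage_seednet,
                  themes = stage_themes, overlap = stage_overlap)
  stages <- intersect(PIPELINE_STAGES, config$stages)
  timings <- list()
  for (st in stages) {
    t0 <- proc.time()[["elapsed"]]
    tryCatch(runners[[st]](config, log), error = function(e) {
      stop("stage '", st, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[st]] <- round(proc.time()[["elapsed"]] - t0, 3)
  }
  manifest <- list(
    package = "ribostress",
    version = as.character(packageVersion("ribostress")),
    seed = config$seed,
    thresholds = config$thresholds,
    stages_completed = stages,
    stage_seconds = timings,
    input_checksums = as.list(md5sum(paths))
  )
  write_json(manifest, out_path(config, "manifest.json"),
             auto_unbox = TRUE, pretty = TRUE, null = "null")
  writeLines(log_lines, out_path(config, "run.log"))
  invisible(manifest)
}

#' Generate every demo input file and the matching configuration
#'
#' Materialises the synthetic world on disk: composite reference (FASTA +
#' locus table) and error-free reads (FASTQ); per-species count and
#' metadata TSVs from the planted [demoDesign()]; family table, ortholog
#' map, OBO DAG, annotation TSVs and theme map from
#' [generateFixtures()].
#'
#' @param dir directory to populate.
#' @param seed master seed; per-generator seeds are small fixed offsets of
#'   it, so the whole input set is a pure function of `seed`.
#' @param nPerGroup samples per (sex, group) cell (default 20).
#' @return A RunConfig pointing at the generated files.
#' @export
writeDemoInputs <- function(dir, seed = 1L, nPerGroup = 20L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inp <- file.path(dir, "inputs")
  dir.create(inp, showWarnings = FALSE)

  ref <- generateCompositeReference(seed = seed + 11L)
  rs <- simulateReads(ref, read_len = 75L, depth_per_locus = 50L,
                      seed = seed + 12L)
  writeReferenceFasta(ref, file.path(inp, "reference.fa"))
  writeLociTable(ref, file.path(inp, "loci.tsv"))
  writeReadsFastq(rs$reads, file.path(inp, "reads.fq"))

  fx <- generateFixtures(seed = seed + 13L)
  writeFamilyTable(fx$families, file.path(inp, "families.tsv"))
  writeOrthologMap(fx$orthologs, file.path(inp, "orthologs.tsv"))
  writeOBO(fx$dags$mouse, file.path(inp, "go.obo"))
  writeThemeMap(fx$themes, file.path(inp, "themes.json"))

  counts <- meta <- ann <- list()
  for (i in seq_along(c("mouse", "human"))) {
    sp <- c("mouse", "human")[i]
    sim <- simulateCounts(demoDesign(sp, nPerGroup = nPerGroup,
                                     seed = seed + 20L + i))
    counts[[sp]] <- file.path(inp, paste0("counts_", sp, ".tsv"))
    meta[[sp]] <- file.path(inp, paste0("meta_", sp, ".tsv"))
    writeCountsTable(sim$se, counts[[sp]])
    writeSampleMeta(as.data.frame(colData(sim$se)), meta[[sp]])
    ann[[sp]] <- file.path(inp, paste0("annotations_", sp, ".tsv"))
    writeAnnotations(fx$annotations[[sp]], ann[[sp]])
  }

  runConfig(
    out_dir = file.path(dir, "results"),
    inputs = list(
      ref_fasta = file.path(inp, "reference.fa"),
      loci = file.path(inp, "loci.tsv"),
      reads = file.path(inp, "reads.fq"),
      counts = counts, meta = meta,
      families = file.path(inp, "families.tsv"),
      orthologs = file.path(inp, "orthologs.tsv"),
      obo = file.path(inp, "go.obo"),
      annotations = ann,
      themes = file.path(inp, "themes.json")
    ),
    seed = seed
  )
}

#' Run the all-synthetic end-to-end demo
#'
#' Generates every input with [writeDemoInputs()] and runs the full
#' pipeline. At the default toy scale a run takes well under a minute on
#' one CPU.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @param nPerGroup samples per (sex, group) cell.
#' @param align if `FALSE`, the read-assignment stage is skipped and the
#'   pipeline starts from the simulated count matrices.
#' @return Invisibly, a list with the `config`, the `manifest` and the key
#'   result tables read back from disk (`de`, `families`, `common_down`,
#'   `themes`).
#' @examples
#' \donttest{
#' demo <- makeDemo(file.path(tempdir(), "ribostress-demo"), seed = 1)
#' demo$common_down
#' }
#' @export
makeDemo <- function(dir = file.path(tempdir(), "ribostress-demo"),
                     seed = 1L, nPerGroup = 20L, align = TRUE) {
  config <- writeDemoInputs(dir, seed = seed, nPerGroup = nPerGroup)
  if (!align) config$stages <- setdiff(config$stages, "align")
  manifest <- runPipeline(config)
  res <- list(
    config = config, manifest = manifest,
    de = lapply(setNames(config$species, config$species), function(sp) {
      readDETable(out_path(config, "de_", sp, ".tsv"))
    }),
    families = lapply(setNames(config$species, config$species),
                      function(sp) {
      read_tsv(out_path(config, "families_", sp, ".tsv"))
    }),
    common_down = read_tsv(out_path(config, "common_down.tsv"))$gene,
    themes = read_tsv(out_path(config, "themes_long.tsv"))
  )
  invisible(res)
}
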