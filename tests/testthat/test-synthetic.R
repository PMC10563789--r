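## Synthetic-data generators: composite reference, reads, NB counts,
## fixtures.

test_that("pseudogene divergence is exactly the recorded substitutions", {
  ## divergence 0: byte-identical copies, empty truth
  ref0 <- generateCompositeReference(n_parents = 2, pseudos_per_parent = 1,
                                     divergence_rate = 0, seed = 5)
  seqs0 <- lociSeqs(ref0)
  expect_identical(as.character(seqs0[["RP01-ps1"]]),
                   as.character(seqs0[["RP01"]]))
  expect_true(all(lengths(truthDivergence(ref0)) == 0))

  ## divergence 0.05: Hamming distance oracle equals the truth record
  ref <- generateCompositeReference(n_parents = 3, pseudos_per_parent = 2,
                                    mrna_len = 600, divergence_rate = 0.05,
                                    seed = 11)
  seqs <- lociSeqs(ref)
  loci <- refLoci(ref)
  for (ps in names(truthDivergence(ref))) {
    parent <- S4Vectors::mcols(loci)$parent_of[
      S4Vectors::mcols(loci)$locus_id == ps]
    a <- strsplit(as.character(seqs[[parent]]), "")[[1]]
    b <- strsplit(as.character(seqs[[ps]]), "")[[1]]
    mismatch <- which(a != b)
    expect_identical(mismatch, truthDivergence(ref)[[ps]])
  }

  expect_error(generateCompositeReference(divergence_rate = 1.5),
               "divergence_rate")
})

test_that("reference generation is a pure function of (parameters, seed)", {
  r1 <- generateCompositeReference(seed = 42)
  r2 <- generateCompositeReference(seed = 42)
  expect_identical(as.character(refContigs(r1)), as.character(refContigs(r2)))
  expect_identical(truthDivergence(r1), truthDivergence(r2))
  r3 <- generateCompositeReference(seed = 43)
  expect_false(identical(as.character(refContigs(r1)),
                         as.character(refContigs(r3))))
})

test_that("simulated reads are exact substrings of their origin locus", {
  ref <- generateCompositeReference(seed = 7)
  seqs <- as.character(lociSeqs(ref))

  empty <- simulateReads(ref, read_len = 75, depth_per_locus = 0)
  expect_length(empty$reads, 0)
  expect_identical(nrow(empty$truth), 0L)

  rs <- simulateReads(ref, read_len = 75, depth_per_locus = 50, seed = 3)
  expect_length(rs$reads, 50 * length(seqs))
  expect_identical(names(rs$reads), rs$truth$read_id)
  found <- vapply(seq_along(rs$reads), function(i) {
    origin <- seqs[[rs$truth$locus_id[i]]]
    rd <- as.character(rs$reads[[i]])
    if (rs$truth$strand[i] == "-") rd <- rc_chr(rd)
    grepl(rd, origin, fixed = TRUE)
  }, logical(1))
  expect_true(all(found))

  expect_error(simulateReads(ref, read_len = 10000), "read_len")
})

test_that("null count simulation has mean observed log2FC near 0", {
  genes <- paste0("g", 1:20)
  est <- replicate(100, {
    d <- simDesign(genes = genes, nPerGroup = 20, sexes = "F",
                   covariates = numeric(0),
                   baseMeanLog = c(meanlog = log(200), sdlog = 0.5),
                   seed = sample.int(1e6, 1))
    sim <- simulateCounts(d)
    de <- deTest(normalizeLogCPM(assay(sim$se, "counts")),
                 colData(sim$se)$group)
    de$log2FC
  })
  expect_true(all(abs(rowMeans(est)) < 0.05))
})

test_that("planted log2FC of -1 is recovered within [-1.3, -0.7]", {
  genes <- paste0("g", 1:50)
  hits <- vapply(1:40, function(s) {
    d <- simDesign(genes = genes, nPerGroup = 20, sexes = "F",
                   planted = c(g1 = -1), covariates = numeric(0),
                   dispersion = 0.1,
                   baseMeanLog = c(meanlog = log(200), sdlog = 0.5),
                   seed = s)
    sim <- simulateCounts(d)
    de <- deTest(normalizeLogCPM(assay(sim$se, "counts")),
                 colData(sim$se)$group)
    lfc <- de$log2FC[de$gene == "g1"]
    lfc >= -1.3 && lfc <= -0.7
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("module members correlate with their seed with the given sign", {
  genes <- paste0("g", 1:30)
  mod <- list(list(seeds = "g1", members = c("g2", "g3"), sign = 1,
                   magnitude = 0.8, latent = "z"),
              list(seeds = character(0), members = "g4", sign = -1,
                   magnitude = 0.8, latent = "z"))
  res <- vapply(1:40, function(s) {
    d <- simDesign(genes = genes, nPerGroup = 20, sexes = "F",
                   modules = mod, covariates = numeric(0),
                   baseMeanLog = c(meanlog = log(200), sdlog = 0.5),
                   seed = s)
    X <- normalizeLogCPM(assay(simulateCounts(d)$se, "counts"))
    c(pos = cor(X["g1", ], X["g2", ], method = "spearman") > 0,
      neg = cor(X["g1", ], X["g4", ], method = "spearman") < 0)
  }, logical(2))
  expect_gte(mean(res["pos", ]), 0.95)
  expect_gte(mean(res["neg", ]), 0.95)
})

test_that("dispersion 0 degenerates to Poisson (variance/mean near 1)", {
  genes <- paste0("g", 1:50)
  d <- simDesign(genes = genes, nPerGroup = 20, sexes = "F",
                 dispersion = 0, libSizeRange = c(1e6, 1e6),
                 covariates = numeric(0), groups = c("control", "stress"),
                 baseMeanLog = c(meanlog = log(200), sdlog = 0.5),
                 seed = 9)
  cnt <- assay(simulateCounts(d)$se, "counts")
  ratio <- apply(cnt, 1, var) / rowMeans(cnt)
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("fixtures are a valid, rooted, deterministic world", {
  fx1 <- generateFixtures(seed = 2)
  fx2 <- generateFixtures(seed = 2)
  expect_identical(fx1$families, fx2$families)
  expect_identical(fx1$annotations, fx2$annotations)

  ## acyclicity is enforced at construction; validity must also hold
  expect_true(validObject(fx1$dags$mouse))
  ## every theme anchor exists in the DAG
  anchors <- unlist(lapply(fx1$themes, `[[`, "anchor_terms"))
  expect_true(all(anchors %in% goTerms(fx1$dags$mouse)$id))
  ## family table includes large and small RPG families
  expect_true(all(c("large_rpg", "small_rpg") %in% fx1$families$family_id))
  ## every annotated gene exists in the species universe
  expect_true(all(fx1$annotations$mouse$gene %in%
                    fx1$universes$mouse$genes))
  ## cyclic edges are rejected
  expect_error(
    goDag(data.frame(id = c("A", "B"), name = c("a", "b")),
          parents = list(A = "B", B = "A")),
    "cyclic"
  )
})
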