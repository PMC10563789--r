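## GO DAG operations, over-representation, themes, pathway overlap.

test_that("ancestor closure handles chains, diamonds and roots", {
  dag <- toy_dag()
  expect_identical(goAncestors(dag, "D"), character(0))    # root
  expect_identical(goAncestors(dag, "B"), "D")             # chain
  expect_setequal(goAncestors(dag, "A"), c("B", "C", "D")) # diamond, once
  expect_length(goAncestors(dag, "A"), 3)
  expect_error(goAncestors(dag, "Z"), "unknown term")

  ## brute-force BFS oracle over the diamond
  bfs <- function(term, parents) {
    seen <- character(0); frontier <- parents[[term]] %||% character(0)
    while (length(frontier)) {
      seen <- union(seen, frontier)
      frontier <- unique(unlist(lapply(frontier, function(t)
        parents[[t]] %||% character(0))))
      frontier <- setdiff(frontier, seen)
    }
    seen
  }
  parents <- list(A = c("B", "C"), B = "D", C = "D")
  for (t in c("A", "B", "C", "D")) {
    expect_setequal(goAncestors(dag, t), bfs(t, parents))
  }
})

test_that("annotation propagation reaches every ancestor", {
  ann <- data.frame(gene = c("x", "y", "z"), term = c("A", "A", "B"))
  dag <- toy_dag(ann)
  ## x annotated to leaf A counts for B, C and D too
  expect_setequal(dag@term2genes[["D"]], c("x", "y", "z"))
  expect_setequal(dag@term2genes[["B"]], c("x", "y", "z"))
  expect_setequal(dag@term2genes[["C"]], c("x", "y"))
  ## monotonicity: a term has at least as many genes as each child
  for (child in c("A", "B", "C")) {
    for (parent in goAncestors(dag, child)) {
      expect_gte(length(dag@term2genes[[parent]]),
                 length(dag@term2genes[[child]]))
    }
  }
})

test_that("GO enrichment ranks the fully recovered term first", {
  fx <- generateFixtures(seed = 4)
  dag <- fx$dags$mouse
  syn <- fx$universes$mouse$synapse
  enr <- goEnrichment(syn, dag, q_threshold = NULL)
  expect_identical(enr$term[1], "GO:0007268")
  expect_identical(enr$k[1], length(syn))
  expect_true(all(enr$q >= enr$p))

  ## p for a small toy case matches the enumeration oracle
  ann <- data.frame(gene = paste0("g", 1:8),
                    term = rep(c("A", "E"), each = 4))
  dag2 <- toy_dag(ann)
  enr2 <- goEnrichment(paste0("g", 1:4), dag2, q_threshold = NULL)
  for (i in seq_len(nrow(enr2))) {
    expect_equal(enr2$p[i],
                 hyper_enum_p(enr2$N[i], enr2$K[i], enr2$n[i], enr2$k[i]),
                 tolerance = 1e-12)
  }

  ## FDR filtering never retains q above the cutoff
  enr3 <- goEnrichment(syn, dag)
  expect_true(all(enr3$q < 0.05))
  expect_warning(goEnrichment(character(0), dag), "empty gene list")
})

test_that("theme assignment is total over keyword and DAG routes", {
  fx <- generateFixtures(seed = 4)
  dag <- fx$dags$mouse
  themes <- fx$themes
  ## keyword substring route
  expect_true("synapse" %in% assignThemes("GO:0007268", dag, themes))
  ## DAG descent route: innate immune response under the immune anchor
  expect_true("immune" %in% assignThemes("GO:0045087", dag, themes))
  ## multi-assignment: translation matches ribosome keyword and anchor
  expect_true("ribosome" %in% assignThemes("GO:0006412", dag, themes))
  ## no route matches -> unclassified, never empty
  expect_identical(assignThemes("GO:0007049", dag, themes),
                   "unclassified")
  ## a term matching two themes records both
  tm2 <- list(t1 = list(keywords = "synaptic", anchor_terms = character(0)),
              t2 = list(keywords = character(0),
                        anchor_terms = "GO:0099536"))
  expect_setequal(assignThemes("GO:0007268", dag, tm2), c("t1", "t2"))
})

test_that("signed theme matrix counts contributing seeds correctly", {
  ## universe of 60 genes; term A has 8 members
  ann <- data.frame(gene = paste0("g", 1:60),
                    term = c(rep("A", 8), rep("E", 52)))
  dag <- toy_dag(ann)
  themes <- list(leafy = list(keywords = "leaf",
                              anchor_terms = character(0)))
  ## 5 seeds: 3 whose negative lists contain all of term A's genes,
  ## 2 with unrelated singletons
  rows <- list()
  for (s in 1:3) {
    rows[[s]] <- data.frame(stratum = "st", seed = paste0("seed", s),
                            gene = paste0("g", 1:8), rho = -0.9,
                            p = 0.001, sign = "negative")
  }
  for (s in 4:5) {
    rows[[s]] <- data.frame(stratum = "st", seed = paste0("seed", s),
                            gene = paste0("g", 50 + s), rho = -0.5,
                            p = 0.01, sign = "negative")
  }
  net <- do.call(rbind, rows)
  stm <- signedThemeMatrix(net, dag, themes)
  rowA <- stm$table[stm$table$term == "A", ]
  expect_identical(nrow(rowA), 1L)
  expect_identical(rowA$contributing_seeds, 3L)
  expect_identical(rowA$sign, "negative")
  expect_identical(rowA$themes, "leafy")
  ## negative sign encodes as a negative matrix entry
  expect_lt(stm$matrix["A", "st|negative"], 0)
})

test_that("pathway overlap preserves each side's enrichment strength", {
  ea <- data.frame(term = c("T1", "T2", "T3", "T4", "T5"),
                   q = c(1e-4, 1e-3, 0.01, 0.02, 0.04))
  eb <- data.frame(term = c("T1", "T2", "T3", "T6", "T7"),
                   q = c(0.03, 0.01, 1e-5, 0.04, 0.02))
  ov <- pathwayOverlap(ea, eb)
  expect_identical(nrow(ov$shared), 3L)
  expect_identical(nrow(ov$only_a), 2L)
  expect_identical(nrow(ov$only_b), 2L)
  expect_equal(ov$shared$neglog_q_a[ov$shared$term == "T1"], 4)
  expect_equal(ov$shared$neglog_q_b[ov$shared$term == "T1"],
               -log10(0.03))
  ## identical tables share everything; disjoint tables share nothing
  same <- pathwayOverlap(ea, ea)
  expect_identical(nrow(same$only_a), 0L)
  expect_identical(nrow(same$only_b), 0L)
  disj <- pathwayOverlap(ea, data.frame(term = "TX", q = 0.01))
  expect_identical(nrow(disj$shared), 0L)
})
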