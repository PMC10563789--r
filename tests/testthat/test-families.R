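## Symbol harmonisation, suffix stripping, hypergeometric family overlap.

test_that("pseudogene suffixes strip to the parent symbol", {
  m <- stripPseudogeneSuffix(c("Rpl7a-ps3", "Rpl13a", "Gm-ps"), "mouse")
  expect_identical(m$parent_symbol, c("Rpl7a", "Rpl13a", "Gm"))
  expect_identical(m$is_pseudogene, c(TRUE, FALSE, TRUE))

  h <- stripPseudogeneSuffix(c("RPL36AAS1", "RPL13A", "GAS5"), "human")
  expect_identical(h$parent_symbol[1:2], c("RPL36A", "RPL13A"))
  ## pattern-only mode strips GAS5 too; the annotation-gated mode does not
  expect_true(h$is_pseudogene[3])
  h2 <- stripPseudogeneSuffix(c("RPL36AAS1", "GAS5"), "human",
                              known_pseudogenes = "RPL36AAS1")
  expect_identical(h2$parent_symbol, c("RPL36A", "GAS5"))
  expect_error(stripPseudogeneSuffix("", "mouse"), "empty")
})

test_that("symbol harmonisation: map precedence, case rule, dropping", {
  ## case convention both ways
  expect_identical(harmonizeSymbols(c("Rps29", "Rpl9"), from = "mouse"),
                   c("RPS29", "RPL9"))
  expect_identical(harmonizeSymbols("RPL9", from = "human"), "Rpl9")

  ## explicit map overrides the case rule
  map <- data.frame(mouse_symbol = "Gm12345", human_symbol = "RPL9P1")
  expect_identical(harmonizeSymbols(c("Gm12345", "Rps5"), "mouse", map),
                   c("RPL9P1", "RPS5"))

  ## many-to-many map rows are rejected with the offenders listed
  bad <- data.frame(mouse_symbol = c("A", "A"),
                    human_symbol = c("X", "Y"))
  expect_error(harmonizeSymbols("A", "mouse", bad), "A")

  ## disjoint target universe drops everything with a message
  expect_message(
    out <- harmonizeSymbols(c("Rps5", "Rpl9"), "mouse",
                            universe = c("OTHER1", "OTHER2")),
    "dropped")
  expect_identical(out, character(0))
})

test_that("hypergeometric overlap equals enumeration and Fisher", {
  ## worked value: N=10, K=5, n=5, k=5 -> 1/choose(10,5) = 1/252
  r <- familyOverlapTest(letters[1:5], letters[1:5], universe_size = 10)
  expect_equal(r$p, 1 / 252, tolerance = 1e-12)
  expect_identical(c(r$k, r$K, r$n, r$N), c(5L, 5L, 5L, 10L))

  ## k = 0 -> p = 1
  expect_equal(familyOverlapTest("zz", letters[1:4],
                                 universe_size = 10)$p, 1)

  ## random configurations vs enumeration oracle and fisher.test
  set.seed(3)
  for (i in 1:50) {
    N <- sample(5:12, 1)
    uni <- paste0("g", seq_len(N))
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    fam <- sample(uni, K)
    de <- sample(uni, n)
    r <- familyOverlapTest(de, fam, universe_size = N)
    expect_equal(r$p, hyper_enum_p(N, K, n, r$k), tolerance = 1e-12)
    tab <- matrix(c(r$k, r$K - r$k, r$n - r$k, N - r$K - r$n + r$k), 2)
    expect_equal(r$p, fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
    ## symmetry in the two sets at fixed N
    expect_equal(r$p, familyOverlapTest(fam, de, universe_size = N)$p,
                 tolerance = 1e-12)
  }
})

test_that("enrichment score matrix is capped -log10(q), monotone in q", {
  e1 <- data.frame(family = c("f1", "f2"), q = c(0.05, 1))
  e2 <- data.frame(family = c("f1", "f2"), q = c(1e-30, 0.5))
  m <- enrichmentScoreMatrix(list(a.up = e1, b.down = e2))
  expect_equal(m["a.up", "f1"], -log10(0.05), tolerance = 1e-12)
  expect_equal(m["a.up", "f2"], 0)
  expect_equal(m["b.down", "f1"], 10)  # capped
  ## monotone: smaller q never gives a smaller entry
  expect_true(m["b.down", "f1"] >= m["a.up", "f1"])
  expect_warning(
    enrichmentScoreMatrix(list(x = data.frame(family = "f", q = 0))),
    "capped")
})

test_that("cross-species intersection works in the human namespace", {
  expect_identical(crossSpeciesCommon(character(0), c("RPL9", "RPS5")),
                   character(0))
  expect_identical(crossSpeciesCommon(c("Rps29", "Rpl9", "Rpl36a"),
                                      c("RPL9", "RPS5", "RPS29")),
                   c("RPS29", "RPL9"))
  ## map-driven pseudogene pairing
  map <- data.frame(mouse_symbol = "Rpl3-ps1", human_symbol = "RPL3AS1")
  expect_identical(crossSpeciesCommon("Rpl3-ps1", "RPL3AS1", map),
                   "RPL3AS1")
})
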