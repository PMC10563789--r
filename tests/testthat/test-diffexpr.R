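## Filtering, normalisation, covariate adjustment, Welch testing, BH.

test_that("low-count filter removes mean <= threshold inclusively", {
  m <- rbind(zero = c(0, 0, 0, 0),
             exact5 = c(5, 5, 5, 5),
             six = c(6, 6, 6, 6))
  kept <- rownames(filterLowCounts(m))
  expect_identical(kept, "six")
  ## sum-reading behind the flag
  expect_identical(rownames(filterLowCounts(m, threshold = 20,
                                            stat = "sum")), "six")
  expect_warning(filterLowCounts(m, threshold = 100), "no genes")
})

test_that("log-CPM matches hand arithmetic and is scale invariant", {
  ## libsize 1e6 exactly; count 100 -> log2(101)
  m <- rbind(g1 = c(100, 0), g2 = c(1e6 - 100, 1e6))
  colnames(m) <- c("a", "b")
  X <- normalizeLogCPM(m)
  expect_equal(X["g1", "a"], log2(101), tolerance = 1e-12)
  expect_equal(X["g1", "b"], 0)

  ## doubling a sample's counts leaves CPM unchanged at pseudocount 0
  m2 <- m
  m2[, "a"] <- m2[, "a"] * 2
  expect_equal(normalizeLogCPM(m, pseudocount = 0),
               normalizeLogCPM(m2, pseudocount = 0))

  bad <- rbind(g1 = c(1, 0))
  colnames(bad) <- c("ok", "empty")
  expect_error(normalizeLogCPM(bad), "empty")
})

test_that("covariate adjustment is OLS residualisation", {
  set.seed(4)
  n <- 8
  age <- rnorm(n)
  ph <- rnorm(n)
  X <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:n)))
  X[1, ] <- 2 * age  # noiseless linear gene

  ## identity contract with no covariates
  expect_identical(covariateAdjust(X, NULL), X)

  adj <- covariateAdjust(X, data.frame(age = age, ph = ph))
  expect_lt(abs(cor(adj[1, ], age)), 1e-10)

  ## normal-equations oracle
  M <- cbind(1, age, ph)
  beta <- solve(t(M) %*% M, t(M) %*% t(X))
  expect_equal(adj, X - t(M %*% beta), tolerance = 1e-10)

  ## rank-deficient design names the collinear column
  expect_error(covariateAdjust(X, data.frame(age = age, age2 = 2 * age)),
               "age2")
})

test_that("Welch test matches the closed-form statistic", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  X <- rbind(g = c(x, y))
  g <- rep(c("control", "stress"), each = 4)
  de <- deTest(X, g)

  ## textbook Welch oracle
  se2 <- var(x) / 4 + var(y) / 4
  tt <- (mean(y) - mean(x)) / sqrt(se2)
  df <- se2^2 / ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3)
  expect_equal(de$log2FC, 1)
  expect_equal(de$p, 2 * pt(-abs(tt), df), tolerance = 1e-12)

  ## degenerate zero-variance: exact +1 shift -> smallest representable p
  X2 <- rbind(g = rep(c(0, 1), each = 4))
  expect_warning(de2 <- deTest(X2, g), "zero-variance")
  expect_identical(de2$p, .Machine$double.xmin)
  expect_identical(de2$log2FC, 1)

  expect_error(deTest(X, rep("control", 8)), "two levels")
  expect_error(deTest(X[, 1:5, drop = FALSE], g[1:5]), "at least 2")
})

test_that("null p-values are uniform (KS on 2,000 null genes)", {
  set.seed(99)
  X <- matrix(rnorm(2000 * 40), 2000, 40)
  g <- rep(c("control", "stress"), each = 20)
  de <- deTest(X, g)
  expect_gt(ks.test(de$p, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.1, NA)), "\\[0, 1\\]")

  set.seed(10)
  for (i in 1:200) {
    p <- runif(sample(1:200, 1))
    expect_equal(bhAdjust(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("significance selection honours the active threshold rule", {
  de <- data.frame(gene = c("a", "b", "c"),
                   log2FC = c(1, -2, 0),
                   p = c(0.049, 0.001, 0.001),
                   q = c(0.2, 0.01, 0.01))
  ## p-mode includes the p=0.049 gene despite q=0.2
  sp <- selectSignificant(de, "p_threshold")
  expect_identical(sp$up, "a")
  ## q-mode excludes it
  sq <- selectSignificant(de, "q_threshold")
  expect_identical(sq$up, character(0))
  expect_identical(sq$down, "b")
  ## zero log2FC genes join neither set
  expect_false("c" %in% c(sp$up, sp$down, sq$up, sq$down))
  ## empty table gives two empty sets
  se <- selectSignificant(de[0, ], "p_threshold")
  expect_identical(lengths(se), c(up = 0L, down = 0L))
})
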