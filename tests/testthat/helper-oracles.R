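## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: plain-string scanning instead of Biostrings
## matching, explicit enumeration instead of closed forms.

## all permutations of 1..n as rows (n! x n); cached per n
.perm_cache <- new.env(parent = emptyenv())
perm_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  pm <- if (n == 1L) {
    matrix(1L, 1, 1)
  } else {
    p <- perm_matrix(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
      cbind(k, ifelse(p >= k, p + 1L, p))
    }))
  }
  .perm_cache[[key]] <- pm
  pm
}

## exact two-sided permutation p for Spearman rho on tie-free vectors
spearman_perm_p <- function(x, y) {
  n <- length(x)
  P <- perm_matrix(n)
  rx <- rank(x)
  rho_obs <- cor(rx, rank(y))
  denom <- sum((seq_len(n) - mean(seq_len(n)))^2)
  rho_all <- (as.numeric(P %*% rx) - n * mean(seq_len(n)) * mean(rx)) /
    denom
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

## brute-force BH by its step-up definition: q(k) = min over i >= k of
## m * p(i) / i, in the order of sorted p
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, rev(cummin(rev(m * ps / seq_len(m)))))
  out <- numeric(m)
  out[o] <- q
  out
}

## exact hypergeometric upper tail by enumeration of the pmf
hyper_enum_p <- function(N, K, n, k) {
  js <- max(0L, n + K - N):min(n, K)
  js <- js[js >= k]
  if (length(js) == 0L) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

## plain-character reverse complement (no Biostrings)
rc_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

## naive both-strand exact scan of one read against named locus strings;
## returns the distinct loci containing the read
naive_read_loci <- function(read, locus_strings) {
  hit <- grepl(read, locus_strings, fixed = TRUE) |
    grepl(rc_chr(read), locus_strings, fixed = TRUE)
  names(locus_strings)[hit]
}

naive_status <- function(nhits) {
  if (nhits == 1L) "unique" else if (nhits >= 2L) "discarded_multilocus"
  else "unmapped"
}

## random ACGT string helper for fixtures built in tests
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## small GODag fixture: diamond A -> {B, C} -> D plus an isolated root E
toy_dag <- function(annotations = NULL) {
  goDag(
    data.frame(id = c("A", "B", "C", "D", "E"),
               name = c("leaf term", "left mid", "right mid",
                        "root term", "other root")),
    parents = list(A = c("B", "C"), B = "D", C = "D"),
    annotations = annotations
  )
}
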