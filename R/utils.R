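## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators are pure
#' functions of their arguments and never perturb the caller's RNG stream.
#'
#' @param seed integer scalar passed to [set.seed()].
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

## Random DNA string(s) of the given lengths.
random_dna <- function(lengths) {
  vapply(
    lengths,
    function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = ""),
    character(1)
  )
}

## Reverse complement of a plain character vector (ACGT only).
revcomp_chr <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

## Stop unless every character of every sequence is in {A,C,G,T}.
## `what` names the offending entity in the error message.
check_acgt <- function(seqs, what = "sequence") {
  af <- alphabetFrequency(DNAStringSet(seqs), baseOnly = TRUE)
  bad <- which(af[, "other"] > 0)
  if (length(bad) > 0) {
    nm <- names(seqs)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop(
      "non-ACGT characters in ", what, ": ",
      paste(utils::head(nm, 5), collapse = ", "),
      call. = FALSE
    )
  }
  invisible(TRUE)
}

## scalar assertion helpers --------------------------------------------------

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(name, " must be a single number in [", lower, ", ", upper, "]",
         call. = FALSE)
  }
  invisible(x)
}

## deterministic TSV writer used by all pipeline outputs
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
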