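# Internal helpers shared across modules. All coordinates inside the package
# are 0-based half-open; conversions happen only at format boundaries
# (GFF3 and RepeatMasker .out are 1-based closed, BED is 0-based half-open).

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorized, case-preserving in the sense that output is uppercase; used on
#' simulated reads and small oracle fixtures.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements (uppercase).
#' @examples
#' revcomp(c("ACGT", "AAAC"))
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgtN", "TGCATGCAN", x))
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Run code under a fully specified RNG state so identical seeds give
# byte-identical simulator output regardless of the session's RNG settings.
with_sim_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  set.seed(seed)
  force(code)
}

# Substitute errors into reads at a fixed per-base rate; only reads drawing at
# least one error are touched.
apply_read_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  rl <- nchar(seqs)
  n_err <- rbinom(length(seqs), rl, error_rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(rl[i], n_err[i])
    chars[pos] <- vapply(chars[pos], function(b) {
      sample(setdiff(DNA_BASES, toupper(b)), 1)
    }, character(1))
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

# Draw n non-overlapping interval start positions for blocks of the given
# lengths on [0, total): classic gap construction, uniform over arrangements.
place_nonoverlapping <- function(lengths, total) {
  n <- length(lengths)
  if (n == 0) return(integer(0))
  free <- total - sum(lengths)
  stopifnot(free >= 0)
  gaps <- sort(sample.int(free + 1, n, replace = TRUE) - 1L)
  gaps + cumsum(c(0L, lengths[-n]))
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

gc_fraction <- function(x) {
  stringi::stri_count_charclass(x, "[GCgc]") /
    pmax(1L, stringi::stri_count_charclass(x, "[ACGTacgt]"))
}
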