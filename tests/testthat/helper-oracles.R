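# Independent brute-force oracles and tiny fixture builders used across the
# suite. Oracles deliberately share no code with the implementation paths
# they check.

# enumerate every k-substring of every sequence, canonicalize by string
# comparison against the reverse complement, and tabulate
oracle_count_kmers <- function(seqs, k) {
  kmers <- unlist(lapply(seqs, function(s) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) return(character(0))
    subs <- substring(s, 1:(n - k + 1), k:n)
    subs[!grepl("[^ACGT]", subs)]
  }))
  if (length(kmers) == 0) {
    return(tibble::tibble(kmer = character(0), count = integer(0)))
  }
  rc <- chartr("ACGT", "TGCA", vapply(strsplit(kmers, ""), function(x) {
    paste(rev(x), collapse = "")
  }, character(1)))
  canon <- ifelse(kmers <= rc, kmers, rc)
  tab <- table(canon)
  tibble::tibble(kmer = names(tab), count = as.integer(tab))
}

# interval union through a per-base boolean array
oracle_merge <- function(hits, k, scaffold_length) {
  out <- list()
  for (sc in unique(hits$scaffold)) {
    covered <- logical(scaffold_length)
    for (s in hits$start[hits$scaffold == sc]) {
      covered[(s + 1):(s + k)] <- TRUE
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep)) {
      out[[sc]] <- tibble::tibble(scaffold = sc, start = starts[keep],
                                  end = ends[keep])
    }
  }
  dplyr::bind_rows(out)
}

# all-pairs overlap count of fixed-length reads vs gene intervals
oracle_gene_counts <- function(placements, genes, read_length) {
  vapply(seq_len(nrow(genes)), function(i) {
    sum(placements$scaffold == genes$scaffold[i] &
          placements$start < genes$end[i] &
          placements$start + read_length > genes$start[i])
  }, numeric(1))
}

random_reads <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

tiny_config <- function(...) {
  defaults <- list(n_autosomal_scaffolds = 1, n_x_scaffolds = 1,
                   n_y_scaffolds = 1,
                   scaffold_length_range = c(40000L, 40000L),
                   n_genes_per_scaffold = 3, mean_depth = 5,
                   female_library_scale = 1, seed = 7L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

truth_compartment <- function(sim) {
  setNames(sim$truth$scaffolds$compartment, sim$truth$scaffolds$scaffold)
}
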