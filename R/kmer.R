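# Fine-scale Y detection. Canonical 25-mers (lexicographic minimum of a
# k-mer and its reverse complement, collapsing the strand ambiguity of
# double-stranded sequencing) are counted per sexed library; k-mers seen in
# the male library but never in the female library are located on the
# assembly, merged into Y-unique regions, and summarized as density along
# chromosome-scale scaffolds in 1.8 Mb bins. K-mers are held as 2-bit codes
# in doubles (exact up to k = 26).

#' Count canonical k-mers in a read set
#'
#' Every length-k window of every read contributes one count to its
#' canonical form; windows containing non-ACGT symbols are skipped.
#'
#' @param readset a \code{read_set}, a read tibble, or a character vector of
#'   sequences.
#' @param k k-mer length (default 25).
#' @return a \code{kmer_table}: list with \code{k} and \code{counts}, a
#'   tibble of \code{code} (numeric 2-bit encoding) and \code{count}.
#' @examples
#' count_kmers("ACGTA", k = 4)$counts
#' @export
count_kmers <- function(readset, k = 25) {
  seqs <- if (inherits(readset, "read_set")) readset$reads$seq
          else if (is.data.frame(readset)) readset$seq
          else readset
  counts <- as_tibble(cpp_count_kmers(seqs, as.integer(k)))
  structure(list(k = as.integer(k), counts = counts), class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("<kmer_table> k=%d, %s distinct canonical k-mers, %s total\n",
              x$k, format(nrow(x$counts), big.mark = ","),
              format(sum(x$counts$count), big.mark = ",")))
  invisible(x)
}

#' Decode canonical k-mer codes to sequences
#'
#' @param table a \code{kmer_table}, or a numeric code vector (then `k` is
#'   required).
#' @param k k-mer length.
#' @return character vector of k-mers.
#' @export
decode_kmers <- function(table, k = NULL) {
  if (inherits(table, "kmer_table")) {
    cpp_decode_kmers(table$counts$code, table$k)
  } else {
    cpp_decode_kmers(table, k)
  }
}

#' Canonical form of k-mer strings
#'
#' @param kmers character vector, all of one length.
#' @return the lexicographically smaller of each k-mer and its reverse
#'   complement.
#' @export
canonical_kmers <- function(kmers) {
  rc <- revcomp(toupper(kmers))
  pmin(toupper(kmers), rc)
}

#' Male-unique k-mers
#'
#' K-mers with male count at least \code{min_male_count} and female count
#' exactly \code{max_female_count} (default 0: strictly absent from the
#' female library). The male count floor (default 2) drops singleton
#' sequencing-error k-mers; 1 reproduces the literal "present in male"
#' reading.
#'
#' @param male,female \code{kmer_table}s with the same k.
#' @param min_male_count minimum male count (default 2).
#' @param max_female_count maximum female count (default 0).
#' @return a \code{kmer_set}: list with \code{k} and sorted numeric
#'   \code{codes}.
#' @export
male_unique <- function(male, female, min_male_count = 2,
                        max_female_count = 0) {
  if (male$k != female$k) abort("k-mer tables have different k")
  keep <- male$counts$count >= min_male_count
  codes <- male$counts$code[keep]
  if (max_female_count == 0) {
    codes <- codes[!(codes %in% female$counts$code)]
  } else {
    fc <- female$counts$count[match(codes, female$counts$code)]
    codes <- codes[is.na(fc) | fc <= max_female_count]
  }
  structure(list(k = male$k, codes = sort(codes)), class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("<kmer_set> k=%d, %s k-mers\n", x$k,
              format(length(x$codes), big.mark = ",")))
  invisible(x)
}

#' Locate k-mers on an assembly
#'
#' Reports every exact occurrence of each k-mer on either strand (each
#' assembly window is canonicalized before lookup) as a forward-strand start
#' coordinate. Matching is case-insensitive: soft-masking is ignored here.
#'
#' @param kmer_set a \code{kmer_set} from [male_unique()].
#' @param assembly named character vector of scaffold sequences.
#' @return tibble with \code{scaffold} and \code{start} (0-based), sorted.
#' @export
locate_kmers <- function(kmer_set, assembly) {
  hits <- cpp_locate_kmers(unname(assembly), kmer_set$k, kmer_set$codes)
  out <- tibble(scaffold = names(assembly)[hits$seq_idx],
                start = as.integer(hits$start))
  arrange(out, .data$scaffold, .data$start)
}

#' Merge k-mer hits into Y-unique regions
#'
#' Each hit spans \code{[start, start + k)}; spans that overlap or lie
#' within \code{max_gap} of one another are unioned (gap 0 merges only
#' overlapping/abutting spans, the bedtools-merge default). Every region has
#' length >= k.
#'
#' @param hits tibble from [locate_kmers()].
#' @param k k-mer length (default 25).
#' @param max_gap maximum gap bridged when merging (default 0).
#' @return tibble with \code{scaffold}, \code{start}, \code{end},
#'   \code{n_kmers}; regions per scaffold are disjoint and sorted.
#' @export
merge_y_regions <- function(hits, k = 25, max_gap = 0) {
  if (nrow(hits) == 0) {
    return(tibble(scaffold = character(0), start = integer(0),
                  end = integer(0), n_kmers = integer(0)))
  }
  hits <- arrange(hits, .data$scaffold, .data$start)
  hits |>
    group_by(.data$scaffold) |>
    mutate(
      span_end = as.numeric(.data$start + k),
      new_run = .data$start > dplyr::lag(cummax(.data$span_end),
                                         default = -Inf) + max_gap,
      run = cumsum(.data$new_run)
    ) |>
    group_by(.data$scaffold, .data$run) |>
    summarise(start = as.integer(min(.data$start)),
              end = as.integer(max(.data$span_end)),
              n_kmers = dplyr::n(), .groups = "drop") |>
    select("scaffold", "start", "end", "n_kmers") |>
    arrange(.data$scaffold, .data$start)
}

#' Density of Y-unique regions along scaffolds
#'
#' Tiles each scaffold into non-overlapping bins (default 1.8 Mb, the
#' chromosome-scale summary window). \code{n_regions} counts regions by the
#' bin containing their midpoint; \code{n_bases} apportions region bases
#' exactly to the bins that contain them.
#'
#' @param regions tibble from [merge_y_regions()].
#' @param assembly named character vector (or a lengths tibble).
#' @param bin bin width in bp (default 1,800,000).
#' @return tibble with \code{scaffold}, \code{start}, \code{end},
#'   \code{n_regions}, \code{n_bases}.
#' @export
density_track <- function(regions, assembly, bin = 1800000) {
  bins <- tile_windows(assembly, window_size = bin) |>
    select("scaffold", "start", "end") |>
    mutate(n_regions = 0L, n_bases = 0)
  if (nrow(regions) > 0) {
    mid_bin <- paste(regions$scaffold,
                     ((regions$start + regions$end) %/% 2) %/% bin,
                     sep = "\r")
    key <- paste(bins$scaffold, bins$start %/% bin, sep = "\r")
    tab <- table(mid_bin)
    hit <- match(names(tab), key)
    bins$n_regions[hit[!is.na(hit)]] <-
      as.integer(tab[!is.na(hit)])
    for (i in seq_len(nrow(regions))) {
      rows <- which(bins$scaffold == regions$scaffold[i] &
                      bins$start < regions$end[i] &
                      bins$end > regions$start[i])
      ov <- pmin(bins$end[rows], regions$end[i]) -
        pmax(bins$start[rows], regions$start[i])
      bins$n_bases[rows] <- bins$n_bases[rows] + ov
    }
  }
  bins
}
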