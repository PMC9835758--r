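# Coverage module: tile scaffolds into non-overlapping 10 kb windows, place
# reads (internal exact placer or external BAM), and summarize per-window
# RPKM and per-gene read counts.

#' Tile an assembly into non-overlapping windows
#'
#' Windows tile each scaffold completely; the final window of a scaffold may
#' be shorter and is flagged \code{partial}.
#'
#' @param assembly named character vector of sequences, a \code{sexscan_sim},
#'   or a tibble from [assembly_lengths()].
#' @param window_size window size in bp (default 10000, the region-CQ scale).
#' @return tibble with \code{scaffold}, \code{start}, \code{end} (0-based
#'   half-open), \code{index} (ordinal within scaffold), \code{width},
#'   \code{partial}.
#' @examples
#' tile_windows(c(s1 = strrep("A", 25000)))
#' @export
tile_windows <- function(assembly, window_size = 10000) {
  stopifnot(window_size >= 1)
  lens <- if (is.data.frame(assembly)) assembly else assembly_lengths(assembly)
  out <- lapply(seq_len(nrow(lens)), function(i) {
    L <- as.integer(lens$length[i])
    starts <- as.integer(seq(0L, L - 1L, by = window_size))
    tibble(scaffold = lens$scaffold[i], start = starts,
           end = as.integer(pmin(starts + window_size, L)),
           index = seq_along(starts))
  })
  out <- mutate(bind_rows(out), width = .data$end - .data$start,
                partial = .data$width < window_size)
  attr(out, "window_size") <- window_size
  out
}

#' Place reads on an assembly with an exact seed-indexed matcher
#'
#' Each read is searched, forward and reverse-complement, for exact matches
#' against the assembly via an index of seed k-mers (case-insensitive, so
#' soft-masked bases participate; repeat handling happens through the
#' uniqueness policy). Reads with exactly one best location are
#' \code{unique}, more than one \code{ambiguous}, none \code{unmapped}. Reads
#' with simulated errors fall back to the seed-anchored location when at
#' least \code{min_identity} of bases match. Under the default policy only
#' unique placements are retained for coverage; \code{"random"} retains
#' ambiguous reads at one of their best locations, chosen with the session
#' RNG.
#'
#' @param readset a \code{read_set} or a tibble with \code{read_id},
#'   \code{seq}.
#' @param assembly named character vector of scaffold sequences.
#' @param policy \code{"unique"} (default) or \code{"random"}.
#' @param min_identity identity threshold for the errored-read fallback
#'   (default 0.95).
#' @param seed_length exact seed length for the index (default 31).
#' @return tibble with \code{read_id}, \code{scaffold}, \code{start} (0-based),
#'   \code{strand}, \code{n_best}, \code{status} (unique/ambiguous/unmapped)
#'   and \code{retained}.
#' @export
place_reads <- function(readset, assembly, policy = c("unique", "random"),
                        min_identity = 0.95, seed_length = 31) {
  policy <- match.arg(policy)
  reads <- if (inherits(readset, "read_set")) readset$reads else readset
  if (length(assembly) == 0 || all(nchar(assembly) == 0)) {
    abort("cannot index an empty assembly")
  }
  if (any(nchar(reads$seq) > min(nchar(assembly)))) {
    warn("some reads are longer than the shortest scaffold")
  }
  res <- cpp_place_reads(reads$seq, unname(assembly), as.integer(seed_length),
                         min_identity, policy == "random")
  status <- dplyr::case_when(res$n_best == 0 ~ "unmapped",
                             res$n_best == 1 ~ "unique",
                             TRUE ~ "ambiguous")
  out <- tibble(
    read_id = reads$read_id,
    scaffold = names(assembly)[res$scaf_idx],
    start = res$start,
    strand = c("-", NA, "+")[res$strand + 2L],
    n_best = res$n_best,
    mismatches = res$mismatches,
    status = status,
    retained = status == "unique" | (policy == "random" &
                                       status == "ambiguous")
  )
  attr(out, "read_length") <- as.integer(max(nchar(reads$seq), 0))
  out
}

#' Load placements from a coordinate-sorted BAM/SAM file
#'
#' Primary alignments with \code{MAPQ >= min_mapq} become unique placements;
#' mapped records below the threshold are ambiguous, unmapped records
#' unmapped. Secondary and supplementary alignments are dropped.
#'
#' @param path BAM (or plain SAM, converted on the fly) file.
#' @param min_mapq MAPQ threshold for unique placements (default 20, a
#'   conventional unique-mapping proxy).
#' @param assembly optional named character vector; reference names are
#'   checked against it.
#' @return placement tibble as from [place_reads()].
#' @export
load_alignments <- function(path, min_mapq = 20, assembly = NULL) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  prm <- Rsamtools::ScanBamParam(
    flag = flags, what = c("qname", "rname", "pos", "strand", "mapq", "flag"))
  b <- Rsamtools::scanBam(path, param = prm)[[1]]
  if (length(b$qname) == 0) {
    return(tibble(read_id = character(0), scaffold = character(0),
                  start = integer(0), strand = character(0),
                  n_best = integer(0), mismatches = integer(0),
                  status = character(0), retained = logical(0)))
  }
  if (!is.null(assembly)) {
    refs <- unique(as.character(b$rname[!is.na(b$pos)]))
    bad <- setdiff(refs, names(assembly))
    if (length(bad) > 0) {
      abort("BAM reference names absent from assembly: ",
            paste(bad, collapse = ", "))
    }
  }
  mapped <- !is.na(b$pos)
  status <- dplyr::case_when(
    !mapped ~ "unmapped",
    b$mapq >= min_mapq ~ "unique",
    TRUE ~ "ambiguous"
  )
  tibble(
    read_id = b$qname,
    scaffold = ifelse(mapped, as.character(b$rname), NA_character_),
    start = ifelse(mapped, b$pos - 1L, NA_integer_),
    strand = ifelse(mapped, as.character(b$strand), NA_character_),
    n_best = ifelse(!mapped, 0L, ifelse(status == "unique", 1L, 2L)),
    mismatches = NA_integer_,
    status = status,
    retained = status == "unique"
  )
}

#' Per-window normalized coverage (RPKM)
#'
#' A read is assigned to the window containing its start coordinate.
#' \code{RPKM = count / ((window length / 1000) * (library_size / 1e6))}.
#'
#' @param placements placement tibble; only rows with \code{retained = TRUE}
#'   (or all rows if that column is absent) are counted.
#' @param windows tibble from [tile_windows()].
#' @param library_size mapped-library size for normalization; defaults to the
#'   number of retained placements.
#' @param sex optional label stored on the result.
#' @return the windows tibble with \code{count} and \code{rpkm} columns (and
#'   a \code{library_size}/\code{sex} attribute).
#' @export
window_rpkm <- function(placements, windows, library_size = NULL,
                        sex = NULL) {
  if ("retained" %in% names(placements)) {
    placements <- dplyr::filter(placements, .data$retained)
  }
  library_size <- library_size %||% nrow(placements)
  if (library_size <= 0) abort("library_size must be > 0")
  wsize <- attr(windows, "window_size") %||% max(windows$width)
  idx <- match(
    paste(placements$scaffold, pmin(placements$start %/% wsize + 1L,
                                    ave_max_index(windows)[placements$scaffold]),
          sep = "\r"),
    paste(windows$scaffold, windows$index, sep = "\r"))
  counts <- tabulate(idx, nbins = nrow(windows))
  out <- mutate(windows, count = counts,
                rpkm = counts / ((.data$width / 1000) * (library_size / 1e6)))
  attr(out, "library_size") <- library_size
  attr(out, "sex") <- sex
  out
}

# max window index per scaffold, as a named vector (reads starting inside the
# final partial window belong to it)
ave_max_index <- function(windows) {
  mx <- vapply(split(windows$index, windows$scaffold), max, numeric(1))
  mx
}

#' Count reads overlapping gene intervals
#'
#' A read counts for a gene if its placement interval overlaps the gene
#' interval by at least 1 bp; a read spanning two genes counts for both, but
#' at most once per gene.
#'
#' @param placements placement tibble (retained rows are counted).
#' @param genes tibble with \code{gene_id}, \code{scaffold}, \code{start},
#'   \code{end} (0-based half-open).
#' @param read_length read length used for the placement interval; defaults
#'   to the modal mapped read length inferred from placements if absent, else
#'   must be given.
#' @param library_size library size stored alongside the counts; defaults to
#'   the number of retained placements.
#' @param assembly optional named character vector; genes on scaffolds absent
#'   from it trigger a warning (they still get zero counts).
#' @return tibble with \code{gene_id}, \code{scaffold}, \code{start},
#'   \code{end}, \code{count}, \code{library_size}.
#' @export
count_gene_reads <- function(placements, genes, read_length = NULL,
                             library_size = NULL, assembly = NULL) {
  if ("retained" %in% names(placements)) {
    placements <- dplyr::filter(placements, .data$retained)
  }
  library_size <- library_size %||% nrow(placements)
  read_length <- read_length %||% attr(placements, "read_length") %||% 100L
  if (!is.null(assembly)) {
    missing <- setdiff(unique(genes$scaffold), names(assembly))
    if (length(missing) > 0) {
      warn(paste0("genes on scaffolds absent from the assembly get zero ",
                  "counts: ", paste(missing, collapse = ", ")))
    }
  }
  counts <- integer(nrow(genes))
  if (nrow(placements) > 0 && nrow(genes) > 0) {
    q <- GenomicRanges::GRanges(
      placements$scaffold,
      IRanges::IRanges(start = placements$start + 1L, width = read_length))
    s <- GenomicRanges::GRanges(
      genes$scaffold, IRanges::IRanges(start = genes$start + 1L,
                                       end = genes$end))
    # differing seqlevel sets between reads and genes are expected
    hits <- suppressWarnings(GenomicRanges::countOverlaps(s, q,
                                                          minoverlap = 1L))
    counts <- as.integer(hits)
  }
  tibble(gene_id = genes$gene_id, scaffold = genes$scaffold,
         start = genes$start, end = genes$end, count = counts,
         library_size = library_size)
}
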