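# Format boundaries. Soft-masking (lowercase) is semantic throughout, so
# FASTA is read with seqinr (which preserves case) and written by a small
# case-preserving 60-column writer. GFF3/BED go through rtracklayer; the
# package is 0-based half-open internally, GFF3 is 1-based closed.

#' Read a (possibly soft-masked) FASTA assembly
#'
#' @param path FASTA file.
#' @return named character vector of sequences, case preserved.
#' @export
read_fasta <- function(path) {
  x <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  setNames(vapply(x, as.character, character(1)), names(x))
}

#' Write a FASTA file, preserving soft-masking
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    L <- nchar(seqs[[i]])
    if (L > 0) {
      starts <- seq(1L, L, by = width)
      writeLines(substring(seqs[[i]], starts, pmin(starts + width - 1L, L)),
                 con)
    }
  }
  invisible(path)
}

#' Write a read set as FASTQ (Phred+33, constant quality "I")
#'
#' @param readset a \code{read_set} or a tibble with \code{read_id},
#'   \code{seq}.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(readset, path) {
  reads <- if (inherits(readset, "read_set")) readset$reads else readset
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    rec <- rbind(paste0("@", reads$read_id), reads$seq, "+",
                 strrep("I", nchar(reads$seq)))
    writeLines(as.vector(rec), con)
  }
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ file.
#' @param sex optional label attached to the returned \code{read_set}.
#' @return a \code{read_set}.
#' @export
read_fastq <- function(path, sex = "unknown") {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  reads <- tibble(read_id = names(x), seq = unname(as.character(x)))
  structure(list(sex = sex, reads = reads, library_size = nrow(reads)),
            class = "read_set")
}

#' Write gene intervals as GFF3
#'
#' @param genes tibble with \code{gene_id}, \code{scaffold}, \code{start},
#'   \code{end} (0-based half-open).
#' @param path output file.
#' @param scaffold_lengths optional tibble from [assembly_lengths()] used for
#'   sequence-region pragmas.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, scaffold_lengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$scaffold,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = "+"
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$Name <- genes$gene_id
  if (!is.null(scaffold_lengths)) {
    lens <- setNames(scaffold_lengths$length, scaffold_lengths$scaffold)
    GenomeInfoDb::seqlevels(gr) <- names(lens)
    GenomeInfoDb::seqlengths(gr) <- lens
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene intervals from GFF3
#'
#' Keeps \code{gene} features (or everything, if no type column), converting
#' to the package's 0-based half-open coordinates.
#'
#' @param path GFF3 file.
#' @return tibble with \code{gene_id}, \code{scaffold}, \code{start},
#'   \code{end}.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    keep <- as.character(gr$type) == "gene"
    if (any(keep)) gr <- gr[keep]
  }
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$ID)
  } else {
    sprintf("gene_%d", seq_along(gr))
  }
  tibble(
    gene_id = ids,
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals tibble with \code{scaffold}, \code{start}, \code{end} and
#'   optionally \code{name}.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(chrom = intervals$scaffold,
                   start = format(intervals$start, scientific = FALSE,
                                  trim = TRUE),
                   end = format(intervals$end, scientific = FALSE,
                                trim = TRUE),
                   name = intervals$name %||%
                     sprintf("iv_%d", seq_len(nrow(intervals))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

write_tsv_plain <- function(tbl, path) {
  write.table(as.data.frame(tbl), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  as_tibble(read.table(path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE, comment.char = ""))
}

#' Write a simulation fixture to disk
#'
#' Emits the soft-masked assembly FASTA, one FASTQ per read set, the gene
#' models as GFF3, truth intervals as BED, and machine-readable truth tables
#' as TSV.
#'
#' @param sim a \code{sexscan_sim}.
#' @param readsets named list of \code{read_set}s (names become file stems;
#'   conventionally \code{female}, \code{male}).
#' @param out_dir output directory (created if needed).
#' @param force overwrite existing files (default FALSE: refuses).
#' @return tibble manifest with \code{what} and \code{path}.
#' @export
write_fixture <- function(sim, readsets = list(), out_dir, force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    assembly = file.path(out_dir, "assembly.fa"),
    genes = file.path(out_dir, "genes.gff3"),
    truth_scaffolds = file.path(out_dir, "truth_scaffolds.tsv"),
    truth_genes = file.path(out_dir, "truth_genes.tsv"),
    truth_repeats = file.path(out_dir, "truth_repeats.bed"),
    truth_injections = file.path(out_dir, "truth_injections.bed"),
    truth_flanks = file.path(out_dir, "truth_flanks.tsv")
  )
  if (length(readsets) > 0) {
    fq <- setNames(file.path(out_dir, sprintf("reads_%s.fastq",
                                              names(readsets))),
                   paste0("reads_", names(readsets)))
    paths <- c(paths, fq)
  }
  if (!force && any(file.exists(paths))) {
    abort("fixture files already exist; use force = TRUE to overwrite")
  }
  write_fasta(sim$assembly, paths[["assembly"]])
  write_gff3(sim$truth$genes, paths[["genes"]],
             assembly_lengths(sim$assembly))
  write_tsv_plain(sim$truth$scaffolds, paths[["truth_scaffolds"]])
  write_tsv_plain(sim$truth$genes, paths[["truth_genes"]])
  write_bed(mutate(sim$truth$repeats, name = .data$class),
            paths[["truth_repeats"]])
  write_bed(mutate(sim$truth$injections,
                   name = sprintf("y_injection_%d", dplyr::row_number())),
            paths[["truth_injections"]])
  write_tsv_plain(sim$truth$flanks, paths[["truth_flanks"]])
  for (nm in names(readsets)) {
    write_fastq(readsets[[nm]], paths[[paste0("reads_", nm)]])
  }
  tibble(what = names(paths), path = unname(paths))
}
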