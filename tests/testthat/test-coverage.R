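test_that("windows tile scaffolds completely, keeping partial tails", {
  w <- tile_windows(c(s1 = strrep("A", 25000)))
  expect_identical(w$start, c(0L, 10000L, 20000L))
  expect_identical(w$end, c(10000L, 20000L, 25000L))
  expect_identical(w$partial, c(FALSE, FALSE, TRUE))

  w1 <- tile_windows(c(s1 = strrep("A", 10000)))
  expect_identical(nrow(w1), 1L)
  expect_false(w1$partial)

  w2 <- tile_windows(c(s1 = strrep("A", 9999)))
  expect_identical(nrow(w2), 1L)
  expect_true(w2$partial)
  expect_identical(w2$end, 9999L)

  # property: tiling partitions [0, length) for arbitrary lengths
  for (L in c(10001, 34567, 100000)) {
    w <- tile_windows(tibble::tibble(scaffold = "s", length = L))
    expect_identical(w$start, c(0L, head(w$end, -1)))
    expect_identical(max(w$end), as.integer(L))
    expect_true(all(w$width > 0))
  }
})

test_that("RPKM follows count / (kb * millions of mapped reads)", {
  w <- tile_windows(tibble::tibble(scaffold = "s", length = 15000))
  pl <- tibble::tibble(
    read_id = sprintf("r%d", 1:200),
    scaffold = "s",
    start = c(rep(0L, 100), rep(10000L, 100)),
    retained = TRUE
  )
  track <- window_rpkm(pl, w, library_size = 1e6)
  expect_equal(track$rpkm[1], 10)  # 100 / (10 * 1)
  expect_equal(track$rpkm[2], 20)  # partial 5 kb window: 100 / (5 * 1)
  # zero reads
  empty <- window_rpkm(pl[0, ], w, library_size = 10)
  expect_equal(empty$rpkm, c(0, 0))
  expect_error(window_rpkm(pl[0, ], w), "library_size")
  # scale invariance: doubling counts and library leaves RPKM unchanged
  track2 <- window_rpkm(dplyr::bind_rows(pl, pl), w, library_size = 2e6)
  expect_equal(track2$rpkm, track$rpkm)
})

test_that("window counts conserve retained placements", {
  sim <- simulate_assembly(tiny_config())
  pl <- place_reads(simulate_reads(sim, "male"), sim$assembly)
  w <- tile_windows(sim$assembly)
  track <- window_rpkm(pl, w)
  expect_identical(sum(track$count), sum(pl$retained))
})

test_that("error-free unique placements reproduce the encoded origins", {
  sim <- simulate_assembly(tiny_config(repeat_fraction = 0))
  rs <- simulate_reads(sim, "male")
  pl <- place_reads(rs, sim$assembly)
  origins <- parse_read_origin(pl$read_id)
  L <- setNames(nchar(sim$assembly), names(sim$assembly))
  interior <- origins$pos >= 0 &
    origins$pos + sim$config$read_length <= L[origins$source]
  # every interior read is placed uniquely at its origin
  expect_true(all(pl$status[interior] == "unique"))
  expect_identical(pl$scaffold[interior], origins$source[interior])
  expect_identical(pl$start[interior], origins$pos[interior])
  expect_identical(pl$strand[interior], origins$strand[interior])
  # flank-overlapping reads carry context absent from the assembly
  expect_true(all(pl$status[!interior] == "unmapped"))
})

test_that("repeat-copy reads are ambiguous and excluded by default", {
  locus <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                 collapse = "")
  filler1 <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                   collapse = "")
  filler2 <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                   collapse = "")
  asm <- c(s1 = paste0(filler1, locus), s2 = paste0(locus, filler2))
  reads <- tibble::tibble(read_id = c("dup", "uniq"),
                          seq = c(substr(locus, 101, 200),
                                  substr(filler1, 1, 100)))
  pl <- place_reads(reads, asm)
  expect_identical(pl$status, c("ambiguous", "unique"))
  expect_identical(pl$retained, c(FALSE, TRUE))
  expect_identical(pl$n_best[1], 2L)
  # random-best policy retains the ambiguous read at one of its loci
  plr <- place_reads(reads, asm, policy = "random")
  expect_true(all(plr$retained))
})

test_that("errored reads fall back to the seed-anchored locus", {
  sim <- simulate_assembly(tiny_config(repeat_fraction = 0))
  asm <- sim$assembly
  read <- substr(asm[["autosome_1"]], 5001, 5100)
  mutate_at <- function(s, pos) {
    for (p in pos) {
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 toupper(substr(s, p, p)))[1]
    }
    s
  }
  ok <- mutate_at(read, c(40, 60, 80))       # 3% divergence: placeable
  bad <- mutate_at(read, seq(35, 98, by = 7)) # ~10%: below 95% identity
  pl <- place_reads(tibble::tibble(read_id = c("ok", "bad"),
                                   seq = c(ok, bad)), asm)
  expect_identical(pl$status, c("unique", "unmapped"))
  expect_identical(pl$start[1], 5000L)
  expect_identical(pl$mismatches[1], 3L)
})

test_that("placements agree with a Biostrings exact-match oracle", {
  sim <- simulate_assembly(tiny_config(repeat_fraction = 0, seed = 21))
  rs <- simulate_reads(sim, "male")
  idx <- seq_len(min(50, nrow(rs$reads)))
  pl <- place_reads(rs$reads[idx, ], sim$assembly)
  subjects <- Biostrings::DNAStringSet(toupper(sim$assembly))
  for (i in idx) {
    hits <- 0L; where <- NULL
    for (q in c(rs$reads$seq[i], revcomp(rs$reads$seq[i]))) {
      m <- Biostrings::vmatchPattern(q, subjects)
      hits <- hits + sum(lengths(m))
      if (sum(lengths(m)) > 0) {
        sc <- which(lengths(m) > 0)[1]
        where <- c(names(sim$assembly)[sc],
                   Biostrings::startIndex(m)[[sc]][1] - 1L)
      }
    }
    if (hits == 1) {
      expect_identical(pl$status[i], "unique")
      expect_identical(pl$scaffold[i], where[[1]])
      expect_identical(pl$start[i], as.integer(where[[2]]))
    } else if (hits == 0) {
      expect_identical(pl$status[i], "unmapped")
    }
  }
})

test_that("SAM/BAM loading respects MAPQ and alignment flags", {
  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:s1\tLN:10000",
    paste("r1", 0, "s1", 101, 0, "50M", "*", 0, 0, strrep("A", 50),
          strrep("I", 50), sep = "\t"),
    paste("r2", 0, "s1", 201, 30, "50M", "*", 0, 0, strrep("A", 50),
          strrep("I", 50), sep = "\t"),
    paste("r3", 16, "s1", 301, 60, "50M", "*", 0, 0, strrep("A", 50),
          strrep("I", 50), sep = "\t"),
    paste("r4", 256, "s1", 401, 60, "50M", "*", 0, 0, strrep("A", 50),
          strrep("I", 50), sep = "\t")  # secondary: dropped
  )
  path <- tempfile(fileext = ".sam")
  writeLines(sam, path)
  pl <- load_alignments(path, min_mapq = 20)
  expect_identical(nrow(pl), 3L)            # secondary excluded
  expect_identical(sum(pl$status == "unique"), 2L)
  expect_identical(pl$start[pl$read_id == "r2"], 200L)
  expect_identical(pl$strand[pl$read_id == "r3"], "-")
  expect_error(load_alignments(path, assembly = c(other = "ACGT")),
               "reference names")
  # empty SAM
  empty <- tempfile(fileext = ".sam")
  writeLines(sam[1:2], empty)
  expect_identical(nrow(load_alignments(empty)), 0L)
})

test_that("gene read counts match the quadratic overlap oracle", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    scaffold = c("s1", "s1", "s2"),
    start = c(100L, 250L, 0L),
    end = c(250L, 400L, 150L)
  )
  set.seed(1)
  pl <- tibble::tibble(
    read_id = sprintf("r%d", 1:10),
    scaffold = sample(c("s1", "s2"), 10, replace = TRUE),
    start = sample(0L:400L, 10),
    retained = TRUE
  )
  counts <- count_gene_reads(pl, genes, read_length = 50)
  expect_equal(counts$count, oracle_gene_counts(pl, genes, 50))
  # a read spanning the boundary of two abutting genes counts for both
  spanning <- tibble::tibble(read_id = "span", scaffold = "s1",
                             start = 230L, retained = TRUE)
  both <- count_gene_reads(spanning, genes, read_length = 50)
  expect_equal(both$count[1:2], c(1L, 1L))
  # genes on scaffolds absent from the assembly warn and get zero
  expect_warning(
    zero <- count_gene_reads(pl, tibble::tibble(gene_id = "gX",
                                                scaffold = "nope",
                                                start = 0L, end = 100L),
                             read_length = 50,
                             assembly = c(s1 = "A", s2 = "A")),
    "absent")
  expect_identical(zero$count, 0L)
})
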