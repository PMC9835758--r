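test_that("a design without Y material yields no Y truth entries", {
  sim <- simulate_assembly(tiny_config(n_y_scaffolds = 0))
  expect_false(any(sim$truth$scaffolds$compartment == "Y"))
  expect_false(any(sim$truth$genes$compartment == "Y"))
  expect_identical(nrow(sim$truth$injections), 0L)
})

test_that("identical configs give byte-identical FASTA, truth and reads", {
  cfg <- tiny_config(error_rate = 0.01,
                     y_injections = list(list(target = "autosome_1",
                                              length = 2000, offset = 5000)))
  sim1 <- simulate_assembly(cfg)
  sim2 <- simulate_assembly(cfg)
  expect_identical(sim1$assembly, sim2$assembly)
  expect_identical(sim1$truth, sim2$truth)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  write_fixture(sim1, list(), d1, force = TRUE)
  write_fixture(sim2, list(), d2, force = TRUE)
  expect_identical(readLines(file.path(d1, "assembly.fa")),
                   readLines(file.path(d2, "assembly.fa")))
  expect_identical(simulate_reads(sim1, "male")$reads,
                   simulate_reads(sim2, "male")$reads)
})

test_that("soft-masked fraction tracks the configured repeat fraction", {
  sim <- simulate_assembly(tiny_config(
    n_x_scaffolds = 0, n_y_scaffolds = 0, repeat_fraction = 0.3,
    scaffold_length_range = c(100000L, 100000L)))
  seq <- sim$assembly[[1]]
  frac <- stringi::stri_count_charclass(seq, "[acgt]") / nchar(seq)
  expect_gt(frac, 0.3 * 0.95)
  expect_lt(frac, 0.3 * 1.05)
  # masked bases coincide with the truth repeat intervals
  rep_bases <- sum(sim$truth$repeats$end - sim$truth$repeats$start)
  expect_equal(stringi::stri_count_charclass(seq, "[acgt]"), rep_bases)
})

test_that("read counts follow the closed-form Poisson expectation", {
  # 100 kb autosomal scaffold, depth 10/copy, 100 bp reads, female (2 copies):
  # expectation ~ 2 * 10 * 100000 / 100 = 20000 reads
  counts <- vapply(1:10, function(s) {
    sim <- simulate_assembly(tiny_config(
      n_x_scaffolds = 0, n_y_scaffolds = 0,
      scaffold_length_range = c(100000L, 100000L), mean_depth = 10,
      seed = 100 + s))
    simulate_reads(sim, "female")$library_size
  }, numeric(1))
  expected <- 2 * 10 * 100000 / 100
  tol <- 4 * sqrt(expected / 10)   # 4 sd of the 10-seed mean
  expect_lt(abs(mean(counts) - expected), tol + 0.002 * expected)
})

test_that("female read sets never contain Y-origin reads; depth 0 is empty", {
  sim <- simulate_assembly(tiny_config())
  rs <- simulate_reads(sim, "female")
  origins <- parse_read_origin(rs$reads$read_id)
  expect_false(any(grepl("^y_", origins$source)))
  empty <- simulate_reads(sim, "male",
                          config = modifyList(sim$config,
                                              list(mean_depth = 0)))
  expect_identical(empty$library_size, 0L)
  # a female-only design with only Y scaffolds cannot be sampled
  ysim <- simulate_assembly(tiny_config(n_autosomal_scaffolds = 0,
                                        n_x_scaffolds = 0))
  expect_error(simulate_reads(ysim, "female"), "copy number")
})

test_that("per-compartment depth converges to mean_depth x copy number", {
  sim <- simulate_assembly(tiny_config(
    scaffold_length_range = c(100000L, 100000L), mean_depth = 20, seed = 9))
  for (sex in c("female", "male")) {
    rs <- simulate_reads(sim, sex)
    origins <- parse_read_origin(rs$reads$read_id)
    for (i in seq_len(nrow(sim$truth$scaffolds))) {
      sc <- sim$truth$scaffolds[i, ]
      copy <- if (sex == "female") sc$copy_female else sc$copy_male
      n <- sum(origins$source == sc$scaffold)
      depth <- n * sim$config$read_length / (sc$length +
                                               sim$config$read_length + 1)
      expect_lt(abs(depth - 20 * copy), max(0.1 * 20 * copy, 0.25))
    }
  }
})

test_that("Y injection splices sequence and shifts downstream coordinates", {
  base <- tiny_config(n_x_scaffolds = 0, n_y_scaffolds = 0,
                      scaffold_length_range = c(100000L, 100000L))
  sim0 <- simulate_assembly(base)
  inj <- list(list(target = "autosome_1", length = 5000L, offset = 20000L))
  sim <- inject_y_segments(sim0, inj)
  expect_identical(nchar(sim$assembly[["autosome_1"]]), 105000L)
  expect_identical(sim$truth$injections$start, 20000L)
  expect_identical(sim$truth$injections$end, 25000L)
  # flanks of the splice are the original sequence
  expect_identical(substr(sim$assembly[[1]], 1, 20000),
                   substr(sim0$assembly[[1]], 1, 20000))
  expect_identical(substring(sim$assembly[[1]], 25001),
                   substring(sim0$assembly[[1]], 20001))
  # genes at/after the insertion point shift by the injected length
  g0 <- sim0$truth$genes
  g1 <- sim$truth$genes
  after <- g0$start >= 20000
  expect_identical(g1$start[after], g0$start[after] + 5000L)
  before <- g0$end <= 20000
  expect_identical(g1$start[before], g0$start[before])
  # no injections requested: identity
  expect_identical(inject_y_segments(sim0, list()), sim0)
})

test_that("invalid injections are rejected", {
  sim <- simulate_assembly(tiny_config())
  expect_error(inject_y_segments(sim, list(
    list(target = "autosome_1", length = 1000, offset = 10000),
    list(target = "autosome_1", length = 1000, offset = 10500))),
    "overlap")
  expect_error(inject_y_segments(sim, list(
    list(target = "autosome_1", length = 1000, offset = 99999999))),
    "bounds")
  expect_error(inject_y_segments(sim, list(
    list(target = "y_1", length = 1000, offset = 100))), "non-Y")
})

test_that("fixtures round-trip: FASTA masking, FASTQ counts, BED bounds", {
  sim <- simulate_assembly(tiny_config(
    y_injections = list(list(target = "autosome_1", length = 2000,
                             offset = 5000))))
  rs_m <- simulate_reads(sim, "male")
  dir <- file.path(tempdir(), "fixture_roundtrip")
  unlink(dir, recursive = TRUE)
  manifest <- write_fixture(sim, list(male = rs_m), dir)
  expect_true(all(file.exists(manifest$path)))
  expect_error(write_fixture(sim, list(male = rs_m), dir), "force")

  fa <- read_fasta(file.path(dir, "assembly.fa"))
  expect_identical(fa, sim$assembly)   # sequences AND soft-masking

  fq <- read_fastq(file.path(dir, "reads_male.fastq"))
  expect_identical(fq$library_size, rs_m$library_size)
  expect_identical(fq$reads$seq, rs_m$reads$seq)

  bed <- read.table(file.path(dir, "truth_repeats.bed"), sep = "\t")
  lens <- setNames(nchar(sim$assembly), names(sim$assembly))
  expect_true(all(bed$V2 >= 0))
  expect_true(all(bed$V3 <= lens[bed$V1]))
  expect_true(all(bed$V2 < bed$V3))

  genes <- read_gff3(file.path(dir, "genes.gff3"))
  expect_identical(genes$start, sim$truth$genes$start)
  expect_identical(genes$end, sim$truth$genes$end)
})
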