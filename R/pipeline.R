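# One-call orchestration: simulate (or load) -> coverage -> CQ -> Y k-mers
# -> repeat summary, with config-hash-based stage skipping and a
# machine-readable run summary. All stage outputs are plain text
# (TSV/BED/JSON) so every number in the summary is recomputable from disk.

#' Assemble a pipeline run configuration
#'
#' Either \code{sim} (a [sim_config()]) or explicit input paths
#' (\code{assembly}, \code{reads_female}, \code{reads_male}, optionally
#' \code{genes}, \code{bam_female}/\code{bam_male}, \code{rmout}) must be
#' given.
#'
#' @param out_dir output directory.
#' @param sim optional [sim_config()] for a fully synthetic run.
#' @param assembly,reads_female,reads_male,genes,bam_female,bam_male,rmout
#'   input file paths for a file-based run.
#' @param window CQ window size in bp.
#' @param thresholds a [cq_thresholds()].
#' @param k,min_male_count,bin Y k-mer parameters.
#' @param policy,min_mapq,min_identity placement parameters.
#' @param seed integer seed for any stochastic step.
#' @return a \code{run_config} list.
#' @export
run_config <- function(out_dir, sim = NULL, assembly = NULL,
                       reads_female = NULL, reads_male = NULL, genes = NULL,
                       bam_female = NULL, bam_male = NULL, rmout = NULL,
                       window = 10000, thresholds = cq_thresholds(),
                       k = 25, min_male_count = 2, bin = 1800000,
                       policy = "unique", min_mapq = 20,
                       min_identity = 0.95, seed = 1L) {
  if (is.null(sim) && (is.null(assembly) || is.null(reads_female) ||
                       is.null(reads_male))) {
    abort("either a sim config or assembly + sexed reads must be provided")
  }
  structure(list(out_dir = out_dir, sim = sim, assembly = assembly,
                 reads_female = reads_female, reads_male = reads_male,
                 genes = genes, bam_female = bam_female,
                 bam_male = bam_male, rmout = rmout, window = window,
                 thresholds = thresholds, k = k,
                 min_male_count = min_male_count, bin = bin,
                 policy = policy, min_mapq = min_mapq,
                 min_identity = min_identity, seed = as.integer(seed)),
            class = "run_config")
}

#' Read/write a run configuration as YAML
#'
#' @param path YAML file.
#' @param config a \code{run_config}.
#' @return `read_run_config` returns a \code{run_config};
#'   `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$thresholds)) {
    y$thresholds <- do.call(cq_thresholds, y$thresholds)
  }
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  if (!is.null(y$sim)) {
    y$sim <- unclass(y$sim)
    y$sim$y_injections <- lapply(y$sim$y_injections, unclass)
  }
  if (!is.null(y$thresholds)) y$thresholds <- unclass(y$thresholds)
  yaml::write_yaml(y[!vapply(y, is.null, logical(1))], path,
                   precision = 17L)
  invisible(path)
}

run_config_hash <- function(config) {
  h <- unclass(config)
  h$out_dir <- NULL
  # integer/double drift through YAML round-trips must not change the hash
  h <- rapply(h, function(x) if (is.numeric(x)) as.numeric(x) else x,
              how = "replace")
  rlang::hash(h)
}

stage_paths <- function(out_dir) {
  list(
    state = file.path(out_dir, "state.json"),
    windows_f = file.path(out_dir, "coverage_female.tsv"),
    windows_m = file.path(out_dir, "coverage_male.tsv"),
    gene_counts_f = file.path(out_dir, "gene_counts_female.tsv"),
    gene_counts_m = file.path(out_dir, "gene_counts_male.tsv"),
    cq_windows = file.path(out_dir, "cq_windows.tsv"),
    calls = file.path(out_dir, "scaffold_calls.tsv"),
    gene_assignments = file.path(out_dir, "gene_assignments.tsv"),
    y_regions = file.path(out_dir, "y_unique_regions.bed"),
    y_density = file.path(out_dir, "y_density.tsv"),
    repeats = file.path(out_dir, "repeat_summary.tsv"),
    summary = file.path(out_dir, "run_summary.json")
  )
}

#' Run the full sex-chromosome screening pipeline
#'
#' Executes simulate/load, coverage, CQ, Y-k-mer and repeat-summary stages
#' in order, writes every stage product as plain text under \code{out_dir},
#' and returns a \code{sexscan_run} summary object. A rerun with an
#' unchanged config (same hash) reuses the stage outputs on disk; on a stage
#' failure a \code{FAILED_<stage>} marker file is left next to any partial
#' outputs.
#'
#' @param config a [run_config()].
#' @param force recompute even if outputs with a matching config hash exist.
#' @return a \code{sexscan_run} object; see [tidy()] / [glance()] methods.
#' @export
run_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- stage_paths(config$out_dir)
  h <- run_config_hash(config)
  state <- if (file.exists(paths$state)) {
    jsonlite::read_json(paths$state, simplifyVector = TRUE)
  } else list()
  fresh <- !identical(state$config_hash, h) || force
  files_exist <- all(file.exists(unlist(paths[setdiff(names(paths),
                                                      "state")])))
  run_stage <- function(stage, code) {
    marker <- file.path(config$out_dir, paste0("FAILED_", stage))
    tryCatch({
      r <- force(code)
      if (file.exists(marker)) unlink(marker)
      r
    }, error = function(e) {
      file.create(marker)
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
  }

  if (!fresh && files_exist) {
    skipped <- TRUE
    cq_windows <- read_tsv_plain(paths$cq_windows)
    attr(cq_windows, "window_size") <- config$window
    calls <- read_tsv_plain(paths$calls)
    assignments <- read_tsv_plain(paths$gene_assignments)
    y_regions <- as_tibble(setNames(
      read.table(paths$y_regions, sep = "\t",
                 col.names = c("scaffold", "start", "end", "name"),
                 colClasses = c("character", "integer", "integer",
                                "character")),
      c("scaffold", "start", "end", "name")))
    y_density <- read_tsv_plain(paths$y_density)
    repeat_summary <- read_tsv_plain(paths$repeats)
  } else {
    skipped <- FALSE
    inputs <- run_stage("inputs", load_run_inputs(config))
    cov <- run_stage("coverage", {
      windows <- tile_windows(inputs$assembly, config$window)
      pl_f <- inputs$placements_female %||%
        place_reads(inputs$reads_female, inputs$assembly,
                    policy = config$policy,
                    min_identity = config$min_identity)
      pl_m <- inputs$placements_male %||%
        place_reads(inputs$reads_male, inputs$assembly,
                    policy = config$policy,
                    min_identity = config$min_identity)
      track_f <- window_rpkm(pl_f, windows, sex = "female")
      track_m <- window_rpkm(pl_m, windows, sex = "male")
      write_tsv_plain(track_f, paths$windows_f)
      write_tsv_plain(track_m, paths$windows_m)
      gc_f <- gc_m <- NULL
      if (!is.null(inputs$genes) && nrow(inputs$genes) > 0) {
        gc_f <- count_gene_reads(pl_f, inputs$genes,
                                 assembly = inputs$assembly)
        gc_m <- count_gene_reads(pl_m, inputs$genes,
                                 assembly = inputs$assembly)
        write_tsv_plain(gc_f, paths$gene_counts_f)
        write_tsv_plain(gc_m, paths$gene_counts_m)
      } else {
        write_tsv_plain(tibble(), paths$gene_counts_f)
        write_tsv_plain(tibble(), paths$gene_counts_m)
      }
      list(track_f = track_f, track_m = track_m, gc_f = gc_f, gc_m = gc_m)
    })
    cqres <- run_stage("cq", {
      cq_windows <- tag_regions(region_cq(cov$track_f, cov$track_m),
                                config$thresholds)
      calls <- call_scaffolds(cq_windows, config$thresholds)
      write_tsv_plain(cq_windows, paths$cq_windows)
      write_tsv_plain(calls, paths$calls)
      assignments <- tibble()
      if (!is.null(cov$gc_f)) {
        assignments <- assign_genes(gene_cq(cov$gc_f, cov$gc_m),
                                    context_cq(inputs$genes, cq_windows),
                                    config$thresholds)
      }
      write_tsv_plain(assignments, paths$gene_assignments)
      list(cq_windows = cq_windows, calls = calls,
           assignments = assignments)
    })
    cq_windows <- cqres$cq_windows
    calls <- cqres$calls
    assignments <- cqres$assignments
    ykres <- run_stage("ykmer", {
      tab_m <- count_kmers(inputs$reads_male, config$k)
      tab_f <- count_kmers(inputs$reads_female, config$k)
      uniq <- male_unique(tab_m, tab_f, config$min_male_count)
      hits <- locate_kmers(uniq, inputs$assembly)
      y_regions <- merge_y_regions(hits, config$k)
      y_density <- density_track(y_regions, inputs$assembly, config$bin)
      write_bed(mutate(y_regions,
                       name = sprintf("yu_%d", dplyr::row_number())),
                paths$y_regions)
      write_tsv_plain(y_density, paths$y_density)
      list(y_regions = y_regions, y_density = y_density)
    })
    y_regions <- ykres$y_regions
    y_density <- ykres$y_density
    repeat_summary <- run_stage("repeats", {
      rs <- masked_fraction(inputs$assembly, calls)
      if (!is.null(config$rmout)) {
        cf <- class_fractions(read_repeatmasker_out(config$rmout),
                              inputs$assembly, calls)
        write_tsv_plain(cf, file.path(config$out_dir,
                                      "repeat_classes.tsv"))
      }
      write_tsv_plain(rs, paths$repeats)
      rs
    })
    jsonlite::write_json(list(config_hash = h, time = format(Sys.time())),
                         paths$state, auto_unbox = TRUE)
  }

  tag_counts <- count(cq_windows, .data$tag)
  summary <- list(
    n_scaffolds = nrow(calls),
    n_x_candidates = sum(calls$call == "X-candidate"),
    n_y_candidates = sum(calls$call == "Y-candidate"),
    window_tags = setNames(as.list(tag_counts$n), tag_counts$tag),
    n_genes = nrow(assignments),
    gene_assignments = if (nrow(assignments)) {
      as.list(table(assignments$assignment))
    } else list(),
    n_y_unique_regions = nrow(y_regions),
    y_unique_bases = as.numeric(sum(y_regions$end - y_regions$start)),
    provenance = list(config_hash = h,
                      version = as.character(utils::packageVersion("sexscan")),
                      skipped = skipped)
  )
  jsonlite::write_json(summary, stage_paths(config$out_dir)$summary,
                       auto_unbox = TRUE, digits = NA)
  structure(list(config = config, summary = summary, calls = calls,
                 cq_windows = cq_windows, gene_assignments = assignments,
                 y_regions = y_regions, y_density = y_density,
                 repeat_summary = repeat_summary,
                 files = stage_paths(config$out_dir)),
            class = "sexscan_run")
}

# Resolve run inputs: either simulate under the config seed or read files.
load_run_inputs <- function(config) {
  if (!is.null(config$sim)) {
    sim <- simulate_assembly(config$sim)
    fix_dir <- file.path(config$out_dir, "sim")
    rs_f <- simulate_reads(sim, "female")
    rs_m <- simulate_reads(sim, "male")
    write_fixture(sim, list(female = rs_f, male = rs_m), fix_dir,
                  force = TRUE)
    list(assembly = sim$assembly, truth = sim$truth,
         genes = sim$truth$genes, reads_female = rs_f, reads_male = rs_m,
         placements_female = NULL, placements_male = NULL)
  } else {
    assembly <- read_fasta(config$assembly)
    genes <- if (!is.null(config$genes)) read_gff3(config$genes)
    pf <- if (!is.null(config$bam_female)) {
      load_alignments(config$bam_female, config$min_mapq, assembly)
    }
    pm <- if (!is.null(config$bam_male)) {
      load_alignments(config$bam_male, config$min_mapq, assembly)
    }
    list(assembly = assembly, truth = NULL, genes = genes,
         reads_female = read_fastq(config$reads_female, "female"),
         reads_male = read_fastq(config$reads_male, "male"),
         placements_female = pf, placements_male = pm)
  }
}

#' @export
print.sexscan_run <- function(x, ...) {
  s <- x$summary
  cat("<sexscan_run>\n")
  cat(sprintf("  scaffolds: %d (%d X-candidate, %d Y-candidate)\n",
              s$n_scaffolds, s$n_x_candidates, s$n_y_candidates))
  cat(sprintf("  Y-unique regions: %d (%s bases)\n", s$n_y_unique_regions,
              format(s$y_unique_bases, big.mark = ",")))
  cat(sprintf("  outputs: %s\n", x$config$out_dir))
  invisible(x)
}

#' @rdname sexscan_tidiers
#' @export
tidy.sexscan_run <- function(x, ...) {
  x$calls
}

#' Tidiers for pipeline runs
#'
#' \code{tidy()} returns the per-scaffold call table; \code{glance()} a
#' one-row run summary.
#'
#' @param x a \code{sexscan_run}.
#' @param ... unused.
#' @name sexscan_tidiers
#' @export
glance.sexscan_run <- function(x, ...) {
  s <- x$summary
  tibble(n_scaffolds = s$n_scaffolds, n_x_candidates = s$n_x_candidates,
         n_y_candidates = s$n_y_candidates,
         n_windows_x = s$window_tags$X %||% 0L,
         n_windows_y = s$window_tags$Y %||% 0L,
         n_genes = s$n_genes,
         n_genes_x = s$gene_assignments$X %||% 0L,
         n_genes_y = s$gene_assignments$Y %||% 0L,
         n_y_unique_regions = s$n_y_unique_regions,
         y_unique_bases = s$y_unique_bases)
}

#' Export candidate intervals for PCR validation
#'
#' For each Y-unique region (or any interval set) emits candidate amplicon
#' intervals suitable for external primer design: within the region, of a
#' length inside \code{amplicon_range}, preferring spans that avoid
#' soft-masked bases; the masked fraction, GC fraction and distance to the
#' region edge are reported.
#'
#' @param regions tibble with \code{scaffold}, \code{start}, \code{end}.
#' @param assembly soft-masked named character vector.
#' @param amplicon_range length-2 numeric, allowed amplicon lengths in bp.
#' @param max_per_region candidates kept per region (default 3).
#' @param step candidate grid step in bp (default 100).
#' @return tibble with \code{scaffold}, \code{start}, \code{end},
#'   \code{length}, \code{gc_fraction}, \code{masked_fraction},
#'   \code{edge_distance}.
#' @export
validate_targets <- function(regions, assembly,
                             amplicon_range = c(400, 800),
                             max_per_region = 3, step = 100) {
  out <- list()
  len <- as.integer(floor(mean(amplicon_range)))
  for (i in seq_len(nrow(regions))) {
    width <- regions$end[i] - regions$start[i]
    use_len <- if (width >= len) len else if (width >= amplicon_range[1]) {
      as.integer(width)
    } else next
    starts <- seq(regions$start[i], regions$end[i] - use_len, by = step)
    seqs <- substring(assembly[[regions$scaffold[i]]], starts + 1,
                      starts + use_len)
    cand <- tibble(
      scaffold = regions$scaffold[i],
      start = as.integer(starts),
      end = as.integer(starts + use_len),
      length = use_len,
      gc_fraction = gc_fraction(seqs),
      masked_fraction = stringi::stri_count_charclass(seqs, "[acgt]") /
        use_len,
      edge_distance = pmin(starts - regions$start[i],
                           regions$end[i] - (starts + use_len))
    )
    cand <- head(arrange(cand, .data$masked_fraction,
                         dplyr::desc(.data$edge_distance)),
                 max_per_region)
    out[[length(out) + 1]] <- cand
  }
  bind_rows(out) %||% tibble()
}
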