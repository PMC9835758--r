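#' Configuration for the synthetic sexed-WGS generator
#'
#' Defines the study design the simulator emulates: a multi-scaffold assembly
#' with autosomal (copy number 2 in both sexes), X (2 in females / 1 in males)
#' and Y (0 / 1) compartments, interspersed soft-masked repeat tracts, gene
#' intervals, optional Y segments spliced into autosomal scaffolds, and sexed
#' single-end read sets whose per-base depth follows the copy numbers with
#' Poisson noise.
#'
#' @param n_autosomal_scaffolds,n_x_scaffolds,n_y_scaffolds scaffold counts
#'   per compartment.
#' @param scaffold_length_range integer length-2 vector, min/max scaffold
#'   length in bp (uniformly drawn; equal values fix the length). The minimum
#'   must be at least three 10 kb coverage windows.
#' @param repeat_fraction proportion of scaffold bases in repeat tracts,
#'   in \[0, 1).
#' @param shared_repeat_fraction proportion of repeat tracts drawn from a
#'   repeat library common to all compartments (models cross-mapping).
#' @param repeat_divergence per-base substitution rate applied independently
#'   to each repeat copy (default 0.02: copies stay recognisable but are
#'   mostly k-mer-distinct at k = 25).
#' @param n_genes_per_scaffold gene intervals simulated per scaffold.
#' @param read_length read length in bp.
#' @param mean_depth fold-coverage per haploid copy (so an autosome is
#'   sampled at \code{2 * mean_depth} in both sexes).
#' @param error_rate per-base substitution error rate in \[0, 0.05\].
#' @param female_library_scale multiplier on the female sampling rate,
#'   emulating unequal sequencing effort between the two libraries; the
#'   default 224.8/202.5 matches a typical female:male library-size ratio.
#'   RPKM normalization cancels it, so CQ expectations are unchanged.
#' @param seed integer seed; identical configs (including seed) produce
#'   byte-identical outputs.
#' @param y_injections list of Y-segment splices, each a list/row with fields
#'   \code{target} (autosomal or X scaffold name), \code{length} (bp) and
#'   \code{offset} (0-based insertion point on the original scaffold).
#'
#' @return an object of class \code{sim_config} (a validated named list).
#' @examples
#' cfg <- sim_config(n_autosomal_scaffolds = 1, n_x_scaffolds = 1,
#'                   n_y_scaffolds = 1, scaffold_length_range = c(5e4, 5e4),
#'                   mean_depth = 5, seed = 1)
#' @export
sim_config <- function(n_autosomal_scaffolds = 10,
                       n_x_scaffolds = 10,
                       n_y_scaffolds = 10,
                       scaffold_length_range = c(100000L, 100000L),
                       repeat_fraction = 0.3,
                       shared_repeat_fraction = 0,
                       repeat_divergence = 0.02,
                       n_genes_per_scaffold = 5,
                       read_length = 100,
                       mean_depth = 20,
                       error_rate = 0,
                       female_library_scale = 224.8 / 202.5,
                       seed = 1L,
                       y_injections = list()) {
  cfg <- list(
    n_autosomal_scaffolds = as.integer(n_autosomal_scaffolds),
    n_x_scaffolds = as.integer(n_x_scaffolds),
    n_y_scaffolds = as.integer(n_y_scaffolds),
    scaffold_length_range = as.integer(scaffold_length_range),
    repeat_fraction = repeat_fraction,
    shared_repeat_fraction = shared_repeat_fraction,
    repeat_divergence = repeat_divergence,
    n_genes_per_scaffold = as.integer(n_genes_per_scaffold),
    read_length = as.integer(read_length),
    mean_depth = mean_depth,
    error_rate = error_rate,
    female_library_scale = female_library_scale,
    seed = as.integer(seed),
    y_injections = normalize_injections(y_injections)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

normalize_injections <- function(y_injections) {
  if (is.data.frame(y_injections)) {
    y_injections <- purrr::transpose(as.list(y_injections))
  }
  lapply(y_injections, function(inj) {
    stopifnot(all(c("target", "length", "offset") %in% names(inj)))
    list(target = as.character(inj$target), length = as.integer(inj$length),
         offset = as.integer(inj$offset))
  })
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_autosomal_scaffolds, cfg$n_x_scaffolds, cfg$n_y_scaffolds,
              cfg$n_genes_per_scaffold)
  if (!all(vapply(counts, is_count, logical(1)))) {
    abort("scaffold and gene counts must be non-negative integers")
  }
  rng <- cfg$scaffold_length_range
  if (length(rng) != 2 || any(rng <= 0) || rng[1] > rng[2]) {
    abort("scaffold_length_range must be c(min, max) with 0 < min <= max")
  }
  if (rng[1] < 3 * 10000) {
    abort("scaffold_length_range minimum must be >= 3 coverage windows (30 kb)")
  }
  if (cfg$repeat_fraction < 0 || cfg$repeat_fraction >= 1) {
    abort("repeat_fraction must be in [0, 1)")
  }
  if (cfg$shared_repeat_fraction < 0 || cfg$shared_repeat_fraction > 1) {
    abort("shared_repeat_fraction must be in [0, 1]")
  }
  if (cfg$error_rate < 0 || cfg$error_rate > 0.05) {
    abort("error_rate must be in [0, 0.05]")
  }
  if (cfg$mean_depth < 0) abort("mean_depth must be >= 0")
  if (cfg$read_length < 20) abort("read_length must be >= 20")
  if (rng[1] < cfg$read_length) abort("scaffold length below read_length")
  if (is.na(cfg$seed) || cfg$seed < 0 || cfg$seed > 2^31 - 10) {
    abort("seed must be an integer in [0, 2^31 - 10)")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  scaffolds: %d autosomal, %d X, %d Y (%s-%s bp)\n",
              x$n_autosomal_scaffolds, x$n_x_scaffolds, x$n_y_scaffolds,
              format(x$scaffold_length_range[1], big.mark = ","),
              format(x$scaffold_length_range[2], big.mark = ",")))
  cat(sprintf("  repeats: fraction %.2f (shared %.2f, divergence %.2f)\n",
              x$repeat_fraction, x$shared_repeat_fraction, x$repeat_divergence))
  cat(sprintf("  reads: %d bp, depth %gx/copy, error %.3f, seed %d\n",
              x$read_length, x$mean_depth, x$error_rate, x$seed))
  if (length(x$y_injections)) {
    cat(sprintf("  y_injections: %d\n", length(x$y_injections)))
  }
  invisible(x)
}
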