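# Assembly simulation. Scaffolds are built from i.i.d. uniform-random bases
# with interspersed repeat tracts copied (with small divergence) from repeat
# libraries; tracts are lowercase (soft-masked). Each scaffold additionally
# carries fixed random flanking context (stored in the truth object, never in
# the FASTA): reads are later sampled from the flanked sequence so per-base
# depth is uniform across the whole scaffold, emulating that real scaffolds
# are excised from a larger chromosomal context.

make_repeat_library <- function(prefix, n_elements = 5,
                                length_range = c(300L, 3000L)) {
  lens <- sample(seq(length_range[1], length_range[2]), n_elements,
                 replace = TRUE)
  tibble(
    class = paste0(prefix, "_", seq_len(n_elements)),
    seq = vapply(lens, random_dna, character(1))
  )
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  apply_read_errors(seq, rate)
}

# Build one scaffold sequence with its repeat annotation (local coordinates).
build_scaffold_seq <- function(length, cfg, private_lib, shared_lib) {
  target <- round(cfg$repeat_fraction * length)
  tracts <- list()
  classes <- character(0)
  cum <- 0
  while (cum < target) {
    lib <- if (runif(1) < cfg$shared_repeat_fraction) shared_lib else private_lib
    i <- sample.int(nrow(lib), 1)
    piece <- mutate_seq(lib$seq[i], cfg$repeat_divergence)
    keep <- min(nchar(piece), target - cum)
    piece <- substr(piece, 1, keep)
    tracts[[length(tracts) + 1]] <- tolower(piece)
    classes <- c(classes, lib$class[i])
    cum <- cum + keep
  }
  lens <- nchar(unlist(tracts) %||% character(0))
  starts <- place_nonoverlapping(as.integer(lens), length)
  ord <- order(starts)
  starts <- starts[ord]
  lens <- lens[ord]
  tracts <- tracts[ord]
  classes <- classes[ord]
  pieces <- character(0)
  prev <- 0L
  for (i in seq_along(starts)) {
    pieces <- c(pieces, random_dna(starts[i] - prev), tracts[[i]])
    prev <- starts[i] + lens[i]
  }
  pieces <- c(pieces, random_dna(length - prev))
  list(
    seq = paste(pieces, collapse = ""),
    repeats = tibble(start = as.integer(starts),
                     end = as.integer(starts + lens),
                     class = classes)
  )
}

place_genes <- function(scaffold, length, n_genes,
                        gene_length_range = c(500L, 3000L)) {
  if (n_genes == 0) {
    return(tibble(scaffold = character(0), start = integer(0),
                  end = integer(0)))
  }
  lens <- sample(seq(gene_length_range[1], gene_length_range[2]), n_genes,
                 replace = TRUE)
  starts <- sort(place_nonoverlapping(lens, length))
  tibble(scaffold = scaffold, start = as.integer(starts),
         end = as.integer(starts + lens))
}

compartment_copies <- function(compartment) {
  switch(compartment,
         autosome = c(female = 2L, male = 2L),
         X = c(female = 2L, male = 1L),
         Y = c(female = 0L, male = 1L),
         abort(paste0("unknown compartment: ", compartment)))
}

#' Simulate a soft-masked assembly with known sex-chromosome truth
#'
#' Generates autosomal, X and Y scaffolds with interspersed repeat tracts and
#' gene intervals, and records the full ground truth (compartment and per-sex
#' copy number of every scaffold, gene compartments, repeat intervals,
#' injected Y intervals). If the config requests Y injections they are applied
#' through [inject_y_segments()].
#'
#' @param config a [sim_config()].
#' @return an object of class \code{sexscan_sim}: a list with \code{assembly}
#'   (named character vector of soft-masked sequences), \code{truth} (list of
#'   tibbles: \code{scaffolds}, \code{genes}, \code{repeats},
#'   \code{injections}, \code{flanks}) and \code{config}.
#' @examples
#' sim <- simulate_assembly(sim_config(n_autosomal_scaffolds = 1,
#'   n_x_scaffolds = 0, n_y_scaffolds = 0,
#'   scaffold_length_range = c(3e4, 3e4), seed = 7))
#' sim$truth$scaffolds
#' @export
simulate_assembly <- function(config) {
  cfg <- validate_sim_config(config)
  sim <- with_sim_seed(cfg$seed, {
    n <- c(autosome = cfg$n_autosomal_scaffolds, X = cfg$n_x_scaffolds,
           Y = cfg$n_y_scaffolds)
    shared_lib <- make_repeat_library("shared")
    libs <- list(autosome = make_repeat_library("autosome"),
                 X = make_repeat_library("X"),
                 Y = make_repeat_library("Y"))
    scaffolds <- list(); seqs <- list(); genes <- list(); repeats <- list()
    flanks <- list()
    gene_counter <- 0L
    for (comp in names(n)) {
      for (i in seq_len(n[[comp]])) {
        name <- sprintf("%s_%d", tolower(comp), i)
        L <- if (cfg$scaffold_length_range[1] == cfg$scaffold_length_range[2]) {
          cfg$scaffold_length_range[1]
        } else {
          sample(seq(cfg$scaffold_length_range[1],
                     cfg$scaffold_length_range[2]), 1)
        }
        built <- build_scaffold_seq(L, cfg, libs[[comp]], shared_lib)
        seqs[[name]] <- built$seq
        repeats[[name]] <- mutate(built$repeats, scaffold = name,
                                  .before = 1)
        g <- place_genes(name, L, cfg$n_genes_per_scaffold)
        g$gene_id <- sprintf("g%05d", gene_counter + seq_len(nrow(g)))
        gene_counter <- gene_counter + nrow(g)
        g$compartment <- comp
        genes[[name]] <- g
        cp <- compartment_copies(comp)
        scaffolds[[name]] <- tibble(scaffold = name, compartment = comp,
                                    length = as.integer(L),
                                    copy_female = cp[["female"]],
                                    copy_male = cp[["male"]])
        flanks[[name]] <- tibble(source = name,
                                 left = random_dna(cfg$read_length),
                                 right = random_dna(cfg$read_length))
      }
    }
    truth <- list(
      scaffolds = bind_rows(scaffolds),
      genes = select(bind_rows(genes), "gene_id", "scaffold", "start", "end",
                     "compartment"),
      repeats = bind_rows(repeats),
      injections = tibble(scaffold = character(0), start = integer(0),
                          end = integer(0)),
      flanks = bind_rows(flanks)
    )
    structure(list(assembly = unlist(seqs) %||% setNames(character(0),
                                                         character(0)),
                   truth = truth, config = cfg),
              class = "sexscan_sim")
  })
  if (length(cfg$y_injections) > 0) {
    sim <- inject_y_segments(sim, cfg$y_injections)
  }
  sim
}

#' Splice Y-origin segments into non-Y scaffolds
#'
#' Emulates misassembly: Y-chromosome material erroneously joined into a
#' chromosome-scale scaffold. Each requested segment is freshly generated Y
#' sequence (with the config's repeat structure) spliced at the requested
#' offset; gene and repeat coordinates at or beyond the insertion point are
#' shifted, and the truth records the injected interval. Read simulation
#' treats injected intervals as male-only material with its own flanking
#' context, and samples the surrounding scaffold from the sequence with the
#' segment excised (the true autosomal chromosome of both sexes).
#'
#' @param sim a \code{sexscan_sim} from [simulate_assembly()].
#' @param injections list of injections (see [sim_config()]); defaults to the
#'   config's \code{y_injections}.
#' @return the modified \code{sexscan_sim}.
#' @export
inject_y_segments <- function(sim, injections = sim$config$y_injections) {
  stopifnot(inherits(sim, "sexscan_sim"))
  injections <- normalize_injections(injections)
  if (length(injections) == 0) return(sim)
  req <- bind_rows(lapply(injections, as_tibble))
  req <- arrange(req, .data$target, .data$offset)
  by_target <- split(req, req$target)
  for (tg in names(by_target)) {
    r <- by_target[[tg]]
    if (nrow(r) > 1 &&
        any(r$offset[-1] < (r$offset + r$length)[-nrow(r)])) {
      abort("requested Y injections overlap on scaffold ", tg)
    }
  }
  with_sim_seed(sim$config$seed + 3L, {
    shared_lib <- make_repeat_library("shared_inj")
    y_lib <- make_repeat_library("Y_inj")
    for (inj in seq_len(nrow(req))) {
      tg <- req$target[inj]
      len <- req$length[inj]
      row <- which(sim$truth$scaffolds$scaffold == tg)
      if (length(row) != 1) abort("unknown injection target: ", tg)
      if (sim$truth$scaffolds$compartment[row] == "Y") {
        abort("injection target must be a non-Y scaffold: ", tg)
      }
      # offsets are in original coordinates; account for earlier splices
      prior <- dplyr::filter(sim$truth$injections, .data$scaffold == tg)
      shift <- sum(prior$end - prior$start)
      offset <- req$offset[inj] + shift
      L <- sim$truth$scaffolds$length[row]
      if (req$offset[inj] < 0 || offset > L) {
        abort("injection exceeds bounds of scaffold ", tg)
      }
      built <- build_scaffold_seq(len, sim$config, y_lib, shared_lib)
      seq <- sim$assembly[[tg]]
      sim$assembly[[tg]] <- paste0(substr(seq, 1, offset), built$seq,
                                   substr(seq, offset + 1, L))
      shift_tbl <- function(tbl) {
        if (!nrow(tbl)) return(tbl)
        on_tg <- tbl$scaffold == tg
        whole <- on_tg & tbl$start >= offset
        straddle <- on_tg & tbl$start < offset & tbl$end > offset
        tbl$start[whole] <- tbl$start[whole] + len
        tbl$end[whole | straddle] <- tbl$end[whole | straddle] + len
        tbl
      }
      sim$truth$genes <- shift_tbl(sim$truth$genes)
      sim$truth$repeats <- shift_tbl(sim$truth$repeats)
      sim$truth$injections <- shift_tbl(sim$truth$injections)
      sim$truth$repeats <- bind_rows(
        sim$truth$repeats,
        mutate(built$repeats, scaffold = tg, start = .data$start + offset,
               end = .data$end + offset, .before = 1)
      )
      sim$truth$injections <- bind_rows(
        sim$truth$injections,
        tibble(scaffold = tg, start = as.integer(offset),
               end = as.integer(offset + len))
      )
      sim$truth$scaffolds$length[row] <- L + len
      src <- sprintf("%s@%d", tg, offset)
      sim$truth$flanks <- bind_rows(
        sim$truth$flanks,
        tibble(source = src, left = random_dna(sim$config$read_length),
               right = random_dna(sim$config$read_length))
      )
    }
    sim$truth$injections <- arrange(sim$truth$injections, .data$scaffold,
                                    .data$start)
    sim
  })
}

#' @export
print.sexscan_sim <- function(x, ...) {
  comp <- table(x$truth$scaffolds$compartment)
  cat("<sexscan_sim>\n")
  cat(sprintf("  %d scaffolds (%s), %s bp total\n",
              nrow(x$truth$scaffolds),
              paste(names(comp), comp, sep = ":", collapse = ", "),
              format(sum(x$truth$scaffolds$length), big.mark = ",")))
  cat(sprintf("  %d genes, %d repeat tracts, %d injected Y intervals\n",
              nrow(x$truth$genes), nrow(x$truth$repeats),
              nrow(x$truth$injections)))
  invisible(x)
}

#' Scaffold lengths of an assembly
#'
#' @param assembly named character vector of scaffold sequences (or a
#'   \code{sexscan_sim}).
#' @return a tibble with \code{scaffold} and \code{length}.
#' @export
assembly_lengths <- function(assembly) {
  if (inherits(assembly, "sexscan_sim")) assembly <- assembly$assembly
  tibble(scaffold = names(assembly), length = nchar(assembly))
}
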