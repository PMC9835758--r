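# Sexed read simulation. Reads are sampled from the per-sex *genome* implied
# by the truth, not from the assembly verbatim: each scaffold contributes its
# sequence with injected Y intervals excised (that is the true chromosome of
# both sexes), and each injected Y segment is a separate male-only source.
# Every source is padded with its fixed flanking context so per-base depth is
# uniform over the whole source; flank-overlapping reads carry context bases
# shared between the sexes and simply fail to place on the assembly.

sim_read_sources <- function(sim, sex) {
  cfg <- sim$config
  sc <- sim$truth$scaffolds
  inj <- sim$truth$injections
  out <- vector("list", nrow(sc) + nrow(inj))
  k <- 0L
  for (i in seq_len(nrow(sc))) {
    name <- sc$scaffold[i]
    seq <- sim$assembly[[name]]
    ivs <- dplyr::filter(inj, .data$scaffold == name)
    if (nrow(ivs) > 0) {
      keep_start <- c(0L, ivs$end)
      keep_end <- c(ivs$start, nchar(seq))
      seq <- paste(substring(seq, keep_start + 1, keep_end), collapse = "")
    }
    fl <- dplyr::filter(sim$truth$flanks, .data$source == name)
    copy <- if (sex == "female") sc$copy_female[i] else sc$copy_male[i]
    k <- k + 1L
    out[[k]] <- tibble(source = name, seq = seq, left = fl$left,
                       right = fl$right, copy = copy)
  }
  for (i in seq_len(nrow(inj))) {
    name <- sprintf("%s@%d", inj$scaffold[i], inj$start[i])
    fl <- dplyr::filter(sim$truth$flanks, .data$source == name)
    k <- k + 1L
    out[[k]] <- tibble(
      source = name,
      seq = substring(sim$assembly[[inj$scaffold[i]]], inj$start[i] + 1,
                      inj$end[i]),
      left = fl$left, right = fl$right,
      copy = if (sex == "female") 0L else 1L
    )
  }
  bind_rows(out)
}

#' Simulate a sexed single-end read set
#'
#' Per-base depth over each source sequence is
#' \code{mean_depth * copy_number[source, sex]} (females: autosome 2, X 2,
#' Y 0; males: autosome 2, X 1, Y 1), scaled for the female library by
#' \code{female_library_scale}. Read counts are Poisson, start positions and
#' strands uniform, substitution errors applied at \code{error_rate}. Read
#' ids encode the origin as \code{source:position:strand:serial} (position is
#' the 0-based start on the unpadded source; negative or past-end positions
#' mark flank-overlapping reads).
#'
#' @param sim a \code{sexscan_sim}.
#' @param sex \code{"female"} or \code{"male"}.
#' @param config simulation config; defaults to the sim's own.
#' @return an object of class \code{read_set}: list with \code{sex},
#'   \code{reads} (tibble of \code{read_id}, \code{seq}) and
#'   \code{library_size}.
#' @examples
#' sim <- simulate_assembly(sim_config(n_autosomal_scaffolds = 1,
#'   n_x_scaffolds = 0, n_y_scaffolds = 0,
#'   scaffold_length_range = c(3e4, 3e4), mean_depth = 2, seed = 7))
#' rs <- simulate_reads(sim, "male")
#' rs$library_size
#' @export
simulate_reads <- function(sim, sex = c("female", "male"),
                           config = sim$config) {
  sex <- match.arg(sex)
  cfg <- validate_sim_config(config)
  sources <- sim_read_sources(sim, sex)
  if (nrow(sources) == 0 || all(sources$copy == 0)) {
    abort(sprintf("every copy number is 0 for sex '%s'; nothing to sample",
                  sex))
  }
  rl <- cfg$read_length
  scale <- if (sex == "female") cfg$female_library_scale else 1
  with_sim_seed(cfg$seed + if (sex == "female") 1L else 2L, {
    chunks <- vector("list", nrow(sources))
    for (i in seq_len(nrow(sources))) {
      src <- sources[i, ]
      L <- nchar(src$seq)
      if (L < rl) abort("source shorter than read_length: ", src$source)
      if (src$copy == 0 || cfg$mean_depth == 0) next
      n_starts <- L + rl + 1L   # starts on the padded sequence
      lambda <- src$copy * cfg$mean_depth * scale * n_starts / rl
      n <- rpois(1, lambda)
      if (n == 0) next
      padded <- paste0(src$left, src$seq, src$right)
      starts <- sample.int(n_starts, n, replace = TRUE) - 1L
      minus <- sample(c(FALSE, TRUE), n, replace = TRUE)
      seqs <- substring(padded, starts + 1L, starts + rl)
      seqs[minus] <- revcomp(seqs[minus])
      seqs <- apply_read_errors(seqs, cfg$error_rate)
      chunks[[i]] <- tibble(
        source = src$source,
        pos = starts - rl,     # 0-based on the unpadded source
        strand = ifelse(minus, "-", "+"),
        seq = toupper(seqs)
      )
    }
    reads <- bind_rows(chunks)
    if (nrow(reads) == 0) {
      reads <- tibble(read_id = character(0), seq = character(0))
    } else {
      reads <- mutate(reads,
                      read_id = sprintf("%s:%d:%s:%d", .data$source,
                                        .data$pos, .data$strand,
                                        dplyr::row_number()))
      reads <- select(reads, "read_id", "seq")
    }
    structure(list(sex = sex, reads = reads, library_size = nrow(reads)),
              class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %s, %s reads\n", x$sex,
              format(x$library_size, big.mark = ",")))
  invisible(x)
}

#' Parse the origin encoded in simulated read ids
#'
#' @param read_id character vector of ids from [simulate_reads()].
#' @return tibble with \code{source}, \code{pos} (0-based start on the
#'   unpadded source; negative or beyond the source length for
#'   flank-overlapping reads) and \code{strand}.
#' @export
parse_read_origin <- function(read_id) {
  parts <- stringi::stri_split_fixed(read_id, ":", simplify = TRUE)
  tibble(source = parts[, 1], pos = as.integer(parts[, 2]),
         strand = parts[, 3])
}
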