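# Repeat-content summaries per called compartment. "Known bases" are the
# non-N bases; the masked fraction is lowercase (soft-masked) bases over
# known bases. An optional RepeatMasker-style .out table gives per-class
# fractions, with overlapping same-class annotations flattened first.

compartment_of_calls <- function(calls) {
  dplyr::case_when(calls == "X-candidate" ~ "X",
                   calls == "Y-candidate" ~ "Y",
                   TRUE ~ "autosome")
}

#' Masked-base fraction per compartment
#'
#' Splits scaffolds into compartments by their scaffold calls (X-candidate,
#' Y-candidate, everything else autosome) and reports, per compartment and
#' for the whole assembly, total bases, known (non-N) bases, soft-masked
#' bases and the masked fraction of known bases.
#'
#' @param assembly soft-masked named character vector.
#' @param calls tibble with \code{scaffold} and \code{call} (from
#'   [call_scaffolds()]), or with \code{compartment} directly.
#' @return tibble with \code{compartment}, \code{n_scaffolds},
#'   \code{total_bases}, \code{known_bases}, \code{masked_bases},
#'   \code{masked_fraction}.
#' @export
masked_fraction <- function(assembly, calls) {
  comp <- if ("compartment" %in% names(calls)) calls$compartment
          else compartment_of_calls(calls$call)
  comp <- setNames(comp, calls$scaffold)[names(assembly)]
  comp[is.na(comp)] <- "autosome"
  masked <- stringi::stri_count_charclass(assembly, "[acgt]")
  known <- stringi::stri_count_charclass(assembly, "[ACGTacgt]")
  total <- nchar(assembly)
  if (sum(masked) == 0) {
    warn("no lowercase bases found; is the assembly soft-masked?")
  }
  per <- tibble(compartment = comp, total = total, known = known,
                masked = masked) |>
    group_by(.data$compartment) |>
    summarise(n_scaffolds = dplyr::n(), total_bases = sum(.data$total),
              known_bases = sum(.data$known),
              masked_bases = sum(.data$masked), .groups = "drop")
  all_row <- summarise(per, compartment = "all",
                       n_scaffolds = sum(.data$n_scaffolds),
                       total_bases = sum(.data$total_bases),
                       known_bases = sum(.data$known_bases),
                       masked_bases = sum(.data$masked_bases))
  bind_rows(per, all_row) |>
    mutate(masked_fraction = ifelse(.data$known_bases > 0,
                                    .data$masked_bases / .data$known_bases,
                                    0))
}

#' Read a RepeatMasker .out annotation table
#'
#' Parses the whitespace-delimited dialect (two header lines and a blank
#' line, then one row per annotation). Coordinates are converted from the
#' 1-based closed dialect to 0-based half-open; the class is the part of the
#' class/family column before any "/".
#'
#' @param path .out file.
#' @return tibble with \code{scaffold}, \code{start}, \code{end},
#'   \code{class}, \code{repeat_name}.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  is_data <- grepl("^\\s*\\d+\\s", lines)
  if (!any(is_data)) {
    return(tibble(scaffold = character(0), start = integer(0),
                  end = integer(0), class = character(0),
                  repeat_name = character(0)))
  }
  df <- read.table(text = lines[is_data], header = FALSE, fill = TRUE,
                   stringsAsFactors = FALSE)
  tibble(
    scaffold = as.character(df[[5]]),
    start = as.integer(df[[6]]) - 1L,
    end = as.integer(df[[7]]),
    class = sub("/.*$", "", as.character(df[[11]])),
    repeat_name = as.character(df[[10]])
  )
}

#' Per-class repeat fractions per compartment
#'
#' Overlapping annotations of one class are flattened (unioned) before
#' summing, so a base never counts twice for a class. Fractions are over the
#' compartment's known (non-N) bases.
#'
#' @param annotation tibble from [read_repeatmasker_out()] (or with the same
#'   columns, 0-based half-open).
#' @param assembly named character vector.
#' @param calls scaffold calls as in [masked_fraction()].
#' @return tibble with \code{compartment}, \code{class}, \code{bases},
#'   \code{fraction}.
#' @export
class_fractions <- function(annotation, assembly, calls) {
  lens <- setNames(nchar(assembly), names(assembly))
  bad <- annotation$scaffold[!(annotation$scaffold %in% names(lens)) |
                               annotation$end > lens[annotation$scaffold] |
                               annotation$start < 0]
  if (length(bad) > 0) {
    abort("annotation coordinates outside assembly bounds on: ",
          paste(unique(bad), collapse = ", "))
  }
  comp_tbl <- suppressWarnings(masked_fraction(assembly, calls)) |>
    select("compartment", "known_bases")
  comp <- if ("compartment" %in% names(calls)) calls$compartment
          else compartment_of_calls(calls$call)
  comp <- setNames(comp, calls$scaffold)
  cc <- unname(comp[annotation$scaffold])
  cc[is.na(cc)] <- "autosome"
  ann <- mutate(annotation, compartment = cc)
  flat <- ann |>
    group_by(.data$compartment, .data$class, .data$scaffold) |>
    dplyr::group_modify(function(d, key) {
      ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L,
                                             end = d$end))
      tibble(bases = sum(IRanges::width(ir)))
    }) |>
    group_by(.data$compartment, .data$class) |>
    summarise(bases = sum(.data$bases), .groups = "drop")
  left_join(flat, comp_tbl, by = "compartment") |>
    mutate(fraction = ifelse(.data$known_bases > 0,
                             .data$bases / .data$known_bases, 0)) |>
    select("compartment", "class", "bases", "fraction")
}
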