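# Gene-level CQ. A gene is assigned X (or Y) only when BOTH its own
# library-size-normalized CQ and the CQ of its context window (the 10 kb
# region the gene lies in) pass the threshold — the joint criterion guards
# against isolated coverage artifacts.

#' Per-gene Chromosome Quotient from sexed read counts
#'
#' \code{gene_cq = (f_count / f_library) / (m_count / m_library)}, with the
#' same zero-denominator semantics as [region_cq()].
#'
#' @param female_counts,male_counts tibbles from [count_gene_reads()] for
#'   the two libraries (same genes, same order or joinable by
#'   \code{gene_id}).
#' @return tibble with \code{gene_id}, \code{scaffold}, \code{start},
#'   \code{end}, \code{f_count}, \code{m_count}, \code{f_library},
#'   \code{m_library}, \code{gene_cq}.
#' @export
gene_cq <- function(female_counts, male_counts) {
  m <- male_counts |>
    select("gene_id", m_count = "count", m_library = "library_size")
  out <- female_counts |>
    rename(f_count = "count", f_library = "library_size") |>
    left_join(m, by = "gene_id")
  if (any(out$f_library <= 0) || any(out$m_library <= 0, na.rm = TRUE)) {
    abort("library sizes must be > 0")
  }
  f_norm <- out$f_count / out$f_library
  m_norm <- out$m_count / out$m_library
  mutate(out, gene_cq = dplyr::case_when(
    m_norm > 0 ~ f_norm / m_norm,
    f_norm > 0 ~ Inf,
    TRUE ~ NA_real_
  ))
}

#' Context CQ: the window a gene lies in
#'
#' Returns the CQ of the window containing the gene midpoint (a midpoint on
#' a window boundary belongs to the later window, by the half-open
#' convention). For genes spanning several windows a length-weighted mean of
#' the defined window CQs is also reported.
#'
#' @param genes tibble with \code{gene_id}, \code{scaffold}, \code{start},
#'   \code{end}.
#' @param tagged tibble from [tag_regions()] (or [region_cq()]).
#' @return tibble with \code{gene_id}, \code{context_cq},
#'   \code{context_tag} (if tags present), \code{context_cq_weighted}.
#' @export
context_cq <- function(genes, tagged) {
  wsize <- attr(tagged, "window_size") %||% max(tagged$width)
  mid <- (genes$start + genes$end) %/% 2
  key <- paste(genes$scaffold, mid %/% wsize + 1L, sep = "\r")
  idx <- match(key, paste(tagged$scaffold, tagged$index, sep = "\r"))
  # a midpoint inside the final partial window has index beyond the nominal
  # one; clamp to the last window of the scaffold
  last <- vapply(split(tagged$index, tagged$scaffold), max, numeric(1))
  bad <- which(is.na(idx) & genes$scaffold %in% names(last))
  if (length(bad) > 0) {
    idx[bad] <- match(paste(genes$scaffold[bad], last[genes$scaffold[bad]],
                            sep = "\r"),
                      paste(tagged$scaffold, tagged$index, sep = "\r"))
  }
  weighted <- map_dbl(seq_len(nrow(genes)), function(i) {
    w <- dplyr::filter(tagged, .data$scaffold == genes$scaffold[i],
                       .data$start < genes$end[i],
                       .data$end > genes$start[i], !is.na(.data$cq),
                       is.finite(.data$cq))
    if (nrow(w) == 0) return(NA_real_)
    ov <- pmin(w$end, genes$end[i]) - pmax(w$start, genes$start[i])
    sum(w$cq * ov) / sum(ov)
  })
  tibble(
    gene_id = genes$gene_id,
    context_cq = tagged$cq[idx],
    context_tag = if ("tag" %in% names(tagged)) tagged$tag[idx] else
      NA_character_,
    context_cq_weighted = weighted
  )
}

#' Assign genes to X or Y by the joint gene + context criterion
#'
#' X iff both \code{gene_cq} and \code{context_cq} exceed \code{x_min}; Y iff
#' both fall below \code{y_max}; otherwise none. An undefined context leaves
#' the gene unassigned.
#'
#' @param gene_cqs tibble from [gene_cq()].
#' @param context_cqs tibble from [context_cq()].
#' @param thresholds a [cq_thresholds()].
#' @return \code{gene_cqs} joined with the context columns plus
#'   \code{assignment} in \{X, Y, none\}.
#' @export
assign_genes <- function(gene_cqs, context_cqs,
                         thresholds = cq_thresholds()) {
  out <- left_join(gene_cqs, context_cqs, by = "gene_id")
  mutate(out, assignment = dplyr::case_when(
    is.na(.data$gene_cq) | is.na(.data$context_cq) ~ "none",
    .data$gene_cq > thresholds$x_min &
      .data$context_cq > thresholds$x_min ~ "X",
    .data$gene_cq < thresholds$y_max &
      .data$context_cq < thresholds$y_max ~ "Y",
    TRUE ~ "none"
  ))
}
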