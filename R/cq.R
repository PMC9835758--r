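# Chromosome Quotient analysis. CQ is the female/male normalized coverage
# ratio: ~1 on autosomes (2 copies in both sexes), ~2 on the X (2 female
# copies vs 1 male), ~0 on the Y (absent in females). Windows with CQ above
# x_min are tagged X, below y_max tagged Y; scaffolds with at least
# scaffold_min_fraction of their length in X- or Y-tagged windows become
# candidates.

#' CQ classification thresholds
#'
#' Defaults follow the standard CQ screen: X signature for CQ strictly above
#' 2, Y signature strictly below 0.2, scaffold candidacy at 40 percent or
#' more of scaffold length tagged (inclusive).
#'
#' @param x_min exclusive lower bound for an X tag.
#' @param y_max exclusive upper bound for a Y tag.
#' @param scaffold_min_fraction inclusive minimum tagged-length fraction for
#'   a scaffold call.
#' @param min_window_fraction windows shorter than this fraction of the full
#'   window size are left untagged (undefined).
#' @return a \code{cq_thresholds} list.
#' @export
cq_thresholds <- function(x_min = 2, y_max = 0.2,
                          scaffold_min_fraction = 0.40,
                          min_window_fraction = 0.5) {
  stopifnot(0 < y_max, y_max < x_min)
  stopifnot(scaffold_min_fraction > 0, scaffold_min_fraction <= 1)
  structure(list(x_min = x_min, y_max = y_max,
                 scaffold_min_fraction = scaffold_min_fraction,
                 min_window_fraction = min_window_fraction),
            class = "cq_thresholds")
}

#' Per-window Chromosome Quotient
#'
#' Divides female by male RPKM in each window. Zero-denominator semantics:
#' \code{CQ = f/m} when \code{m > 0}; \code{+Inf} when \code{m = 0, f > 0}
#' (an X-consistent signal); undefined (\code{NA}) when both are 0.
#'
#' @param female,male coverage tibbles from [window_rpkm()] over the same
#'   tiling.
#' @return tibble with the window columns plus \code{f_rpkm}, \code{m_rpkm},
#'   \code{cq}.
#' @export
region_cq <- function(female, male) {
  same <- nrow(female) == nrow(male) &&
    all(female$scaffold == male$scaffold) &&
    all(female$start == male$start) && all(female$end == male$end)
  if (!same) abort("female and male tracks use different window tilings")
  out <- select(female, "scaffold", "start", "end", "index", "width",
                "partial")
  out$f_rpkm <- female$rpkm
  out$m_rpkm <- male$rpkm
  out$cq <- dplyr::case_when(
    male$rpkm > 0 ~ female$rpkm / male$rpkm,
    female$rpkm > 0 ~ Inf,
    TRUE ~ NA_real_
  )
  attr(out, "window_size") <- attr(female, "window_size") %||%
    max(out$width)
  out
}

#' Tag windows as X, Y or neutral by their CQ
#'
#' X for \code{cq > x_min} (including \code{+Inf}), Y for \code{cq < y_max},
#' neutral otherwise; windows with undefined CQ, or shorter than
#' \code{min_window_fraction} of the window size, stay \code{undefined}.
#'
#' @param records tibble from [region_cq()].
#' @param thresholds a [cq_thresholds()].
#' @return `records` with a \code{tag} column.
#' @export
tag_regions <- function(records, thresholds = cq_thresholds()) {
  wsize <- attr(records, "window_size") %||% max(records$width)
  too_short <- records$width < thresholds$min_window_fraction * wsize
  out <- mutate(records, tag = dplyr::case_when(
    too_short | is.na(.data$cq) ~ "undefined",
    .data$cq > thresholds$x_min ~ "X",
    .data$cq < thresholds$y_max ~ "Y",
    TRUE ~ "neutral"
  ))
  attr(out, "window_size") <- wsize
  out
}

#' Call scaffolds as X or Y candidates from tagged windows
#'
#' \code{fraction_x} (resp. \code{fraction_y}) is the total length of X-
#' (Y-) tagged windows divided by scaffold length (the denominator includes
#' undefined windows). A scaffold is an X-candidate when
#' \code{fraction_x >= scaffold_min_fraction}, a Y-candidate analogously; if
#' both qualify the larger fraction wins and an exact tie is left unassigned
#' with a warning. \code{average_cq} is the mean of defined, finite window
#' CQs (the number excluded as infinite is reported).
#'
#' @param tagged tibble from [tag_regions()].
#' @param thresholds a [cq_thresholds()].
#' @return tibble with one row per scaffold: \code{scaffold}, \code{length},
#'   \code{n_windows}, \code{fraction_x}, \code{fraction_y},
#'   \code{average_cq}, \code{n_cq_infinite}, \code{n_cq_undefined},
#'   \code{call}.
#' @export
call_scaffolds <- function(tagged, thresholds = cq_thresholds()) {
  out <- tagged |>
    group_by(.data$scaffold) |>
    summarise(
      length = sum(.data$width),
      n_windows = dplyr::n(),
      fraction_x = sum(.data$width[.data$tag == "X"]) / .data$length,
      fraction_y = sum(.data$width[.data$tag == "Y"]) / .data$length,
      average_cq = mean(.data$cq[is.finite(.data$cq)]),
      n_cq_infinite = sum(is.infinite(.data$cq)),
      n_cq_undefined = sum(is.na(.data$cq)),
      .groups = "drop"
    )
  f <- thresholds$scaffold_min_fraction
  x_ok <- out$fraction_x >= f
  y_ok <- out$fraction_y >= f
  tie <- x_ok & y_ok & out$fraction_x == out$fraction_y
  if (any(tie)) {
    warn(paste0("X/Y fraction tie; leaving unassigned: ",
                paste(out$scaffold[tie], collapse = ", ")))
  }
  out$call <- dplyr::case_when(
    tie ~ "unassigned",
    x_ok & (!y_ok | out$fraction_x > out$fraction_y) ~ "X-candidate",
    y_ok ~ "Y-candidate",
    TRUE ~ "unassigned"
  )
  out
}
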