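# ggplot2 views of the two headline result types: per-window CQ along
# scaffolds and Y-unique-region density along chromosome-scale scaffolds.

#' Plot per-window CQ along scaffolds
#'
#' Points at window midpoints, with horizontal lines at the X and Y
#' thresholds; CQ is shown on a log2-friendly axis with infinite/undefined
#' windows dropped.
#'
#' @param tagged tibble from [tag_regions()].
#' @param scaffolds optional character vector restricting the facets.
#' @param thresholds a [cq_thresholds()] (for the guide lines).
#' @return a ggplot object.
#' @export
plot_cq_windows <- function(tagged, scaffolds = NULL,
                            thresholds = cq_thresholds()) {
  d <- dplyr::filter(tagged, is.finite(.data$cq))
  if (!is.null(scaffolds)) {
    d <- dplyr::filter(d, .data$scaffold %in% scaffolds)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                  y = .data$cq,
                                  colour = .data$tag)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = c(thresholds$y_max, thresholds$x_min),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(X = "#d95f02", Y = "#7570b3",
                                            neutral = "grey60",
                                            undefined = "grey85")) +
    ggplot2::facet_wrap(~scaffold, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "CQ (female/male RPKM)",
                  colour = "tag") +
    ggplot2::theme_minimal()
}

#' Plot Y-unique-region density along scaffolds
#'
#' Bars of Y-unique bases per bin (default 1.8 Mb), one facet per scaffold:
#' a local spike inside an otherwise autosomal scaffold is the signature of
#' misassembled Y material.
#'
#' @param density tibble from [density_track()].
#' @param scaffolds optional facet restriction.
#' @return a ggplot object.
#' @export
plot_y_density <- function(density, scaffolds = NULL) {
  d <- density
  if (!is.null(scaffolds)) {
    d <- dplyr::filter(d, .data$scaffold %in% scaffolds)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                  y = .data$n_bases)) +
    ggplot2::geom_col(width = (d$end - d$start) * 0.9, fill = "#7570b3") +
    ggplot2::facet_wrap(~scaffold, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "Y-unique bases per bin") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a pipeline run
#'
#' @param object a \code{sexscan_run}.
#' @param type \code{"cq"} (per-window CQ) or \code{"density"} (Y-unique
#'   density).
#' @param ... passed on to the underlying plot function.
#' @return a ggplot object.
#' @export
autoplot.sexscan_run <- function(object, type = c("cq", "density"), ...) {
  type <- match.arg(type)
  if (type == "cq") {
    plot_cq_windows(object$cq_windows,
                    thresholds = object$config$thresholds, ...)
  } else {
    plot_y_density(object$y_density, ...)
  }
}
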