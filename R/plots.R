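#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot caller support of a consensus set
#'
#' Bar chart of circles per supporting-caller combination, the usual way to
#' show inter-caller agreement behind a k-of-n consensus rule.
#'
#' @param object A [build_consensus()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot circ_consensus_tbl
#' @export
autoplot.circ_consensus_tbl <- function(object, ...) {
  dat <- dplyr::count(tibble::as_tibble(object), .data$supporting_callers,
                      name = "n_circles")
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$supporting_callers, -.data$n_circles),
    y = .data$n_circles
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "supporting callers", y = "circRNAs",
                  title = "Consensus support across circRNA callers") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot predicted ORFs on their circles
#'
#' Linearized view: one horizontal segment per ORF from its start offset
#' over its coding length (in circle passes on the x axis), coloured by
#' junction-spanning status. Rolling-circle ORFs visibly extend past pass 1.
#'
#' @param object A [find_circular_orfs()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot circ_orf_tbl
#' @export
autoplot.circ_orf_tbl <- function(object, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::mutate(
      x_start = .data$start_offset / .data$circle_length,
      x_end = (.data$start_offset + .data$coding_length) / .data$circle_length
    )
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$x_start, xend = .data$x_end,
    y = .data$orf_id, yend = .data$orf_id,
    colour = .data$junction_spanning
  )) +
    ggplot2::geom_segment(linewidth = 2) +
    ggplot2::geom_vline(xintercept = 1:3, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "circle passes from ORF start",
                  y = NULL, colour = "junction-spanning",
                  title = "Circular ORFs (dashed lines mark junction crossings)") +
    ggplot2::theme_minimal()
}

#' Plot PRM light/heavy ratios
#'
#' Per-peptide points across samples on a log2 scale, the standard display
#' for targeted relative quantification.
#'
#' @param object A [compute_prm_ratios()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prm_ratio_tbl
#' @export
autoplot.prm_ratio_tbl <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(
    x = .data$peptide, y = .data$ratio, colour = .data$sample
  )) +
    ggplot2::geom_point(size = 2, position = ggplot2::position_dodge(0.4)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = NULL, y = "endogenous / heavy ratio (log2 scale)",
                  title = "PRM relative quantification") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
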