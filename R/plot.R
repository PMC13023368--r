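# ggplot2 views of the main result types

#' Plot a coverage track with optional transcript boundaries
#'
#' @param track tibble with `pos`, `coverage` (one locus region).
#' @param boundaries optional one-row tibble from
#'   [boundary_from_coverage()].
#' @return a ggplot.
#' @export
plot_coverage <- function(track, boundaries = NULL) {
  p <- ggplot2::ggplot(track, ggplot2::aes(x = .data$pos, y = .data$coverage)) +
    ggplot2::geom_area(fill = "grey60") +
    ggplot2::labs(x = "position (bp)", y = "coverage") +
    ggplot2::theme_minimal()
  if (!is.null(boundaries) && !is.na(boundaries$tx_start)) {
    p <- p + ggplot2::geom_vline(xintercept = c(boundaries$tx_start,
                                                boundaries$tx_end),
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Candidate tiers per species
#'
#' @param object a `tq_result`.
#' @param ... unused.
#' @return a ggplot bar chart of candidate counts by tier and species.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.tq_result <- function(object, ...) {
  cand <- object$candidates
  if (nrow(cand) == 0L) stop("no candidates to plot", call. = FALSE)
  ggplot2::ggplot(cand, ggplot2::aes(x = .data$species, fill = .data$tier)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(values = c(HIGH = "#1b9e77", MEDIUM = "#d95f02",
                                          LOW = "grey70"), drop = FALSE) +
    ggplot2::labs(x = NULL, y = "TR candidates", fill = "tier") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Presence/absence matrix of the three telomerase characters
#'
#' @param presence tibble from a `tq_result` (`species`,
#'   `telomere_motif`, `tr`, `tert`, `status`).
#' @return a ggplot tile map.
#' @export
plot_presence <- function(presence) {
  long <- tidyr::pivot_longer(presence,
                              cols = c("telomere_motif", "tr", "tert"),
                              names_to = "character", values_to = "state")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$character, y = .data$species,
                                     fill = .data$state)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(present = "#1b9e77",
                                          absent = "#d95f02",
                                          unknown = "grey80")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
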