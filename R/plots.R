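# ggplot2 displays for the main result types.

#' Heatmap of within-taxon Kendall's tau-b
#'
#' Tiles show tau for each (taxon, dnd feature) pair; statistically
#' unachievable pairs (too few genomes, or the feature/prophages absent
#' from the whole taxon) are crossed out.
#'
#' @param scan Tibble from [within_taxon_scan()].
#' @return A ggplot object.
#' @export
plot_cooccur_heatmap <- function(scan) {
  crosses <- dplyr::filter(scan, .data$flag != "ok")
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$feature, y = .data$taxon)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$tau), colour = "grey80") +
    ggplot2::geom_point(data = crosses, shape = 4, size = 3,
                        colour = "grey30") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  limits = c(-1, 1), na.value = "grey95",
                                  name = "Kendall τ-b") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bar chart of per-taxon feature occurrence
#'
#' @param occurrence Tibble from [occurrence_by_taxon()].
#' @return A ggplot object.
#' @export
plot_occurrence <- function(occurrence) {
  ggplot2::ggplot(occurrence,
                  ggplot2::aes(x = .data$feature, y = .data$occurrence,
                               fill = .data$taxon)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "occurrence (fraction of genomes)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot per-replicate relative fitness
#'
#' @param object A `fitness_result` from [relative_fitness()].
#' @param ... Unused.
#' @return A ggplot object: per-replicate W with the mean and the W = 1
#'   neutrality line.
#' @method autoplot fitness_result
#' @export
autoplot.fitness_result <- function(object, ...) {
  per <- tidy(object)
  ggplot2::ggplot(per, ggplot2::aes(x = factor(.data$replicate),
                                    y = .data$W)) +
    ggplot2::geom_hline(yintercept = 1, colour = "red",
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$mean_W, colour = "grey40") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = "replicate", y = "relative fitness W",
      title = sprintf("T%g vs T%g: W = %.3f", object$interval[2],
                      object$interval[1], object$mean_W)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
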