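# Index concordance figure.

#' Scatter of Cultural Importance against Composite Salience
#'
#' One point per species, labelled by code: the visual check that
#' actively-recalled salience and exhaustively-elicited importance tell
#' a consistent story.
#'
#' @param salience A [salience_table()] (needs `species`,
#'   `composite_s`).
#' @param ci A [ci_table()] (needs `species`, `ci`).
#' @return A ggplot object.
#' @export
plot_index_concordance <- function(salience, ci) {
  df <- dplyr::inner_join(salience[, c("species", "composite_s")],
                          ci[, c("species", "ci")], by = "species")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$composite_s, y = .data$ci)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$species),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "Composite Salience",
                  y = "Cultural Importance (CI)") +
    ggplot2::coord_cartesian(xlim = c(0, 1),
                             ylim = c(0, length(use_categories()))) +
    ggplot2::theme_classic()
}
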