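#' Plot an NMDS configuration
#'
#' Scatter of the first two NMDS axes, optionally colored by site (with
#' the stress annotated in the subtitle).
#'
#' @param object An `nmds_fit`.
#' @param meta Optional data frame with `sample` and `site` columns.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.nmds_fit <- function(object, meta = NULL, ...) {
  pts <- object$points
  if (!is.null(meta)) {
    pts <- left_join(pts, as_tibble(meta)[, c("sample", "site")], by = "sample")
  }
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$NMDS1, .data$NMDS2)) +
    ggplot2::labs(
      subtitle = sprintf("stress = %.4f", object$stress),
      x = "NMDS1", y = "NMDS2"
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  if (!is.null(meta)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$site), size = 3)
  } else {
    p + ggplot2::geom_point(size = 3)
  }
}

#' Composite heatmap of species-like-group composition
#'
#' Tile heatmap of relative group abundances (rows ordered by total
#' abundance, most abundant on top), per sample or averaged per site.
#'
#' @param comp Long composition tibble from [composition_matrix()].
#' @param trans Fill transformation (default `"sqrt"` to keep rare groups
#'   visible).
#' @return A ggplot.
#' @export
plot_composition_heatmap <- function(comp, trans = "sqrt") {
  unit <- intersect(c("sample", "site"), names(comp))[1L]
  ord <- comp |>
    group_by(.data$group_id) |>
    summarise(total = sum(.data$abundance)) |>
    arrange(.data$total)
  comp$group_id <- factor(comp$group_id, levels = ord$group_id)
  ggplot2::ggplot(comp, ggplot2::aes(.data[[unit]], .data$group_id,
                                     fill = .data$abundance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = trans, name = "relative\nabundance") +
    ggplot2::labs(x = NULL, y = "species-like group") +
    ggplot2::theme_minimal()
}

#' Per-site boxplots of alpha diversity indices
#'
#' @param diversity Tibble from [alpha_diversity()].
#' @param meta Data frame with `sample` and `site` columns.
#' @return A ggplot faceted by index (Chao1, Shannon, Simpson).
#' @export
plot_alpha_diversity <- function(diversity, meta) {
  long <- diversity |>
    left_join(as_tibble(meta)[, c("sample", "site")], by = "sample") |>
    tidyr::pivot_longer(c("chao1", "shannon", "simpson"),
                        names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$site, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
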