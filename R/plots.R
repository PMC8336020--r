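# ggplot2 display methods. Deliberately plain: points, lines and tiles —
# figure cosmetics are left to the user.

#' @export
autoplot.statis <- function(object, ...) {
  tidy(object, "loadings") |>
    dplyr::mutate(variable = stats::reorder(.data$variable, .data$Axis1)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$Axis1, y = .data$variable)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Compromise axis 1 loading", y = NULL,
                  title = "STATIS compromise: variables on axis 1")
}

#' @export
autoplot.coinertia <- function(object, ...) {
  tidy(object, "scores") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$x_Axis1, y = .data$y_Axis1)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "Metabolite block, axis 1", y = "Gene block, axis 1",
                  title = sprintf("Coinertia row scores (RV = %.2f)", object$rv))
}

#' @export
autoplot.consensus_clust <- function(object, ...) {
  ord <- object$hclust$order
  m <- object$consensus[ord, ord]
  df <- tibble::tibble(
    i = rep(seq_len(nrow(m)), ncol(m)),
    j = rep(seq_len(ncol(m)), each = nrow(m)),
    consensus = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$consensus)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue") +
    ggplot2::labs(x = NULL, y = NULL, title = "Consensus co-assignment matrix")
}

#' @export
autoplot.varpart_result <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = stats::reorder(.data$fraction, .data$value),
                                 y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Variance fraction",
                  title = "Variation partitioning")
}

#' @export
autoplot.trajectory_report <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$time_days, y = .data$Axis1,
                               colour = .data$side, group = interaction(
                                 .data$mouse, .data$side))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~subject) +
    ggplot2::labs(x = "Days from injection", y = "STATIS axis-1 score",
                  colour = "Side",
                  title = "Metabolite-profile trajectories on the tumor axis")
}
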