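#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

matrix_to_long <- function(m) {
  tibble::tibble(
    source = rep(seq_len(nrow(m)), times = ncol(m)),
    target = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.numeric(m)
  )
}

#' Heatmap of a condition network
#'
#' @param object A `condition_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.condition_network <- function(object, ...) {
  df <- matrix_to_long(object$matrix)
  ggplot2::ggplot(df, ggplot2::aes(.data$target, .data$source,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026") +
    ggplot2::labs(title = paste0("PTE network (z): ", object$condition,
                                 ", ", object$subject),
                  x = "target node", y = "source node",
                  fill = "z(PTE)") +
    ggplot2::theme_minimal()
}

#' Circular edge plot of a significant network
#'
#' Nodes on a circle sized by strength; significant directed edges drawn
#' as segments colored by the sign of their statistic.
#'
#' @param object A `stat_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stat_network <- function(object, ...) {
  n <- object$n_nodes
  ang <- 2 * pi * (seq_len(n) - 1) / n
  pos <- tibble::tibble(node = object$nodes$node,
                        x = cos(ang), y = sin(ang),
                        strength = object$nodes$strength)
  p <- ggplot2::ggplot(pos, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$strength),
                        color = "grey30") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("%d significant edges, density %.3g",
                                  nrow(object$edges), object$density))
  if (nrow(object$edges)) {
    ed <- dplyr::left_join(object$edges,
                           dplyr::rename(pos, sx = "x", sy = "y"),
                           by = c(source = "node"))
    ed <- dplyr::left_join(ed, dplyr::rename(pos, tx = "x", ty = "y"),
                           by = c(target = "node"))
    p <- p + ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$sx, y = .data$sy, xend = .data$tx,
                   yend = .data$ty,
                   color = .data$statistic > 0),
      alpha = 0.6, show.legend = FALSE)
  }
  p
}

#' Block heatmap of a multilayer graph
#'
#' @param object A `multilayer_graph`.
#' @param ... Unused.
#' @return A ggplot with state boundaries drawn over the full matrix.
#' @export
autoplot.multilayer_graph <- function(object, ...) {
  df <- matrix_to_long(object$matrix)
  n <- object$n_nodes
  brk <- n * seq_len(length(object$states) - 1) + 0.5
  ggplot2::ggplot(df, ggplot2::aes(.data$target, .data$source,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026") +
    ggplot2::geom_hline(yintercept = brk, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = brk, linewidth = 0.2) +
    ggplot2::labs(title = paste0("Multilayer graph: ",
                                 paste(object$states, collapse = " / ")),
                  x = NULL, y = NULL, fill = "weight") +
    ggplot2::theme_minimal()
}

#' Behavioral accuracy plot
#'
#' Logit-accuracy per modality and group with subject points and group
#' means.
#'
#' @param table A behavioral table (subject, group, modality, n_correct,
#'   n_trials).
#' @return A ggplot.
#' @export
plot_behavior <- function(table) {
  tab <- tibble::as_tibble(table)
  tab$logit_value <- logit_proportion(tab$n_correct, tab$n_trials)
  ggplot2::ggplot(tab, ggplot2::aes(.data$modality, .data$logit_value,
                                    color = .data$group)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(y = "logit(proportion correct)", x = NULL,
                  color = NULL) +
    ggplot2::theme_minimal()
}
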