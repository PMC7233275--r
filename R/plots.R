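#' @importFrom ggplot2 ggplot aes geom_line geom_vline geom_col geom_point
#'   geom_segment geom_text labs facet_wrap theme_minimal position_dodge
NULL

#' @method autoplot melt_features
#' @export
autoplot.melt_features <- function(object, ...) {
  df <- object$normalized
  df$derivative <- object$derivative / max(object$derivative)
  ggplot(df, aes(x = .data$temperature)) +
    geom_line(aes(y = .data$fluorescence)) +
    geom_line(aes(y = .data$derivative), linetype = "dashed") +
    geom_vline(xintercept = object$tm, colour = "red", linetype = "dotted") +
    labs(x = "Temperature (°C)", y = "Normalised fluorescence",
         subtitle = sprintf("Tm = %.2f °C (dashed: scaled -dF/dT)",
                            object$tm)) +
    theme_minimal()
}

#' @method autoplot hrm_clusters
#' @export
autoplot.hrm_clusters <- function(object, ...) {
  df <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    cbind(object$normalized[[i]],
          well_id = object$well_id[i],
          cluster = factor(object$cluster[i]),
          group_id = if ("group_id" %in% names(object)) object$group_id[i]
                     else "all")
  })
  ggplot(df, aes(x = .data$temperature, y = .data$fluorescence,
                 group = .data$well_id, colour = .data$cluster)) +
    geom_line(alpha = 0.7) +
    facet_wrap(~group_id) +
    labs(x = "Temperature (°C)", y = "Normalised fluorescence",
         colour = "Cluster") +
    theme_minimal()
}

#' @method autoplot hrm_difference
#' @export
autoplot.hrm_difference <- function(object, ...) {
  ggplot(object, aes(x = .data$temperature, y = .data$delta_fluorescence,
                     group = .data$well_id)) +
    geom_line(alpha = 0.7) +
    labs(x = "Temperature (°C)",
         y = sprintf("Δ fluorescence vs %s", attr(object, "reference"))) +
    theme_minimal()
}

#' Bar-chart summary of discrimination metrics
#'
#' The usual per-haplotype sensitivity/specificity/accuracy summary of
#' a scored replicate matrix.
#'
#' @param summary tibble from [score_discrimination()].
#' @export
plot_discrimination <- function(summary) {
  long <- tidyr::pivot_longer(
    summary[c("haplotype", "sensitivity", "specificity", "accuracy")],
    -"haplotype", names_to = "metric", values_to = "percent")
  ggplot(long, aes(x = .data$haplotype, y = .data$percent,
                   fill = .data$metric)) +
    geom_col(position = position_dodge()) +
    labs(x = "Haplotype", y = "%", fill = NULL) +
    theme_minimal()
}

#' @method autoplot hrm_amova
#' @export
autoplot.hrm_amova <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$source, y = .data$percent)) +
    geom_col() +
    labs(x = NULL, y = "% of molecular variance") +
    theme_minimal()
}

#' @method autoplot hrm_spnet
#' @export
autoplot.hrm_spnet <- function(object, ...) {
  g <- as_igraph(object)
  set.seed(1)
  xy <- igraph::layout_with_fr(g)
  nodes <- cbind(object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- object$edges
  edges$x <- nodes$x[match(edges$from, nodes$id)]
  edges$y <- nodes$y[match(edges$from, nodes$id)]
  edges$xend <- nodes$x[match(edges$to, nodes$id)]
  edges$yend <- nodes$y[match(edges$to, nodes$id)]
  sz <- if (all(is.na(nodes$frequency))) 3 else 1 + 4 * sqrt(
    nodes$frequency / max(nodes$frequency, na.rm = TRUE))
  ggplot() +
    geom_segment(data = edges, aes(x = .data$x, y = .data$y,
                                   xend = .data$xend, yend = .data$yend)) +
    geom_point(data = nodes, aes(x = .data$x, y = .data$y), size = sz,
               colour = "steelblue") +
    geom_text(data = nodes, aes(x = .data$x, y = .data$y,
                                label = .data$id), vjust = -1.2) +
    geom_text(data = edges,
              aes(x = (.data$x + .data$xend) / 2,
                  y = (.data$y + .data$yend) / 2,
                  label = .data$steps), colour = "grey40") +
    labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}
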