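#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ranked CMP table
#'
#' Pixel count against abundance rank, the whole-image view of CMP
#' diversity.
#'
#' @param object A `cmp_table`.
#' @param n Ranks shown (default all).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cmp_table <- function(object, n = nrow(object), ...) {
  dat <- object[seq_len(min(n, nrow(object))), ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$count)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(x = "CMP rank (0 = most abundant)", y = "Pixels",
                  title = "Ranked CMP frequencies") +
    ggplot2::theme_minimal()
}

#' Per-cell marker profile line graphs
#'
#' One line per cell (marker index on the x axis, top-20-CMP fraction on
#' the y axis), optionally faceted by cluster with the cluster mean
#' overlaid — the per-cluster "signature" view.
#'
#' @param profiles Long profile tibble ([cell_profiles()] format).
#' @param clustering Optional `profile_clustering`; adds faceting by
#'   cluster and a mean-profile overlay.
#' @return A ggplot.
#' @export
plot_cell_profiles <- function(profiles, clustering = NULL) {
  p <- ggplot2::ggplot(profiles,
                       ggplot2::aes(x = .data$marker, y = .data$f,
                                    group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.45, linewidth = 0.3) +
    ggplot2::scale_x_continuous(breaks = unique(profiles$marker)) +
    ggplot2::labs(x = "Marker", y = "Fraction of top-20 CMPs") +
    ggplot2::theme_minimal()
  if (!is.null(clustering)) {
    dat <- dplyr::inner_join(profiles, tidy(clustering), by = "cell_id")
    means <- dat |>
      dplyr::group_by(.data$cluster, .data$marker) |>
      dplyr::summarise(f = mean(.data$f), .groups = "drop")
    p <- ggplot2::ggplot(dat,
                         ggplot2::aes(x = .data$marker, y = .data$f,
                                      group = .data$cell_id)) +
      ggplot2::geom_line(alpha = 0.45, linewidth = 0.3) +
      ggplot2::geom_line(data = means, colour = "red", linewidth = 0.8,
                         ggplot2::aes(group = NULL)) +
      ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
      ggplot2::scale_x_continuous(breaks = unique(profiles$marker)) +
      ggplot2::labs(x = "Marker", y = "Fraction of top-20 CMPs") +
      ggplot2::theme_minimal()
  }
  p
}

#' Plot cluster composition scoring
#'
#' Stacked per-cluster composition with the 1/3-2/3 predominance label.
#'
#' @param object A [score_clusters()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_scoring <- function(object, ...) {
  dat <- object$clusters |>
    dplyr::mutate(n_other = .data$n_total - .data$n_reference) |>
    tidyr::pivot_longer(c("n_reference", "n_other"), names_to = "side",
                        values_to = "n") |>
    dplyr::mutate(side = ifelse(.data$side == "n_reference",
                                object$reference, object$other))
  ggplot2::ggplot(dat, ggplot2::aes(x = base::factor(.data$cluster),
                                    y = .data$n, fill = .data$side)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(data = object$clusters, inherit.aes = FALSE,
                       ggplot2::aes(x = base::factor(.data$cluster),
                                    y = .data$n_total,
                                    label = .data$label),
                       vjust = -0.3, size = 2.6) +
    ggplot2::labs(x = "Cluster", y = "Cells", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a conservation summary
#'
#' Conservation totals (3-of-3 + mean 2-of-3) per column and group.
#'
#' @param object A [conservation_summary()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.conservation_summary <- function(object, ...) {
  dat <- object$summary |>
    dplyr::mutate(column = base::factor(.data$column,
                                        levels = unique(.data$column)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$column, y = .data$total,
                                    fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Column (All / lead marker)",
                  y = "Conserved CMPs (3-of-3 + mean 2-of-3)", fill = NULL) +
    ggplot2::theme_minimal()
}

hclust_segments <- function(h) {
  n <- length(h$order)
  leaf_x <- numeric(n); leaf_x[h$order] <- seq_len(n)
  node_x <- numeric(nrow(h$merge))
  xpos <- function(j) if (j < 0) leaf_x[-j] else node_x[j]
  ypos <- function(j) if (j < 0) 0 else h$height[j]
  segs <- vector("list", nrow(h$merge))
  for (i in seq_len(nrow(h$merge))) {
    a <- h$merge[i, 1]; b <- h$merge[i, 2]
    xa <- xpos(a); xb <- xpos(b)
    node_x[i] <- (xa + xb) / 2
    segs[[i]] <- tibble::tibble(
      x = c(xa, xb, xa), xend = c(xa, xb, xb),
      y = c(ypos(a), ypos(b), h$height[i]),
      yend = c(h$height[i], h$height[i], h$height[i]))
  }
  dplyr::bind_rows(segs)
}

#' Plot a clustering dendrogram
#'
#' @param x A `profile_clustering` object.
#' @param labels Draw leaf labels (sensible only for small n).
#' @return A ggplot.
#' @export
plot_dendrogram <- function(x, labels = FALSE) {
  stopifnot(inherits(x, "profile_clustering"))
  segs <- hclust_segments(x$tree)
  p <- ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::labs(x = NULL, y = "Height",
                  title = sprintf("%s / %s, k = %d", x$linkage, x$metric,
                                  x$k)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (labels) {
    lab <- tibble::tibble(x = seq_along(x$tree$order),
                          label = x$tree$labels[x$tree$order])
    p <- p + ggplot2::geom_text(data = lab, angle = 90, hjust = 1,
                                size = 2.5,
                                ggplot2::aes(x = .data$x, y = 0,
                                             label = .data$label))
  }
  p
}
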