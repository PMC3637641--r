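# ggplot2 views of the main result types.

#' Plot a Rank Products result
#'
#' `type = "ri"` draws the ratio-intensity scatter (log2 ratio of group mean
#' intensities vs log2 of their product) with significant probes coloured by
#' direction; `type = "volcano"` draws log2 rank product against log2 fold
#' change (small rank product = high significance, so the y axis is
#' reversed).
#'
#' @param object An `rp_result`.
#' @param type `"ri"` or `"volcano"`.
#' @param p_cutoff Significance threshold for colouring (default 1e-4).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rp_result <- function(object, type = c("ri", "volcano"),
                               p_cutoff = 1e-4, ...) {
  type <- match.arg(type)
  if (type == "ri") {
    d <- ri_plot_data(object, p_cutoff)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_product,
                                    y = .data$log2_ratio,
                                    colour = .data$regulation)) +
      ggplot2::geom_point(size = 0.6, alpha = 0.7) +
      ggplot2::scale_colour_manual(values = c(up = "red3", down = "green4",
                                              `not significant` = "grey70")) +
      ggplot2::labs(x = "log2(product of group mean intensities)",
                    y = "log2(ratio of group mean intensities)",
                    title = object$study_name) +
      ggplot2::theme_minimal()
  } else {
    d <- volcano_plot_data(object, p_cutoff)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc, y = .data$log2_rp,
                                    colour = .data$significant)) +
      ggplot2::geom_point(size = 0.6, alpha = 0.7) +
      ggplot2::scale_y_reverse() +
      ggplot2::geom_vline(xintercept = c(-1, 1), linetype = "dotted") +
      ggplot2::scale_colour_manual(values = c(`TRUE` = "red3",
                                              `FALSE` = "grey70")) +
      ggplot2::labs(x = "log2 fold change", y = "log2 rank product",
                    title = object$study_name) +
      ggplot2::theme_minimal()
  }
}

#' Plot a GSEA running sum
#'
#' Running-sum trace with a rug of gene-set hit positions; the horizontal
#' line marks zero and the point marks the enrichment score.
#'
#' @param object A `gsea_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gsea_result <- function(object, ...) {
  d <- tidy(object)
  peak <- which.max(abs(d$running_sum))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$running_sum)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = d[peak, ], colour = "red3") +
    ggplot2::geom_rug(data = d[d$hit, ], sides = "b") +
    ggplot2::labs(x = "rank position", y = "running enrichment sum",
                  subtitle = sprintf("ES = %.3f%s", object$es,
                                     if (is.na(object$p)) "" else
                                       sprintf(", p = %.3g", object$p))) +
    ggplot2::theme_minimal()
}

#' Plot a cross-study comparison matrix
#'
#' Tile heatmap of the shared and inverted percentages, faceted by
#' direction and overlap type; cells show the one-decimal display value.
#'
#' @param object A [comparison_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.comparison_matrix <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col_study, y = .data$row_study,
                                  fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$pct_display), size = 3) +
    ggplot2::facet_grid(direction ~ type) +
    ggplot2::scale_fill_gradient(low = "white", high = "orange") +
    ggplot2::labs(x = "column study (denominator)", y = "row study",
                  fill = "% of column list") +
    ggplot2::theme_minimal()
}

#' Plot enrichment results
#'
#' Horizontal bars of -log10(p) for the top terms per category.
#'
#' @param object An `enrichment_result`.
#' @param n_terms Terms shown per category.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enrichment_result <- function(object, n_terms = 10, ...) {
  d <- as_tibble(object) |>
    dplyr::group_by(.data$category) |>
    dplyr::slice_min(.data$p, n = n_terms) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$p),
                                  y = stats::reorder(.data$term_name,
                                                     -.data$p))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~ .data$category, scales = "free_y") +
    ggplot2::labs(x = "-log10 p", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sample dendrogram
#'
#' Leaves are coloured by phenotype group so the case/control split is
#' visible at a glance.
#'
#' @param object A [cluster_samples()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sample_dendrogram <- function(object, ...) {
  hc <- object$hclust
  n <- length(hc$order)
  leaf_x <- setNames(seq_len(n), hc$labels[hc$order])
  # node coordinates from the merge matrix
  xs <- numeric(nrow(hc$merge))
  segs <- list()
  node_x <- function(i) if (i < 0) leaf_x[[hc$labels[-i]]] else xs[i]
  node_h <- function(i) if (i < 0) 0 else hc$height[i]
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    xa <- node_x(a); xb <- node_x(b)
    xs[i] <- (xa + xb) / 2
    segs[[i]] <- tibble(
      x = c(xa, xa, xb), xend = c(xa, xb, xb),
      y = c(node_h(a), hc$height[i], hc$height[i]),
      yend = c(hc$height[i], hc$height[i], node_h(b)))
  }
  leaves <- tibble(sample = names(leaf_x), x = unname(leaf_x),
                   group = unname(object$group[names(leaf_x)]))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = dplyr::bind_rows(segs),
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = -0.02 * max(hc$height),
                                    label = .data$sample,
                                    colour = .data$group),
                       angle = 90, hjust = 1, size = 3) +
    ggplot2::scale_colour_manual(values = c(case = "red3",
                                            control = "steelblue")) +
    ggplot2::labs(y = "1 - centred correlation (average linkage)", x = NULL,
                  title = object$study_name) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
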