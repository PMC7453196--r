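#' Plot CCF point estimates for a pair of samples
#'
#' Scatter of per-SNV CCF estimates in two samples — the classic view in
#' which the truncal cluster sits at (1, 1) and sample-private or subclonal
#' clusters fall on the axes or the interior.
#'
#' @param object A `ccf_matrix`.
#' @param samples Character vector of exactly two sample ids (default: the
#'   first two present).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ccf_matrix
#' @export
autoplot.ccf_matrix <- function(object, samples = NULL, ...) {
  samples <- samples %||% head(unique(object$sample_id), 2)
  if (length(samples) != 2) abort_input("need exactly two samples to plot")
  wide <- object %>%
    filter(.data$sample_id %in% samples, !is.na(.data$ccf)) %>%
    select(all_of(c("snv_id", "sample_id", "ccf"))) %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "ccf") %>%
    tidyr::drop_na()
  ggplot2::ggplot(wide, ggplot2::aes(.data[[samples[1]]], .data[[samples[2]]])) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = paste("CCF,", samples[1]), y = paste("CCF,", samples[2])) +
    ggplot2::theme_minimal()
}

#' Plot cluster CCF locations across samples
#'
#' One panel per sample; clusters ordered by size, point size proportional to
#' the number of assigned SNVs, coloured by clonality when annotated.
#'
#' @param object A `clone_clusters`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot clone_clusters
#' @export
autoplot.clone_clusters <- function(object, ...) {
  d <- tidy(object)
  aes_col <- if ("clonality" %in% names(d)) "clonality" else NULL
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$cluster_id, .data$ccf,
                                       size = .data$n_snvs)) +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "cluster", y = "CCF location", size = "SNVs") +
    ggplot2::theme_minimal()
  if (!is.null(aes_col)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$clonality))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p
}

#' Plot a clone tree
#'
#' Simple segment rendering: branch length proportional to the number of SNVs
#' in the cluster, branch width proportional to the cluster's mean CCF across
#' samples, drivers annotated on their branch.
#'
#' @param object A `clone_tree`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot clone_tree
#' @export
autoplot.clone_tree <- function(object, ...) {
  nodes <- object$nodes
  root <- nodes$cluster_id[is.na(nodes$parent_id)]
  depth_of <- function(id) {
    d <- 0
    while (!is.na(p <- nodes$parent_id[match(id, nodes$cluster_id)])) {
      d <- d + nodes$n_snvs[match(p, nodes$cluster_id)]
      id <- p
    }
    d
  }
  lay <- nodes %>%
    mutate(x0 = vapply(.data$cluster_id, depth_of, double(1)),
           x1 = .data$x0 + .data$n_snvs,
           y = match(.data$cluster_id, sort_tree_ids(nodes, root)))
  seg <- lay %>%
    left_join(lay %>% select(all_of(c("cluster_id", "y"))) %>%
                rename(parent_y = "y"),
              by = c("parent_id" = "cluster_id"))
  drv <- object$drivers %>%
    count(.data$cluster_id, name = "n_drivers") %>%
    left_join(lay, by = "cluster_id")
  p <- ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x0, xend = .data$x1,
                                       y = .data$y, yend = .data$y,
                                       linewidth = .data$mean_ccf)) +
    ggplot2::geom_segment(
      data = seg %>% filter(!is.na(.data$parent_id)),
      ggplot2::aes(x = .data$x0, xend = .data$x0,
                   y = .data$parent_y, yend = .data$y),
      linetype = "dotted", linewidth = 0.3) +
    ggplot2::geom_text(ggplot2::aes(x = .data$x1, y = .data$y,
                                    label = .data$cluster_id),
                       hjust = -0.3, size = 3) +
    ggplot2::scale_linewidth(range = c(0.3, 3)) +
    ggplot2::labs(x = "SNVs (branch length)", y = NULL,
                  linewidth = "mean CCF") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (nrow(drv) > 0) {
    p <- p + ggplot2::geom_point(data = drv,
                                 ggplot2::aes(x = (.data$x0 + .data$x1) / 2,
                                              y = .data$y),
                                 shape = 17, size = 2)
  }
  p
}

# depth-first ordering of cluster ids for plotting
sort_tree_ids <- function(nodes, root) {
  kids <- split(nodes$cluster_id[!is.na(nodes$parent_id)],
                nodes$parent_id[!is.na(nodes$parent_id)])
  out <- character(0)
  rec <- function(id) {
    out <<- c(out, id)
    for (ch in kids[[id]] %||% character(0)) rec(ch)
  }
  rec(root)
  out
}
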