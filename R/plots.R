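#' Heatmap of an all-vs-all core RMSD matrix
#'
#' Models are shown in matrix order (homolog by homolog, ranked within), so
#' planted or real cluster structure appears as blocks.
#'
#' @param dm A `dist_matrix`.
#' @return A ggplot object.
#' @export
plot_dist_matrix <- function(dm) {
  stopifnot(inherits(dm, "dist_matrix"))
  n <- length(dm$ids)
  df <- data.frame(i = rep(seq_len(n), times = n),
                   j = rep(seq_len(n), each = n),
                   rmsd = as.vector(dm$values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$rmsd)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "core RMSD [Å]") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "model index", y = "model index") +
    ggplot2::theme_minimal()
}

#' Cluster size bar chart at the terminating cutoff
#'
#' @param clusters A `clust_result`.
#' @param max_clusters Show at most this many clusters (default 20).
#' @return A ggplot object.
#' @export
plot_cluster_sizes <- function(clusters, max_clusters = 20) {
  stopifnot(inherits(clusters, "clust_result"))
  sizes <- cluster_sizes(clusters)
  k <- min(length(sizes), max_clusters)
  df <- data.frame(cluster = factor(seq_len(k)), size = sizes[seq_len(k)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$size)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "cluster (extraction order)", y = "members",
                  title = sprintf("cutoff %.1f Å (%s)",
                                  clusters$cutoff, clusters$mode)) +
    ggplot2::theme_minimal()
}
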