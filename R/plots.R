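#' @importFrom ggplot2 ggplot aes geom_point geom_tile geom_col autoplot
#'   scale_fill_gradient2 scale_color_gradient2 labs theme_minimal facet_wrap
#'   geom_hline geom_vline scale_size_area
NULL

#' Volcano plot of differential expression results
#'
#' @param de tibble from [wilcoxon_de()].
#' @param alpha adjusted-p gate drawn as a guide line.
#' @return a ggplot.
#' @export
plot_de_volcano <- function(de, alpha = 0.05) {
  ggplot(de, aes(x = .data$log2fc, y = -log10(pmax(.data$p_adj, 1e-300)),
                 color = .data$significant)) +
    geom_point(size = 0.8) +
    geom_hline(yintercept = -log10(alpha), linetype = 2) +
    facet_wrap(~cell_type) +
    labs(x = "average log2 fold change", y = "-log10 adjusted p",
         color = "significant") +
    theme_minimal()
}

#' Heatmap of scaled TF activity by cell type and condition
#'
#' @param activity tibble from [summarize_activity()].
#' @return a ggplot.
#' @export
plot_activity_heatmap <- function(activity) {
  ggplot(activity,
         aes(x = interaction(.data$cell_type, .data$condition, sep = " / "),
             y = .data$tf, fill = .data$activity_scaled)) +
    geom_tile() +
    scale_fill_gradient2(low = "#7b3294", mid = "white", high = "#008837") +
    labs(x = NULL, y = NULL, fill = "scaled\nactivity") +
    theme_minimal()
}

#' Dot summary of differential gene targeting per cell type
#'
#' @param summary tibble from [targeting_summary()].
#' @return a ggplot.
#' @export
plot_targeting_summary <- function(summary) {
  ggplot(summary, aes(x = .data$total_diff, y = .data$cell_type,
                      size = .data$n_selected, color = .data$mean_diff)) +
    geom_point() +
    geom_vline(xintercept = 0, linetype = 2) +
    scale_color_gradient2(low = "#7b3294", mid = "grey80", high = "#008837") +
    scale_size_area() +
    labs(x = "total differential targeting (case - control)", y = NULL) +
    theme_minimal()
}

#' Heatmap of focal-community Jaccard similarities
#'
#' @param ji cell_type x cell_type matrix from
#'   [focal_community_similarity()].
#' @return a ggplot.
#' @export
plot_jaccard_matrix <- function(ji) {
  df <- as_tibble(as.table(ji), .name_repair = "minimal")
  names(df) <- c("a", "b", "jaccard")
  ggplot(df, aes(x = .data$a, y = .data$b, fill = .data$jaccard)) +
    geom_tile() +
    scale_fill_gradient2(low = "white", high = "#2c7fb8", limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "Jaccard") +
    theme_minimal()
}

#' Dot plot of rewiring magnitudes
#'
#' Triangle-style dot plot: regulatory weight change as size/shape direction,
#' cooperativity change as color.
#'
#' @param records classified rewiring records.
#' @return a ggplot.
#' @export
plot_rewiring <- function(records) {
  mags <- rewiring_summary(records)$magnitudes
  ggplot(mags, aes(x = .data$mechanism_protein, y = .data$target,
                   size = abs(.data$reg_delta), color = .data$coop_delta,
                   shape = .data$reg_delta >= 0)) +
    geom_point() +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 24, `FALSE` = 25),
                                labels = c(`TRUE` = "gained", `FALSE` = "lost"),
                                name = "regulation") +
    scale_color_gradient2(low = "#8c510a", mid = "grey85", high = "#01665e") +
    scale_size_area(max_size = 6) +
    facet_wrap(~cell_type) +
    labs(x = "mechanism protein", y = "focal-TF target",
         color = "cooperation\nchange", size = "|regulation change|") +
    theme_minimal()
}

#' @rdname plot_jaccard_matrix
#' @param object a `bipartition`.
#' @param ... unused.
#' @method autoplot bipartition
#' @export
autoplot.bipartition <- function(object, ...) {
  df <- tidy(object) |> dplyr::count(.data$community, .data$role)
  ggplot(df, aes(x = factor(.data$community), y = .data$n, fill = .data$role)) +
    geom_col(position = "stack") +
    labs(x = "community", y = "nodes") +
    theme_minimal()
}

#' @rdname plot_jaccard_matrix
#' @method autoplot diff_communities
#' @export
autoplot.diff_communities <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = factor(.data$community), y = .data$score,
                 color = .data$in_focal_community)) +
    geom_point(position = ggplot2::position_jitter(width = 0.15, seed = 1)) +
    labs(x = "differential community", y = "node differential-modularity score",
         color = "focal community") +
    theme_minimal()
}
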