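#' Gene targeting scores
#'
#' The targeting score of a gene is the sum of all its in-degree edge weights
#' in the regulatory network, negative weights included.
#'
#' @param grn a `grn` object (or TF x gene weight matrix).
#' @param positive_only if `TRUE`, sum only positive weights (sensitivity
#'   analysis; default `FALSE`).
#' @return tibble `gene`, `score`.
#' @export
gene_targeting <- function(grn, positive_only = FALSE) {
  W <- if (inherits(grn, "grn")) grn$weights else as.matrix(grn)
  if (positive_only) W <- pmax(W, 0)
  tibble(gene = colnames(W), score = unname(colSums(W)))
}

#' Differential gene targeting between condition networks
#'
#' Per-gene difference of targeting scores (case minus control), z-normalized
#' within the cell type; genes strictly above the third quartile (linear
#' interpolation) of the raw differences are selected.
#'
#' @param case,ctrl `grn` objects over the identical gene universe.
#' @param focal_set optional gene set; membership is reported in
#'   `in_focal_set`.
#' @param positive_only passed to [gene_targeting()].
#' @return tibble `gene`, `cell_type`, `score_case`, `score_ctrl`, `diff`,
#'   `diff_normalized`, `selected`, `in_focal_set`.
#' @export
differential_targeting <- function(case, ctrl, focal_set = character(),
                                   positive_only = FALSE) {
  g_case <- if (inherits(case, "grn")) case$genes else colnames(case)
  g_ctrl <- if (inherits(ctrl, "grn")) ctrl$genes else colnames(ctrl)
  if (!setequal(g_case, g_ctrl)) {
    only_case <- setdiff(g_case, g_ctrl); only_ctrl <- setdiff(g_ctrl, g_case)
    abort(paste0(
      "gene universes differ between the two networks; only in case: {",
      paste(head(only_case, 5), collapse = ", "), "}, only in control: {",
      paste(head(only_ctrl, 5), collapse = ", "), "}"))
  }
  sc_case <- gene_targeting(case, positive_only)
  sc_ctrl <- gene_targeting(ctrl, positive_only)
  ct <- if (inherits(case, "grn")) case$cell_type else NA_character_
  tab <- left_join(rename(sc_case, score_case = "score"),
                   rename(sc_ctrl, score_ctrl = "score"), by = "gene") |>
    mutate(
      cell_type = ct,
      diff = .data$score_case - .data$score_ctrl,
      diff_normalized = zscore(.data$diff)
    )
  q3 <- lin_quantile(tab$diff, 0.75)
  tab |>
    mutate(
      selected = .data$diff > q3,
      in_focal_set = .data$gene %in% focal_set
    ) |>
    relocate("gene", "cell_type") |>
    arrange(dplyr::desc(.data$diff))
}

#' Hypergeometric over-representation of a gene set in a selection
#'
#' Upper-tail hypergeometric p-value of observing at least the realized
#' overlap between `selected` and `focal_set` inside `universe`.
#'
#' @param selected,focal_set,universe gene identifier vectors,
#'   `selected, focal_set` subsets of `universe`.
#' @return tibble `overlap`, `n_selected`, `n_focal`, `n_universe`, `p`.
#' @export
hypergeometric_enrichment <- function(selected, focal_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) abort("`universe` must be non-empty.")
  selected <- unique(selected); focal_set <- unique(focal_set)
  if (!all(selected %in% universe) || !all(focal_set %in% universe)) {
    abort("`selected` and `focal_set` must be subsets of `universe`.")
  }
  k <- length(intersect(selected, focal_set))
  p <- stats::phyper(k - 1, length(focal_set),
                     length(universe) - length(focal_set),
                     length(selected), lower.tail = FALSE)
  tibble(overlap = k, n_selected = length(selected),
         n_focal = length(focal_set), n_universe = length(universe), p = p)
}

#' Per-cell-type differential-targeting summary
#'
#' Dot-plot-ready totals: the summed positive and negative differential
#' targeting mass, gene counts, and both normalization conventions of the
#' total (per-gene mean and z-score total).
#'
#' @param tables list of [differential_targeting()] tibbles (one per cell
#'   type) or a single such tibble.
#' @return one-row-per-cell-type tibble.
#' @export
targeting_summary <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  bind_rows(tables) |>
    group_by(.data$cell_type) |>
    summarise(
      total_diff = sum(.data$diff),
      mean_diff = mean(.data$diff),
      total_diff_normalized = sum(.data$diff_normalized),
      positive_mass = sum(.data$diff[.data$diff > 0]),
      negative_mass = sum(.data$diff[.data$diff < 0]),
      n_selected = sum(.data$selected),
      n_genes = dplyr::n(),
      .groups = "drop"
    )
}
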