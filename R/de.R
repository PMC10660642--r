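#' Two-sided Wilcoxon rank-sum p-value
#'
#' Midranks are used throughout. When both groups have at most 8 observations
#' the p-value is computed by exact enumeration of all group assignments of
#' the pooled ranks (valid under ties); otherwise the normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y numeric vectors (case, control).
#' @return two-sided p-value in \[0, 1\].
#' @export
rank_sum_p <- function(x, y) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (nx < 1 || ny < 1) abort("both groups must be non-empty.")
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (nx <= 8 && ny <= 8) {
    # exact permutation null of the rank-sum statistic
    idx <- combn(n, nx)
    w_all <- colSums(matrix(r[idx], nrow = nx))
    dev <- abs(w_all - mu)
    return(mean(dev >= abs(w_obs - mu) - 1e-9))
  }
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)  # all values tied
  dev <- abs(w_obs - mu)
  z <- max(dev - 0.5, 0) / sqrt(sigma2)  # continuity-corrected
  min(1, 2 * pnorm(-z))
}

# Seurat-convention average log2 fold change on lognorm values
avg_log2fc <- function(x_case, x_ctrl) {
  log2(mean(expm1(x_case)) + 1) - log2(mean(expm1(x_ctrl)) + 1)
}

#' Wilcoxon rank-sum differential expression within a cell type
#'
#' Compares case vs control cells of one cell type on the lognorm layer.
#' Genes must pass the average log2 fold-change gate `|log2fc| >= lfc_min`
#' to be tested at all; tested genes get a two-sided Wilcoxon rank-sum
#' p-value and a multiplicity-adjusted p over the tested set. The returned
#' table keeps every tested gene; `significant` marks `p_adj < alpha`.
#'
#' @param expr `cell_expr`, lognorm layer.
#' @param cell_type cell type label present in both conditions.
#' @param lfc_min average log2FC gate (default 0.1).
#' @param alpha adjusted-p significance gate (default 0.05).
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @return tibble with columns `gene`, `cell_type`, `log2fc`, `p`, `p_adj`,
#'   `pct_case`, `pct_ctrl`, `direction`, `significant`, sorted by `p`.
#' @export
wilcoxon_de <- function(expr, cell_type, lfc_min = 0.1, alpha = 0.05,
                        adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  if (!inherits(expr, "cell_expr")) abort("`expr` must be a cell_expr.")
  if (expr$layer != "lognorm") abort("wilcoxon_de() needs the lognorm layer; run log_normalize() first.")
  stopifnot_scalar_number(lfc_min, "lfc_min")
  stopifnot_scalar_number(alpha, "alpha", positive = TRUE)
  case_lab <- expr$conditions[1]; ctrl_lab <- expr$conditions[2]
  in_type <- expr$cells$cell_type == cell_type
  n_case <- sum(in_type & expr$cells$condition == case_lab)
  n_ctrl <- sum(in_type & expr$cells$condition == ctrl_lab)
  if (n_case < 3 || n_ctrl < 3) {
    abort(sprintf(
      "cell type '%s' needs >= 3 cells in each condition (found %d case, %d control).",
      cell_type, n_case, n_ctrl))
  }
  vals <- as.matrix(expr$values[in_type, , drop = FALSE])
  cond <- expr$cells$condition[in_type]
  is_case <- cond == case_lab
  xc <- vals[is_case, , drop = FALSE]
  xw <- vals[!is_case, , drop = FALSE]

  lfc <- vapply(seq_len(ncol(vals)),
                function(j) avg_log2fc(xc[, j], xw[, j]), numeric(1))
  pct_case <- colMeans(xc > 0)
  pct_ctrl <- colMeans(xw > 0)
  tested <- which(abs(lfc) >= lfc_min)
  if (!length(tested)) {
    return(tibble(gene = character(), cell_type = character(),
                  log2fc = numeric(), p = numeric(), p_adj = numeric(),
                  pct_case = numeric(), pct_ctrl = numeric(),
                  direction = character(), significant = logical()))
  }
  p <- vapply(tested, function(j) rank_sum_p(xc[, j], xw[, j]), numeric(1))
  p_adj <- stats::p.adjust(p, method = ifelse(adjust == "BH", "BH", "bonferroni"))
  tibble(
    gene = expr$genes[tested],
    cell_type = cell_type,
    log2fc = lfc[tested],
    p = p,
    p_adj = p_adj,
    pct_case = pct_case[tested],
    pct_ctrl = pct_ctrl[tested],
    direction = ifelse(lfc[tested] >= 0, "up", "down"),
    significant = p_adj < alpha
  ) |>
    arrange(.data$p, .data$gene)
}

#' Binned-control gene-set module score
#'
#' Per-cell score: mean lognorm expression of the gene set minus the mean of
#' control genes drawn from the same average-expression bins (equal-frequency
#' bins; `n_ctrl` controls sampled per set gene, pooled). Adding a constant to
#' every value leaves scores unchanged.
#'
#' @param expr `cell_expr`, lognorm layer.
#' @param gene_set character vector of gene ids.
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl controls sampled per set gene per bin (default 100).
#' @param seed integer seed for control sampling.
#' @return tibble `cell_id`, `score`.
#' @export
module_score <- function(expr, gene_set, n_bins = 24, n_ctrl = 100, seed = 1L) {
  if (!inherits(expr, "cell_expr")) abort("`expr` must be a cell_expr.")
  if (expr$layer != "lognorm") abort("module_score() needs the lognorm layer.")
  n_bins <- stopifnot_count(n_bins, "n_bins")
  n_ctrl <- stopifnot_count(n_ctrl, "n_ctrl")
  members <- intersect(gene_set, expr$genes)
  if (!length(members)) abort("gene set has no member present in the matrix.")
  vals <- as.matrix(expr$values)
  avg <- colMeans(vals)
  # equal-frequency bins on average expression (rank-based, ties stable)
  bins <- ceiling(rank(avg, ties.method = "first") / length(avg) * min(n_bins, length(avg)))
  ctrl <- with_seed(seed, {
    unique(unlist(lapply(members, function(g) {
      pool <- expr$genes[bins == bins[match(g, expr$genes)]]
      sample(pool, size = min(n_ctrl, length(pool)), replace = FALSE)
    })))
  })
  score <- rowMeans(vals[, members, drop = FALSE]) -
    rowMeans(vals[, ctrl, drop = FALSE])
  tibble(cell_id = expr$cells$cell_id, score = unname(score))
}

#' Signed-signature score
#'
#' Per-cell mean of sign x centered lognorm expression over the signature
#' members present in the matrix. Flipping every sign negates every score.
#'
#' @param expr `cell_expr`, lognorm layer.
#' @param signed_set data.frame with columns `gene` and `sign` (+1/-1).
#' @return tibble `cell_id`, `score`.
#' @export
signature_score <- function(expr, signed_set) {
  if (!inherits(expr, "cell_expr")) abort("`expr` must be a cell_expr.")
  if (expr$layer != "lognorm") abort("signature_score() needs the lognorm layer.")
  signed_set <- as_tibble(signed_set)
  if (!all(c("gene", "sign") %in% names(signed_set))) {
    abort("`signed_set` needs columns `gene` and `sign`.")
  }
  keep <- signed_set$gene %in% expr$genes
  if (!any(keep)) abort("signature has no member present in the matrix.")
  signed_set <- signed_set[keep, ]
  vals <- as.matrix(expr$values[, signed_set$gene, drop = FALSE])
  centered <- sweep(vals, 2, colMeans(vals), `-`)
  score <- centered %*% signed_set$sign / nrow(signed_set)
  tibble(cell_id = expr$cells$cell_id, score = as.numeric(score))
}
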