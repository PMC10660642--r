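#' Build a signed gene x TF regulon design matrix
#'
#' One column per transcription factor retained; the entry for (gene, TF) is
#' the regulon mode (typically +1 activation / -1 repression) when the gene is
#' a target of that TF, else 0. TFs with fewer than `min_targets` targets
#' matched in `genes` are dropped and reported via the `"dropped"` attribute.
#'
#' @param regulons data.frame with columns `tf`, `target`, `mode`.
#' @param genes gene universe (row order of the design).
#' @param min_targets minimum matched targets for a TF to be retained
#'   (default 5).
#' @return numeric matrix genes x TFs with attribute `"dropped"`.
#' @export
build_design <- function(regulons, genes, min_targets = 5) {
  regulons <- as_tibble(regulons)
  if (!all(c("tf", "target", "mode") %in% names(regulons))) {
    abort("`regulons` needs columns `tf`, `target`, `mode`.")
  }
  min_targets <- stopifnot_count(min_targets, "min_targets")
  if (anyDuplicated(regulons[c("tf", "target")])) {
    abort("duplicate (tf, target) pairs in the regulon table.")
  }
  if (any(!is.finite(regulons$mode)) || any(regulons$mode == 0)) {
    abort("regulon modes must be finite and nonzero.")
  }
  matched <- regulons[regulons$target %in% genes, ]
  counts <- table(matched$tf)
  keep_tfs <- names(counts)[counts >= min_targets]
  dropped <- setdiff(unique(regulons$tf), keep_tfs)
  if (!length(keep_tfs)) {
    abort(sprintf("no TF has >= %d targets in the gene universe.", min_targets))
  }
  keep_tfs <- sort(keep_tfs)
  design <- matrix(0, nrow = length(genes), ncol = length(keep_tfs),
                   dimnames = list(genes, keep_tfs))
  matched <- matched[matched$tf %in% keep_tfs, ]
  design[cbind(match(matched$target, genes), match(matched$tf, keep_tfs))] <-
    matched$mode
  attr(design, "dropped") <- sort(dropped)
  design
}

#' Multivariate-linear-model TF activity
#'
#' Ordinary least squares of each expression profile on
#' \[intercept | design\]; the activity of a TF is the t-statistic of its
#' coefficient (coefficient / standard error). Profiles with zero residual
#' variance get `NA` activities (flagged unavailable) rather than infinities.
#'
#' @param profiles numeric vector (one profile over genes) or genes x profiles
#'   matrix, rows aligned with the design rows.
#' @param design gene x TF signed matrix from [build_design()].
#' @return TF x profiles matrix of t-statistics (a plain named vector when a
#'   single profile is supplied).
#' @export
mlm_activity <- function(profiles, design) {
  single <- is.null(dim(profiles))
  Y <- if (single) matrix(profiles, ncol = 1) else as.matrix(profiles)
  if (nrow(Y) != nrow(design)) {
    abort("profile rows must align with the design's gene rows.")
  }
  X <- cbind(`(intercept)` = 1, design)
  p <- ncol(X); g <- nrow(X)
  if (g <= p) abort("need more genes than TFs + 1 to fit the model.")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, p)]]
    # name the columns they collide with via pairwise correlation of the design
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  C <- chol2inv(qr.R(qrX))  # (X'X)^-1 in pivoted order; pivot is identity here
  B <- C %*% crossprod(X, Y)                    # p x n coefficients
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / (g - p)
  se <- sqrt(outer(diag(C), sigma2))
  tstat <- B / se
  degen <- which(sigma2 <= .Machine$double.eps * 100)
  if (length(degen)) tstat[, degen] <- NA_real_
  tstat <- tstat[-1, , drop = FALSE]            # drop the intercept row
  rownames(tstat) <- colnames(design)
  if (single) tstat[, 1] else tstat
}

#' Per-cell TF activity over an expression matrix
#'
#' Fits the multivariate linear model of [mlm_activity()] to every cell's
#' lognorm profile against the signed regulon design.
#'
#' @param expr `cell_expr`, lognorm layer.
#' @param regulons regulon table (`tf`, `target`, `mode`).
#' @param min_targets minimum matched targets per TF (default 5).
#' @return tibble `cell_id`, `tf`, `activity`.
#' @export
tf_activity <- function(expr, regulons, min_targets = 5) {
  if (!inherits(expr, "cell_expr")) abort("`expr` must be a cell_expr.")
  if (expr$layer != "lognorm") abort("tf_activity() needs the lognorm layer.")
  design <- build_design(regulons, expr$genes, min_targets = min_targets)
  tmat <- mlm_activity(Matrix::t(expr$values), design)
  colnames(tmat) <- expr$cells$cell_id
  as_tibble(as.table(tmat), .name_repair = "minimal") |>
    stats::setNames(c("tf", "cell_id", "activity")) |>
    as_tibble()
}

#' Summarize TF activity by cell type and condition
#'
#' Averages per-profile activities within each (tf, cell_type, condition),
#' z-scales across TFs within each (cell_type, condition), computes the
#' percent change of the (scaled by default) average activity between
#' conditions, and flags priorities from the empirical quartiles of the
#' percent-change distribution over all (tf, cell_type) pairs of the run.
#'
#' @param activities tibble `cell_id`, `tf`, `activity` (from [tf_activity()]).
#' @param cells cell metadata tibble (`cell_id`, `cell_type`, `condition`).
#' @param conditions character(2): (case, control) labels.
#' @param pct_on `"scaled"` (default) or `"mean"`: which activity summary the
#'   percent change is computed on.
#' @param eps guard for the percent-change denominator; TFs with
#'   `|control| < eps` get an infinite sentinel and are excluded from the
#'   quartile ranking.
#' @return tibble, one row per (tf, cell_type, condition): `activity`,
#'   `activity_scaled`, `pct_change`, `priority` in
#'   `{"above_Q3","below_Q1","none"}`.
#' @export
summarize_activity <- function(activities, cells, conditions,
                               pct_on = c("scaled", "mean"), eps = 1e-8) {
  pct_on <- match.arg(pct_on)
  activities <- as_tibble(activities)
  cells <- as_tibble(cells)
  if (length(conditions) != 2L) abort("`conditions` must be (case, control).")
  case_lab <- conditions[1]; ctrl_lab <- conditions[2]

  merged <- inner_join(activities, cells, by = "cell_id")
  have <- distinct(merged, .data$cell_type, .data$condition)
  complete_types <- have |>
    dplyr::count(.data$cell_type) |>
    filter(.data$n == 2L) |>
    pull(.data$cell_type)
  skipped <- setdiff(unique(cells$cell_type), complete_types)
  if (length(skipped)) {
    warn(paste0("cell type(s) missing a condition, skipped: ",
                paste(skipped, collapse = ", ")))
  }
  summ <- merged |>
    filter(.data$cell_type %in% complete_types) |>
    group_by(.data$tf, .data$cell_type, .data$condition) |>
    summarise(activity = mean(.data$activity, na.rm = TRUE), .groups = "drop") |>
    group_by(.data$cell_type, .data$condition) |>
    mutate(activity_scaled = zscore(.data$activity)) |>
    ungroup()

  basis <- if (pct_on == "scaled") "activity_scaled" else "activity"
  chg <- summ |>
    select(all_of(c("tf", "cell_type", "condition", basis))) |>
    tidyr::pivot_wider(names_from = "condition", values_from = all_of(basis)) |>
    mutate(
      pct_change = ifelse(
        abs(.data[[ctrl_lab]]) < eps,
        sign(.data[[case_lab]]) * Inf,
        100 * (.data[[case_lab]] - .data[[ctrl_lab]]) /
          pmax(abs(.data[[ctrl_lab]]), eps))
    ) |>
    select(all_of(c("tf", "cell_type", "pct_change")))
  finite <- chg$pct_change[is.finite(chg$pct_change)]
  q1 <- if (length(finite)) lin_quantile(finite, 0.25) else NA_real_
  q3 <- if (length(finite)) lin_quantile(finite, 0.75) else NA_real_
  chg <- chg |>
    mutate(priority = dplyr::case_when(
      !is.finite(.data$pct_change) ~ "none",
      .data$pct_change > q3 ~ "above_Q3",
      .data$pct_change < q1 ~ "below_Q1",
      TRUE ~ "none"
    ))
  left_join(summ, chg, by = c("tf", "cell_type")) |>
    arrange(.data$cell_type, .data$tf, .data$condition)
}
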