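#' Cell-by-gene expression container
#'
#' Bundles a cell x gene value matrix with per-cell metadata. The `raw` layer
#' holds nonnegative integer counts (UMI-style); the `lognorm` layer holds
#' depth-normalized log values produced by [log_normalize()].
#'
#' @param values cell x gene matrix (base or `Matrix`), rownames = cell ids,
#'   colnames = gene ids.
#' @param cells tibble/data.frame with columns `cell_id`, `cell_type`,
#'   `condition`, `sample_id`, one row per matrix row.
#' @param layer `"raw"` or `"lognorm"`.
#' @param conditions character(2), the (case, control) label pair. Defaults to
#'   the labels found in `cells$condition` (case first if named "case").
#'
#' @return A `cell_expr` object.
#' @export
cell_expr <- function(values, cells, layer = c("raw", "lognorm"),
                      conditions = NULL) {
  layer <- match.arg(layer)
  cells <- as_tibble(cells)
  required <- c("cell_id", "cell_type", "condition", "sample_id")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols)) {
    abort(paste0("`cells` metadata is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (is.null(rownames(values))) rownames(values) <- cells$cell_id
  if (nrow(values) != nrow(cells) ||
      !identical(rownames(values), as.character(cells$cell_id))) {
    abort("rows of `values` must match `cells$cell_id` exactly and in order.")
  }
  if (is.null(colnames(values))) {
    abort("`values` must carry gene identifiers as column names.")
  }
  if (anyNA(cells[required]) || any(!nzchar(unlist(cells[required])))) {
    abort("cell metadata labels must be non-empty and non-missing.")
  }
  if (is.null(conditions)) {
    conditions <- sort(unique(as.character(cells$condition)))
  }
  if (length(conditions) != 2L) {
    abort("exactly two condition labels are required (case, control).")
  }
  if (!all(cells$condition %in% conditions)) {
    abort("`cells$condition` contains labels outside the declared pair.")
  }
  if (layer == "raw") {
    v <- if (inherits(values, "sparseMatrix")) values@x else as.numeric(as.matrix(values))
    if (length(v) && (any(v < 0) || any(v != round(v)))) {
      abort("raw layer entries must be nonnegative integers.")
    }
  }
  structure(
    list(values = values, cells = cells, genes = colnames(values),
         layer = layer, conditions = conditions),
    class = "cell_expr"
  )
}

#' @export
print.cell_expr <- function(x, ...) {
  cat(sprintf("<cell_expr> %d cells x %d genes [layer: %s]\n",
              nrow(x$values), length(x$genes), x$layer))
  cat(sprintf("  cell types: %s\n",
              paste(sort(unique(x$cells$cell_type)), collapse = ", ")))
  cat(sprintf("  conditions: %s vs %s\n", x$conditions[1], x$conditions[2]))
  invisible(x)
}

#' @export
dim.cell_expr <- function(x) dim(x$values)

#' Log-normalize raw counts
#'
#' Depth-normalizes each cell to `scale` expected counts and applies
#' `log(1 + x)`: value = ln(1 + scale * count / cell_total).
#'
#' @param counts a `cell_expr` with a raw layer.
#' @param scale target counts per cell (default 1e4).
#' @return a `cell_expr` with layer `"lognorm"`.
#' @export
log_normalize <- function(counts, scale = 1e4) {
  if (!inherits(counts, "cell_expr")) abort("`counts` must be a cell_expr.")
  if (counts$layer != "raw") abort("log_normalize() needs the raw layer.")
  stopifnot_scalar_number(scale, "scale", positive = TRUE)
  totals <- Matrix::rowSums(counts$values)
  if (any(totals == 0)) {
    bad <- rownames(counts$values)[totals == 0]
    abort(paste0("cells with zero total counts cannot be normalized: ",
                 paste(head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) sprintf(" (+%d more)", length(bad) - 5) else ""))
  }
  v <- counts$values
  if (inherits(v, "sparseMatrix")) {
    v <- Matrix::Diagonal(x = scale / totals) %*% v
    v@x <- log1p(v@x)
  } else {
    v <- log1p(sweep(as.matrix(v), 1, scale / totals, `*`))
  }
  rownames(v) <- rownames(counts$values)
  colnames(v) <- colnames(counts$values)
  out <- counts
  out$values <- v
  out$layer <- "lognorm"
  out
}

#' Fraction of cells detecting a gene, per condition
#'
#' @param expr a `cell_expr`.
#' @param cell_type cell type label.
#' @param gene gene identifier.
#' @return tibble with `gene`, `cell_type`, `pct_case`, `pct_ctrl`.
#' @export
detection_fraction <- function(expr, cell_type, gene) {
  if (!inherits(expr, "cell_expr")) abort("`expr` must be a cell_expr.")
  if (!gene %in% expr$genes) abort(sprintf("unknown gene '%s'.", gene))
  if (!cell_type %in% expr$cells$cell_type) {
    abort(sprintf("unknown cell type '%s'.", cell_type))
  }
  keep <- expr$cells$cell_type == cell_type
  vals <- as.numeric(expr$values[keep, gene])
  cond <- expr$cells$condition[keep]
  case_lab <- expr$conditions[1]; ctrl_lab <- expr$conditions[2]
  tibble(
    gene = gene, cell_type = cell_type,
    pct_case = mean(vals[cond == case_lab] > 0),
    pct_ctrl = mean(vals[cond == ctrl_lab] > 0)
  )
}

# subset helper used across stages
subset_cells <- function(expr, keep) {
  out <- expr
  out$values <- expr$values[keep, , drop = FALSE]
  out$cells <- expr$cells[keep, , drop = FALSE]
  out
}
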