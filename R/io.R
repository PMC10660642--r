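#' Write an expression matrix as MTX + TSV triplet
#'
#' Standard sparse bundle: `matrix.mtx` (genes stay on columns of the source,
#' MTX stores cells x genes), `barcodes.tsv`, `features.tsv`, `metadata.tsv`.
#'
#' @param expr a `cell_expr`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_expression <- function(expr, dir) {
  if (!inherits(expr, "cell_expr")) abort("`expr` must be a cell_expr.")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(expr$values, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble(barcode = rownames(expr$values)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(tibble(feature = colnames(expr$values)),
                   file.path(dir, "features.tsv"), col_names = FALSE)
  readr::write_tsv(expr$cells, file.path(dir, "metadata.tsv"))
  invisible(dir)
}

#' Read an expression matrix written by [write_expression()]
#'
#' @param dir directory with `matrix.mtx`, `barcodes.tsv`, `features.tsv`,
#'   `metadata.tsv`.
#' @param layer layer tag of the stored values (default `"raw"`).
#' @return a `cell_expr`.
#' @export
read_expression <- function(dir, layer = "raw") {
  for (f in c("matrix.mtx", "barcodes.tsv", "features.tsv", "metadata.tsv")) {
    if (!file.exists(file.path(dir, f))) {
      abort(sprintf("missing '%s' under %s.", f, dir))
    }
  }
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  barcodes <- readr::read_tsv(file.path(dir, "barcodes.tsv"),
                              col_names = "barcode", show_col_types = FALSE)
  features <- readr::read_tsv(file.path(dir, "features.tsv"),
                              col_names = "feature", show_col_types = FALSE)
  meta <- readr::read_tsv(file.path(dir, "metadata.tsv"), show_col_types = FALSE)
  m <- as.matrix(m)
  rownames(m) <- barcodes$barcode
  colnames(m) <- features$feature
  cell_expr(m, meta, layer = layer)
}

#' Write a 3-column edge list TSV (source, target, weight)
#'
#' @param edges tibble whose first three columns are source, target, weight.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  edges <- as_tibble(edges)[, 1:3]
  names(edges) <- c("source", "target", "weight")
  readr::write_tsv(edges, path)
  invisible(path)
}

#' Read a 3-column edge list TSV
#'
#' Expects a header `source\\ttarget\\tweight`; malformed lines (wrong field
#' count, non-numeric weight) are reported with their line numbers.
#'
#' @param path TSV path.
#' @param names names for the two identifier columns (default
#'   `c("source", "target")`).
#' @return tibble `source`, `target`, `weight` (renamed per `names`).
#' @export
read_edges <- function(path, names = c("source", "target")) {
  lines <- readr::read_lines(path)
  if (!length(lines)) abort(sprintf("'%s' is empty.", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields != 3L)
  if (length(bad)) {
    abort(sprintf("malformed line(s) in '%s' (need 3 tab-separated fields): %s",
                  path, paste(head(bad, 5), collapse = ", ")))
  }
  body <- fields[-1]
  w <- suppressWarnings(as.numeric(vapply(body, `[[`, "", 3)))
  if (anyNA(w)) {
    abort(sprintf("non-numeric weight at line(s) of '%s': %s", path,
                  paste(head(which(is.na(w)) + 1L, 5), collapse = ", ")))
  }
  out <- tibble(
    a = vapply(body, `[[`, "", 1),
    b = vapply(body, `[[`, "", 2),
    weight = w
  )
  base::names(out)[1:2] <- names
  out
}

#' Read named gene sets (GMT or one-gene-per-line)
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`; a plain list
#' file (one gene per line, no tabs) yields a single set named after the
#' file.
#'
#' @param path input path.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort(sprintf("'%s' contains no gene sets.", path))
  if (!any(grepl("\t", lines))) {
    out <- list(lines)
    names(out) <- tools::file_path_sans_ext(basename(path))
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    abort(sprintf("GMT line(s) with fewer than 3 fields in '%s': %s", path,
                  paste(head(short, 5), collapse = ", ")))
  }
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, "", 1))
}

#' Write named gene sets as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  if (is.null(names(sets))) abort("`sets` must be named.")
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Serialize a GRN as a long-format TSV
#'
#' @param grn a `grn`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grn <- function(grn, path) {
  write_edges(tidy(grn), path)
}
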