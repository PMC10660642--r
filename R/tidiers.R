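#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a regulatory network into a long edge tibble
#'
#' @param x a `grn`.
#' @param ... unused.
#' @return tibble `tf`, `gene`, `weight`, `cell_type`, `condition`.
#' @method tidy grn
#' @export
tidy.grn <- function(x, ...) {
  tibble(
    tf = rep(x$tfs, times = length(x$genes)),
    gene = rep(x$genes, each = length(x$tfs)),
    weight = as.vector(x$weights),
    cell_type = x$cell_type,
    condition = x$condition
  )
}

#' One-row summary of a regulatory network fit
#'
#' @param x a `grn`.
#' @param ... unused.
#' @return tibble with dimensions, convergence and weight summaries.
#' @method glance grn
#' @export
glance.grn <- function(x, ...) {
  tibble(
    n_tfs = length(x$tfs), n_genes = length(x$genes),
    iterations_run = x$iterations_run, converged = x$converged,
    final_delta = if (length(x$deltas)) x$deltas[length(x$deltas)] else NA_real_,
    mean_weight = mean(x$weights),
    frac_positive = mean(x$weights > 0),
    cell_type = x$cell_type, condition = x$condition
  )
}

#' Tidy a bipartite partition
#'
#' @param x a `bipartition`.
#' @param ... unused.
#' @return the assignment tibble (`node`, `role`, `community`).
#' @method tidy bipartition
#' @export
tidy.bipartition <- function(x, ...) as_tibble(x$assignment)

#' One-row summary of a bipartite partition
#' @param x a `bipartition`.
#' @param ... unused.
#' @method glance bipartition
#' @export
glance.bipartition <- function(x, ...) {
  tibble(modularity = x$modularity, n_communities = x$n_communities,
         n_nodes = nrow(x$assignment), seed = x$seed)
}

#' Tidy a differential-community result
#'
#' @param x a `diff_communities`.
#' @param ... unused.
#' @return node-level tibble with community ids, differential-modularity
#'   scores and focal-community membership.
#' @method tidy diff_communities
#' @export
tidy.diff_communities <- function(x, ...) {
  x$node_scores |>
    mutate(in_focal_community = .data$node %in% x$focal_members)
}

#' One-row summary of a differential-community result
#' @param x a `diff_communities`.
#' @param ... unused.
#' @method glance diff_communities
#' @export
glance.diff_communities <- function(x, ...) {
  tibble(
    dscore = x$dscore,
    n_communities = length(unique(x$assignment$community)),
    n_nodes = nrow(x$assignment),
    focal_tf = x$focal_tf %||% NA_character_,
    focal_community_size = length(x$focal_members)
  )
}
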