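#' Positive-edge projection of a regulatory network
#'
#' Community detection operates on the positive edge weights only; edges with
#' weight <= 0 are discarded and nodes left without any positive edge are
#' dropped (reported via the `"dropped_nodes"` attribute).
#'
#' @param grn a `grn` object or TF x gene weight matrix.
#' @return tibble `tf`, `gene`, `weight` (all weights > 0).
#' @export
positive_projection <- function(grn) {
  W <- if (inherits(grn, "grn")) grn$weights else as.matrix(grn)
  keep <- which(W > 0, arr.ind = TRUE)
  if (!nrow(keep)) abort("network has no positive edge weights.")
  edges <- tibble(
    tf = rownames(W)[keep[, 1]],
    gene = colnames(W)[keep[, 2]],
    weight = W[keep]
  )
  dropped <- c(setdiff(rownames(W), edges$tf), setdiff(colnames(W), edges$gene))
  if (length(dropped)) {
    inform(paste0("dropped ", length(dropped),
                  " node(s) without positive edges."))
  }
  attr(edges, "dropped_nodes") <- dropped
  edges |> arrange(.data$tf, .data$gene)
}

# ---- internal: generic bipartite score-matrix partition optimizer ----------
#
# Maximizes S(c) = sum over (tf i, gene j) in the same community of B[i, j]
# by alternating BRIM-style label sweeps with greedy community merges, from
# two deterministic initializations (gene singletons; fast-greedy seeding on
# the positive part of B). Ties always resolve to the lowest community id.

partition_score <- function(B, tf_comm, gene_comm) {
  s <- 0
  for (c in intersect(unique(tf_comm), unique(gene_comm))) {
    s <- s + sum(B[tf_comm == c, gene_comm == c, drop = FALSE])
  }
  s
}

relabel_partition <- function(tf_comm, gene_comm) {
  lab <- c(tf_comm, gene_comm)
  new <- match(lab, unique(lab))
  list(tf = new[seq_along(tf_comm)], gene = new[-seq_along(tf_comm)])
}

sweep_side <- function(B_side, other_ind, own_comm, n_comm) {
  # B_side: nodes x other-side matrix; other_ind: other-side indicator matrix
  M <- B_side %*% other_ind                       # node x community gains
  best <- max.col(M, ties.method = "first")       # lowest community id on ties
  gains <- M[cbind(seq_len(nrow(M)), best)]
  # a node whose best attachment is negative does better detached (gain 0)
  detach <- gains < -1e-12
  out <- best
  if (any(detach)) out[detach] <- n_comm + seq_len(sum(detach))
  out
}

optimize_bipartition <- function(B, n_sweeps = 100L) {
  n_tf <- nrow(B); n_gene <- ncol(B)
  inits <- list(gene_singletons = list(tf = rep(1L, n_tf), gene = seq_len(n_gene)))
  # fast-greedy seeding on the positive part (standard unipartite projection)
  Bpos <- pmax(B, 0)
  if (sum(Bpos) > 0) {
    g <- igraph::graph_from_biadjacency_matrix(Bpos, weighted = TRUE)
    comps <- igraph::components(g)
    fg <- tryCatch(
      igraph::membership(igraph::cluster_fast_greedy(
        igraph::as_undirected(g), weights = igraph::E(g)$weight)),
      error = function(e) comps$membership)
    inits$fast_greedy <- list(tf = as.integer(fg[seq_len(n_tf)]),
                              gene = as.integer(fg[n_tf + seq_len(n_gene)]))
  }
  best <- NULL
  for (init in inits) {
    tf_comm <- init$tf; gene_comm <- init$gene
    score <- partition_score(B, tf_comm, gene_comm)
    for (round in seq_len(n_sweeps)) {
      improved <- FALSE
      # label sweeps (TF side given genes, then gene side given TFs)
      for (side_pass in 1:2) {
        lab <- relabel_partition(tf_comm, gene_comm)
        tf_comm <- lab$tf; gene_comm <- lab$gene
        K <- max(c(tf_comm, gene_comm))
        gene_ind <- matrix(0, n_gene, K)
        gene_ind[cbind(seq_len(n_gene), gene_comm)] <- 1
        tf_comm <- sweep_side(B, gene_ind, tf_comm, K)
        K <- max(c(tf_comm, gene_comm))
        tf_ind <- matrix(0, n_tf, K)
        tf_ind[cbind(seq_len(n_tf), tf_comm)] <- 1
        gene_comm <- sweep_side(t(B), tf_ind, gene_comm, K)
      }
      new_score <- partition_score(B, tf_comm, gene_comm)
      if (new_score > score + 1e-12) { score <- new_score; improved <- TRUE }
      # greedy merge phase on the community-aggregated score matrix
      repeat {
        lab <- relabel_partition(tf_comm, gene_comm)
        tf_comm <- lab$tf; gene_comm <- lab$gene
        K <- max(c(tf_comm, gene_comm))
        if (K < 2) break
        tf_ind <- matrix(0, n_tf, K)
        tf_ind[cbind(seq_len(n_tf), tf_comm)] <- 1
        gene_ind <- matrix(0, n_gene, K)
        gene_ind[cbind(seq_len(n_gene), gene_comm)] <- 1
        Bc <- t(tf_ind) %*% B %*% gene_ind
        gain <- Bc + t(Bc)
        diag(gain) <- -Inf
        mx <- which.max(gain)            # column-major: lowest pair on ties
        if (gain[mx] <= 1e-12) break
        c2 <- ((mx - 1) %/% K) + 1; c1 <- ((mx - 1) %% K) + 1
        keep <- min(c1, c2); drop_c <- max(c1, c2)
        tf_comm[tf_comm == drop_c] <- keep
        gene_comm[gene_comm == drop_c] <- keep
        score <- score + gain[mx]
        improved <- TRUE
      }
      if (!improved) break
    }
    score <- partition_score(B, tf_comm, gene_comm)
    if (is.null(best) || score > best$score + 1e-12) {
      best <- list(tf = tf_comm, gene = gene_comm, score = score)
    }
  }
  lab <- relabel_partition(best$tf, best$gene)
  list(tf = lab$tf, gene = lab$gene, score = best$score)
}

edges_to_matrix <- function(edges) {
  edges <- as_tibble(edges)
  if (!all(c("tf", "gene", "weight") %in% names(edges))) {
    abort("edge list needs columns `tf`, `gene`, `weight`.")
  }
  tfs <- sort(unique(edges$tf)); genes <- sort(unique(edges$gene))
  A <- matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))
  A[cbind(match(edges$tf, tfs), match(edges$gene, genes))] <- edges$weight
  A
}

#' Barber bipartite modularity of a partition
#'
#' `Q = (1/m) * sum_ij [A_ij - k_i d_j / m] delta(c_i, c_j)` over TF x gene
#' pairs, where `m` is the total edge weight and `k`, `d` are TF and gene
#' strengths.
#'
#' @param partition tibble `node`, `role` ("tf"/"gene"), `community`.
#' @param edges tibble `tf`, `gene`, `weight`.
#' @return scalar modularity in \[-1, 1\].
#' @export
barber_modularity <- function(partition, edges) {
  partition <- as_tibble(partition)
  A <- edges_to_matrix(edges)
  tf_part <- partition$community[match(rownames(A), partition$node)]
  gene_part <- partition$community[match(colnames(A), partition$node)]
  if (anyNA(tf_part) || anyNA(gene_part)) {
    miss <- c(rownames(A)[is.na(tf_part)], colnames(A)[is.na(gene_part)])
    abort(paste0("unassigned node(s): ", paste(head(miss, 5), collapse = ", ")))
  }
  m <- sum(A)
  B <- A / m - outer(rowSums(A), colSums(A)) / m^2
  partition_score(B, tf_part, gene_part)
}

#' Bipartite community detection by Barber modularity maximization
#'
#' Greedy agglomerative optimization with BRIM-style alternating label sweeps
#' over the modularity score matrix; deterministic (ties break to the lowest
#' community id). The returned modularity is always >= 0, the score of the
#' all-in-one partition.
#'
#' @param edges tibble `tf`, `gene`, `weight` (positive weights; see
#'   [positive_projection()]).
#' @param seed recorded on the result for provenance; the optimizer itself is
#'   deterministic.
#' @return a `bipartition`: list with `assignment` tibble (`node`, `role`,
#'   `community`), `modularity`, `n_communities`, `seed`.
#' @export
condor_partition <- function(edges, seed = 1L) {
  edges <- as_tibble(edges)
  if (!nrow(edges)) abort("empty edge list.")
  if (any(edges$weight <= 0)) abort("condor_partition() expects positive weights.")
  A <- edges_to_matrix(edges)
  m <- sum(A)
  B <- A / m - outer(rowSums(A), colSums(A)) / m^2
  opt <- optimize_bipartition(B)
  assignment <- bind_rows(
    tibble(node = rownames(A), role = "tf", community = opt$tf),
    tibble(node = colnames(A), role = "gene", community = opt$gene)
  )
  structure(
    list(assignment = assignment, modularity = opt$score,
         n_communities = length(unique(assignment$community)), seed = seed),
    class = "bipartition"
  )
}

#' @export
print.bipartition <- function(x, ...) {
  cat(sprintf("<bipartition> %d nodes in %d communities, Q = %.4f\n",
              nrow(x$assignment), x$n_communities, x$modularity))
  invisible(x)
}

#' Differential community detection between condition networks
#'
#' Scores each (TF, gene) pair by the differential modularity
#' `D_ij = w_case_ij / m_case - k_ctrl_i * d_ctrl_j / m_ctrl^2` (nodes absent
#' from the control network contribute a zero null term) and maximizes the
#' intra-community sum of D with the same optimizer as [condor_partition()].
#' Invariant to uniform rescaling of either network's weights.
#'
#' @param case_edges,ctrl_edges positive-edge tibbles (`tf`, `gene`,
#'   `weight`).
#' @param focal_tf TF whose differential community is extracted; must carry
#'   positive case edges.
#' @param seed recorded for provenance (optimizer deterministic).
#' @param baseline optional control-network `bipartition` stored on the
#'   result.
#' @return a `diff_communities`: `assignment` tibble, `node_scores` tibble
#'   (per-node summed D within its community), `focal_members` node set,
#'   `dscore` (total differential modularity), `baseline`.
#' @export
alpaca_differential <- function(case_edges, ctrl_edges, focal_tf = NULL,
                                seed = 1L, baseline = NULL) {
  A_case <- edges_to_matrix(case_edges)
  A_ctrl <- edges_to_matrix(ctrl_edges)
  tfs <- sort(union(rownames(A_case), rownames(A_ctrl)))
  genes <- sort(union(colnames(A_case), colnames(A_ctrl)))
  if (!is.null(focal_tf) && !focal_tf %in% rownames(A_case)) {
    abort(sprintf("focal TF '%s' is absent from the case network.", focal_tf))
  }
  expand <- function(A, tfs, genes) {
    out <- matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))
    out[rownames(A), colnames(A)] <- A
    out
  }
  Wc <- expand(A_case, tfs, genes)
  Ww <- expand(A_ctrl, tfs, genes)
  m_case <- sum(Wc); m_ctrl <- sum(Ww)
  if (m_case <= 0) abort("case network has no positive edge weight.")
  null_term <- if (m_ctrl > 0) outer(rowSums(Ww), colSums(Ww)) / m_ctrl^2 else 0
  D <- Wc / m_case - null_term
  opt <- optimize_bipartition(D)
  assignment <- bind_rows(
    tibble(node = tfs, role = "tf", community = opt$tf),
    tibble(node = genes, role = "gene", community = opt$gene)
  )
  tf_scores <- vapply(seq_along(tfs), function(i) {
    sum(D[i, opt$gene == opt$tf[i], drop = TRUE])
  }, numeric(1))
  gene_scores <- vapply(seq_along(genes), function(j) {
    sum(D[opt$tf == opt$gene[j], j, drop = TRUE])
  }, numeric(1))
  node_scores <- bind_rows(
    tibble(node = tfs, role = "tf", score = tf_scores, community = opt$tf),
    tibble(node = genes, role = "gene", score = gene_scores, community = opt$gene)
  )
  focal_members <- character(0)
  if (!is.null(focal_tf)) {
    fc <- opt$tf[match(focal_tf, tfs)]
    focal_members <- assignment$node[assignment$community == fc]
  }
  structure(
    list(assignment = assignment, node_scores = node_scores,
         focal_members = focal_members, dscore = opt$score,
         focal_tf = focal_tf, baseline = baseline, seed = seed),
    class = "diff_communities"
  )
}

#' @export
print.diff_communities <- function(x, ...) {
  cat(sprintf("<diff_communities> %d nodes, %d communities, D = %.4f\n",
              nrow(x$assignment), length(unique(x$assignment$community)),
              x$dscore))
  if (!is.null(x$focal_tf)) {
    cat(sprintf("  focal TF %s: community of %d nodes\n", x$focal_tf,
                length(x$focal_members)))
  }
  invisible(x)
}

#' Jaccard similarity of two node sets
#'
#' `|a intersect b| / |a union b|`; defined 0 (with a warning) when both sets
#' are empty.
#'
#' @param a,b character vectors.
#' @return value in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (!length(u)) {
    warn("both sets empty; Jaccard defined as 0.")
    return(0)
  }
  length(intersect(a, b)) / length(u)
}

#' Focal-TF community similarity across cell types
#'
#' Pairwise Jaccard similarity of the focal-TF differential-community
#' memberships.
#'
#' @param results named list of `diff_communities`, one per cell type.
#' @param genes_only compare only gene members (default `FALSE`: TFs and
#'   genes).
#' @return symmetric cell_type x cell_type matrix with unit diagonal; cell
#'   types lacking a focal community get `NA` rows/columns.
#' @export
focal_community_similarity <- function(results, genes_only = FALSE) {
  if (length(results) < 2) abort("need >= 2 cell types.")
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    abort("`results` must be named by cell type.")
  }
  members <- lapply(results, function(r) {
    m <- r$focal_members
    if (genes_only) {
      m <- intersect(m, r$assignment$node[r$assignment$role == "gene"])
    }
    m
  })
  n <- length(members)
  M <- matrix(NA_real_, n, n, dimnames = list(names(results), names(results)))
  missing_focal <- vapply(members, function(m) length(m) == 0, logical(1))
  if (any(missing_focal)) {
    warn(paste0("missing focal community for: ",
                paste(names(results)[missing_focal], collapse = ", ")))
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (!missing_focal[i] && !missing_focal[j]) {
        M[i, j] <- jaccard(members[[i]], members[[j]])
      }
    }
  }
  diag(M)[!missing_focal] <- 1
  M
}

#' Adjusted Rand agreement between two labelings
#'
#' @param a,b label vectors of equal length.
#' @return adjusted Rand index (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) abort("label vectors must have equal length.")
  tab <- table(a, b)
  s <- sum(choose(tab, 2))
  ra <- sum(choose(rowSums(tab), 2)); rb <- sum(choose(colSums(tab), 2))
  n <- length(a)
  expected <- ra * rb / choose(n, 2)
  denom <- (ra + rb) / 2 - expected
  if (denom == 0) return(1)
  (s - expected) / denom
}
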