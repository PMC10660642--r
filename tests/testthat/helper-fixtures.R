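# Shared fixtures and independent oracles. The oracles are deliberately
# naive re-derivations (enumeration, straight-line loops, hand formulas) so
# they stay independent of the package's optimized paths.

# small hand-built expression object: 2 conditions x 1 cell type
tiny_expr <- function(values, conditions = c("case", "control")) {
  n <- nrow(values)
  cells <- tibble::tibble(
    cell_id = sprintf("c%02d", seq_len(n)),
    cell_type = "A",
    condition = rep(conditions, length.out = n),
    sample_id = "s1"
  )
  rownames(values) <- cells$cell_id
  cell_expr(values, cells, layer = "lognorm", conditions = conditions)
}

expr_from_groups <- function(case_mat, ctrl_mat) {
  vals <- rbind(case_mat, ctrl_mat)
  colnames(vals) <- colnames(case_mat) %||% paste0("g", seq_len(ncol(vals)))
  cells <- tibble::tibble(
    cell_id = sprintf("c%03d", seq_len(nrow(vals))),
    cell_type = "A",
    condition = rep(c("case", "control"), c(nrow(case_mat), nrow(ctrl_mat))),
    sample_id = "s1"
  )
  rownames(vals) <- cells$cell_id
  cell_expr(vals, cells, layer = "lognorm")
}

`%||%` <- rlang::`%||%`

matrix_to_edge_tbl <- function(M) {
  idx <- which(M > 0, arr.ind = TRUE)
  tibble::tibble(tf = rownames(M)[idx[, 1]], gene = colnames(M)[idx[, 2]],
                 weight = M[idx])
}

# --- oracle: exact two-sided rank-sum p by direct enumeration --------------
oracle_rank_sum_p <- function(x, y) {
  r <- rank(c(x, y))
  nx <- length(x); n <- length(r)
  idx <- utils::combn(n, nx)
  w_all <- colSums(matrix(r[idx], nrow = nx))
  mu <- nx * (n + 1) / 2
  mean(abs(w_all - mu) >= abs(sum(r[seq_len(nx)]) - mu) - 1e-9)
}

# --- oracle: upper-tail hypergeometric p by pmf summation ------------------
oracle_hyper_p <- function(k, n_focal, n_universe, n_selected) {
  kk <- k:min(n_focal, n_selected)
  sum(choose(n_focal, kk) * choose(n_universe - n_focal, n_selected - kk)) /
    choose(n_universe, n_selected)
}

# --- oracle: all set partitions of n items (restricted growth strings) -----
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(mx + 1)) rec(c(prefix, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# --- oracle: best Barber modularity by exhaustive partition enumeration ----
oracle_best_modularity <- function(edges) {
  nodes <- c(sort(unique(edges$tf)), sort(unique(edges$gene)))
  roles <- c(rep("tf", length(unique(edges$tf))),
             rep("gene", length(unique(edges$gene))))
  best <- -Inf
  for (p in all_partitions(length(nodes))) {
    q <- barber_modularity(
      tibble::tibble(node = nodes, role = roles, community = p), edges)
    if (q > best) best <- q
  }
  best
}

# --- oracle: straight-line message-passing reference loop ------------------
# independent re-derivation: per-element Tanimoto, apply()-style z-scores
oracle_panda <- function(motif, ppi, coexpr, alpha, iters) {
  zn <- function(M) {
    za <- if (stats::sd(M) == 0) M * 0 else (M - mean(M)) / stats::sd(M)
    zr <- t(apply(M, 1, function(r) {
      if (stats::sd(r) == 0) rep(NA_real_, length(r)) else (r - mean(r)) / stats::sd(r)
    }))
    zc <- apply(M, 2, function(co) {
      if (stats::sd(co) == 0) rep(NA_real_, length(co)) else (co - mean(co)) / stats::sd(co)
    })
    zr[is.na(zr)] <- za[is.na(zr)]
    zc[is.na(zc)] <- za[is.na(zc)]
    (zr + zc) / 2
  }
  tan <- function(X, Y) {
    out <- matrix(0, nrow(X), nrow(Y))
    for (i in seq_len(nrow(X))) {
      for (j in seq_len(nrow(Y))) {
        ipv <- sum(X[i, ] * Y[j, ])
        d2 <- sum(X[i, ]^2) + sum(Y[j, ]^2) - abs(ipv)
        out[i, j] <- if (d2 <= 0) 0 else ipv / sqrt(d2)
      }
    }
    out
  }
  W <- zn(motif); P <- zn(ppi); C <- zn(coexpr)
  for (it in seq_len(iters)) {
    R <- tan(P, t(W)); A <- tan(W, C)
    W <- (1 - alpha) * W + alpha * (R + A) / 2
    P <- zn((1 - alpha) * P + alpha * tan(W, W))
    C <- zn((1 - alpha) * C + alpha * tan(t(W), t(W)))
  }
  if (alpha > 0) W <- zn(W)
  dimnames(W) <- dimnames(motif)
  W
}

# small deterministic panda inputs: 3 TFs x 4 genes
panda_toy <- function(seed = 7) {
  set.seed(seed)
  motif <- matrix(rbinom(12, 1, 0.5), 3, 4,
                  dimnames = list(paste0("t", 1:3), paste0("g", 1:4)))
  P <- matrix(runif(9), 3, 3); P <- (P + t(P)) / 2; diag(P) <- 1
  dimnames(P) <- list(paste0("t", 1:3), paste0("t", 1:3))
  X <- matrix(rnorm(40), 10, 4)
  C <- stats::cor(X)
  dimnames(C) <- list(paste0("g", 1:4), paste0("g", 1:4))
  list(motif = motif, ppi = P, coexpr = C)
}
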