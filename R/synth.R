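#' Synthetic study ground truth
#'
#' Creates the scaffold of a two-condition, multi-cell-type single-nucleus
#' study: TF and gene universes (TF nodes double as genes, so focal targets
#' can also be proteins of the cooperativity layer), per-cell-type marker
#' genes, negative-binomial baseline means and dispersions, and empty planted
#' slots to be filled by [plant_perturbation()].
#'
#' @param n_tfs number of TFs (>= 4; the first is the focal TF, the last two
#'   are mechanism proteins).
#' @param n_genes total genes including the TF genes (>= n_tfs).
#' @param cell_types character vector of cell type labels.
#' @param conditions character(2): (case, control).
#' @param n_markers_per_type marker genes with elevated means per cell type.
#' @param seed integer seed.
#' @return a `synthetic_truth` object.
#' @export
synthetic_truth <- function(n_tfs = 10, n_genes = 100,
                            cell_types = c("neuron", "astrocyte", "microglia"),
                            conditions = c("case", "control"),
                            n_markers_per_type = 5, seed = 1L) {
  n_tfs <- stopifnot_count(n_tfs, "n_tfs", min = 4L)
  n_genes <- stopifnot_count(n_genes, "n_genes", min = n_tfs)
  if (length(conditions) != 2L || conditions[1] == conditions[2]) {
    abort("`conditions` must be two distinct labels (case, control).")
  }
  if (!length(cell_types) || anyDuplicated(cell_types)) {
    abort("`cell_types` must be non-empty and unique.")
  }
  tf_names <- sprintf("TF%02d", seq_len(n_tfs))
  gene_names <- c(tf_names, sprintf("G%04d", seq_len(n_genes - n_tfs)))
  truth <- with_seed(seed, {
    markers <- list()
    pool <- setdiff(gene_names, tf_names)
    for (ct in cell_types) {
      mk <- sample(pool, min(n_markers_per_type, length(pool)))
      markers[[ct]] <- mk
      pool <- setdiff(pool, mk)
    }
    list(
      tf_names = tf_names,
      gene_names = gene_names,
      cell_types = cell_types,
      conditions = conditions,
      focal_tf = tf_names[1],
      mechanism_proteins = tf_names[c(n_tfs - 1L, n_tfs)],
      markers = markers,
      baseline_means = stats::setNames(
        exp(stats::rnorm(n_genes, mean = 1, sd = 0.8)), gene_names),
      dispersion = stats::setNames(
        stats::runif(n_genes, 0.2, 0.5), gene_names),
      planted_de = list(),
      planted_active_tf = NULL,
      planted_module = NULL,
      planted_rewired = NULL,
      de_lfc = NULL,
      module_boost = NULL,
      seed = as.integer(seed)
    )
  })
  structure(truth, class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d TFs, %d genes, %d cell types, seed %d\n",
              length(x$tf_names), length(x$gene_names), length(x$cell_types),
              x$seed))
  cat(sprintf("  planted: %d DE sets, active TF: %s, module: %s, %d rewired pairs\n",
              length(x$planted_de),
              if (is.null(x$planted_active_tf)) "none" else x$planted_active_tf$tf,
              if (is.null(x$planted_module)) "none" else
                sprintf("%d edges", nrow(x$planted_module$edges)),
              if (is.null(x$planted_rewired)) 0L else nrow(x$planted_rewired)))
  invisible(x)
}

validate_truth <- function(truth) {
  if (!inherits(truth, "synthetic_truth")) abort("not a synthetic_truth.")
  stopifnot(all(truth$baseline_means > 0), all(truth$dispersion > 0),
            length(truth$conditions) == 2L)
  planted_genes <- c(
    unlist(lapply(truth$planted_de, function(d) d$gene)),
    truth$planted_module$edges$gene,
    truth$planted_rewired$target
  )
  if (length(planted_genes) && !all(planted_genes %in% truth$gene_names)) {
    abort("planted sets reference genes outside the gene universe.")
  }
  planted_cts <- c(names(truth$planted_de),
                   truth$planted_active_tf$cell_types,
                   truth$planted_module$cell_type,
                   truth$planted_rewired$cell_type)
  if (length(planted_cts) && !all(planted_cts %in% truth$cell_types)) {
    abort("planted structure references an unknown cell type.")
  }
  invisible(truth)
}

#' Generate motif, PPI, and regulon priors
#'
#' Motif prior: TF x gene 0/1 bipartite edges at the requested density, every
#' TF guaranteed >= 1 target. PPI prior: symmetric, nonnegative, unit
#' diagonal. Regulon: the motif edges with random +1/-1 modes of regulation.
#' Deterministic given `seed`.
#'
#' @param n_tfs,n_genes universe sizes (`n_tfs >= 2`, `n_genes >= n_tfs`).
#' @param motif_density,ppi_density expected edge densities in (0, 1).
#' @param seed integer seed.
#' @param tf_names,gene_names optional identifier vectors (defaults match
#'   [synthetic_truth()] naming).
#' @return list with `motif` (tibble `tf`, `gene`, `weight`), `ppi` (tibble
#'   `source`, `target`, `weight`, symmetric incl. unit diagonal), `regulon`
#'   (tibble `tf`, `target`, `mode`).
#' @export
generate_priors <- function(n_tfs, n_genes, motif_density, ppi_density,
                            seed = 1L, tf_names = NULL, gene_names = NULL) {
  n_tfs <- stopifnot_count(n_tfs, "n_tfs", min = 2L)
  n_genes <- stopifnot_count(n_genes, "n_genes", min = n_tfs)
  for (d in list(c(motif_density, "motif_density"), c(ppi_density, "ppi_density"))) {
    v <- as.numeric(d[1])
    if (!is.finite(v) || v <= 0 || v >= 1) {
      abort(sprintf("`%s` must be inside (0, 1).", d[2]))
    }
  }
  if (is.null(tf_names)) tf_names <- sprintf("TF%02d", seq_len(n_tfs))
  if (is.null(gene_names)) {
    gene_names <- c(tf_names, sprintf("G%04d", seq_len(n_genes - n_tfs)))
  }
  with_seed(seed, {
    M <- matrix(stats::rbinom(n_tfs * n_genes, 1, motif_density),
                n_tfs, n_genes, dimnames = list(tf_names, gene_names))
    empty <- which(rowSums(M) == 0)
    for (i in empty) M[i, sample.int(n_genes, 1)] <- 1
    P <- matrix(0, n_tfs, n_tfs, dimnames = list(tf_names, tf_names))
    ut <- upper.tri(P)
    w <- stats::rbinom(sum(ut), 1, ppi_density) * stats::runif(sum(ut), 0.5, 1)
    P[ut] <- w
    P <- P + Matrix::t(P)
    diag(P) <- 1
    P <- as.matrix(P)
    idx <- which(M == 1, arr.ind = TRUE)
    regulon <- tibble(
      tf = tf_names[idx[, 1]],
      target = gene_names[idx[, 2]],
      mode = sample(c(-1, 1), nrow(idx), replace = TRUE)
    ) |> arrange(.data$tf, .data$target)
    list(
      motif = matrix_to_edges(M, c("tf", "gene")),
      ppi = matrix_to_edges(P, c("source", "target"), keep_zero = FALSE),
      regulon = regulon
    )
  })
}

matrix_to_edges <- function(M, names2, keep_zero = FALSE) {
  idx <- if (keep_zero) {
    cbind(rep(seq_len(nrow(M)), ncol(M)), rep(seq_len(ncol(M)), each = nrow(M)))
  } else {
    which(M != 0, arr.ind = TRUE, useNames = FALSE)
  }
  out <- tibble(
    a = rownames(M)[idx[, 1]],
    b = colnames(M)[idx[, 2]],
    weight = M[idx]
  ) |> arrange(.data$a, .data$b)
  names(out)[1:2] <- names2
  out
}

edges_to_prior_matrix <- function(edges, rows, cols, symmetric = FALSE) {
  edges <- as_tibble(edges)
  nm <- names(edges)[1:2]
  M <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  keep <- edges[[nm[1]]] %in% rows & edges[[nm[2]]] %in% cols
  e <- edges[keep, ]
  M[cbind(match(e[[nm[1]]], rows), match(e[[nm[2]]], cols))] <- e$weight
  if (symmetric) {
    M2 <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
    keep2 <- edges[[nm[2]]] %in% rows & edges[[nm[1]]] %in% cols
    e2 <- edges[keep2, ]
    M2[cbind(match(e2[[nm[2]]], rows), match(e2[[nm[1]]], cols))] <- e2$weight
    M <- pmax(M, M2)
  }
  M
}

#' Plant recoverable perturbations into a synthetic truth
#'
#' Fills the planted slots: `n_de_per_type` differentially expressed genes
#' per cell type (alternating sign, |log2FC| = `|de_lfc|`), one active TF
#' whose regulon targets shift by 0.5 log2 units (mode-consistently) in case
#' cells, one strengthened coexpression module tied to a TF in one cell type,
#' and four rewired (target, mechanism protein) pairs covering all four
#' regulation x cooperation categories.
#'
#' @param truth a [synthetic_truth()].
#' @param de_lfc nonzero log2 fold change for planted DE genes.
#' @param module_boost positive latent-factor scale of the planted module's
#'   case-only coexpression.
#' @param n_de_per_type planted DE genes per cell type.
#' @param module_size genes in the planted module.
#' @return the truth with all planted slots filled.
#' @export
plant_perturbation <- function(truth, de_lfc = 1, module_boost = 1,
                               n_de_per_type = 20, module_size = 10) {
  validate_truth(truth)
  if (!is.numeric(de_lfc) || de_lfc == 0) abort("`de_lfc` must be nonzero.")
  stopifnot_scalar_number(module_boost, "module_boost", positive = TRUE)
  n_de_per_type <- stopifnot_count(n_de_per_type, "n_de_per_type")
  if (n_de_per_type > length(truth$gene_names)) {
    abort("`n_de_per_type` exceeds the number of genes.")
  }
  with_seed(child_seed(truth$seed, 2L), {
    tf_named <- truth$tf_names
    plain <- setdiff(truth$gene_names, c(tf_named, unlist(truth$markers)))

    # planted DE: alternating up/down genes, distinct per cell type
    pool <- plain
    planted_de <- list()
    for (ct in truth$cell_types) {
      n_take <- min(n_de_per_type, length(pool))
      if (n_take < n_de_per_type) pool <- plain    # recycle if universe small
      g <- sample(pool, n_de_per_type)
      pool <- setdiff(pool, g)
      planted_de[[ct]] <- tibble(
        gene = g,
        lfc = de_lfc * rep_len(c(1, -1), n_de_per_type)
      )
    }

    # planted active TF: second TF, all cell types, positive direction
    active_tf <- tf_named[2]
    planted_active_tf <- list(tf = active_tf, cell_types = truth$cell_types,
                              direction = 1, shift = 0.5)

    # planted strengthened module: a 3-TF regulatory module over a block of
    # plain genes, realized in the case networks only (case-specific motif
    # support + a case-only shared latent factor in the first cell type)
    spare_tfs <- setdiff(tf_named, c(truth$focal_tf, truth$mechanism_proteins,
                                     active_tf))
    module_tfs <- spare_tfs[seq_len(min(3L, length(spare_tfs)))]
    module_genes <- sample(setdiff(plain, unlist(lapply(planted_de, `[[`, "gene"))),
                           min(module_size, length(plain)))
    planted_module <- list(
      tf = module_tfs[1], tfs = module_tfs,
      cell_type = truth$cell_types[1],
      edges = tidyr::expand_grid(tf = module_tfs, gene = module_genes),
      boost = module_boost
    )

    # planted rewiring: four targets (TF-named genes, so they are proteins of
    # the cooperativity layer) x the first mechanism protein, one per category
    mech <- truth$mechanism_proteins[1]
    rew_targets <- setdiff(spare_tfs, module_tfs)
    if (length(rew_targets) < 4) rew_targets <- spare_tfs
    if (length(rew_targets) < 4) {
      abort("need >= 4 spare TF-named genes to plant all rewiring categories.")
    }
    rew_targets <- rew_targets[1:4]
    # cooperation anchor genes: each (target, mechanism) pair gets a private
    # block of genes; when cooperation is present in a condition both
    # proteins share these motif targets (similar regulatory profiles =>
    # positive inferred cooperativity), when absent only the target keeps
    # them
    anchor_pool <- setdiff(plain, c(unlist(lapply(planted_de, `[[`, "gene")),
                                    module_genes))
    k <- max(2L, min(6L, length(anchor_pool) %/% 5))
    if (length(anchor_pool) < 5 * 2) {
      abort("gene universe too small to plant rewiring anchor blocks.")
    }
    coop_anchors <- lapply(1:4, function(i) {
      anchor_pool[seq((i - 1) * k + 1, i * k)]
    })
    decoy_anchors <- anchor_pool[seq(4 * k + 1, min(5 * k, length(anchor_pool)))]
    planted_rewired <- tibble(
      cell_type = truth$cell_types[1],
      target = rew_targets,
      mechanism_protein = mech,
      category = rewiring_categories(),
      # regulation axis: present flags (ctrl, case)
      reg_ctrl = c(FALSE, TRUE, TRUE, TRUE),
      reg_case = c(TRUE, FALSE, TRUE, TRUE),
      # cooperation axis
      coop_ctrl = c(FALSE, TRUE, FALSE, TRUE),
      coop_case = c(TRUE, FALSE, TRUE, FALSE),
      anchors = coop_anchors
    )

    out <- truth
    out$decoy_anchors <- decoy_anchors
    out$focal_gene_set <- c(rew_targets,
                            sample(setdiff(plain, module_genes),
                                   min(10, length(setdiff(plain, module_genes)))))
    out$planted_de <- planted_de
    out$planted_active_tf <- planted_active_tf
    out$planted_module <- planted_module
    out$planted_rewired <- planted_rewired
    out$de_lfc <- de_lfc
    out$module_boost <- module_boost
    validate_truth(out)
  })
}

#' Apply planted rewiring and module structure to priors
#'
#' Produces condition-specific motif and PPI priors from condition-agnostic
#' ones: planted module edges are guaranteed in the motif prior of both
#' conditions; the planted rewired pairs set the focal-TF motif edge and the
#' target-mechanism PPI edge present (1) or absent (0) per condition
#' according to their intended category. The category-to-edit mapping:
#' regulation gained/lost toggles the focal-TF -> target motif edge between
#' conditions; cooperation gained/lost toggles the target <-> mechanism PPI
#' edge.
#'
#' @param truth planted [synthetic_truth()].
#' @param priors list from [generate_priors()].
#' @return list with per-condition `motif` and `ppi` matrices
#'   (`$motif$case`, `$motif$control`, ...), regulon unchanged.
#' @export
apply_truth_to_priors <- function(truth, priors) {
  validate_truth(truth)
  M <- edges_to_prior_matrix(priors$motif, truth$tf_names, truth$gene_names)
  P <- edges_to_prior_matrix(priors$ppi, truth$tf_names, truth$tf_names,
                             symmetric = TRUE)
  diag(P) <- 1
  M_case <- M; M_ctrl <- M; P_case <- P; P_ctrl <- P
  if (!is.null(truth$planted_module)) {
    # the module is strengthened in the case networks: its TF-gene edges are
    # present in the case motif prior and absent from the control one, and
    # simulate_counts() adds the matching case-only coexpression
    me <- truth$planted_module$edges
    M_case[cbind(match(me$tf, truth$tf_names),
                 match(me$gene, truth$gene_names))] <- 1
    M_ctrl[cbind(match(me$tf, truth$tf_names),
                 match(me$gene, truth$gene_names))] <- 0
  }
  if (!is.null(truth$planted_rewired) && nrow(truth$planted_rewired)) {
    pr <- truth$planted_rewired
    all_anchors <- unlist(pr$anchors)
    # mechanism proteins carry a controlled regulatory profile: exactly the
    # anchor blocks of the pairs whose cooperation is present in a
    # condition; targets are blanked on other pairs' anchors so cooperation
    # similarity is governed by the planted flags alone
    for (mm in unique(pr$mechanism_protein)) {
      M_case[mm, ] <- 0; M_ctrl[mm, ] <- 0
    }
    for (tt in pr$target) {
      M_case[tt, all_anchors] <- 0; M_ctrl[tt, all_anchors] <- 0
      # the planted targets' regulatory in-edges are controlled too: only
      # the focal TF (per presence flag) supports them, so edge presence in
      # the inferred network tracks the planted flag rather than background
      # motif density
      M_case[, tt] <- 0; M_ctrl[, tt] <- 0
    }
    # the focal TF likewise gets a controlled profile: its curated gene set
    # in both conditions plus the planted edges per their presence flags
    if (!is.null(truth$focal_gene_set)) {
      extras <- setdiff(truth$focal_gene_set, pr$target)
      M_case[truth$focal_tf, ] <- 0; M_ctrl[truth$focal_tf, ] <- 0
      M_case[truth$focal_tf, extras] <- 1
      M_ctrl[truth$focal_tf, extras] <- 1
    }
    decoy <- truth$mechanism_proteins[length(truth$mechanism_proteins)]
    # no focal-decoy cooperativity: otherwise the decoy's (absence-marking)
    # edge feeds back into the focal edge through the responsibility message
    P_case[truth$focal_tf, decoy] <- 0; P_case[decoy, truth$focal_tf] <- 0
    P_ctrl[truth$focal_tf, decoy] <- 0; P_ctrl[decoy, truth$focal_tf] <- 0
    for (i in seq_len(nrow(pr))) {
      r <- pr[i, ]
      M_case[truth$focal_tf, r$target] <- as.numeric(r$reg_case)
      M_ctrl[truth$focal_tf, r$target] <- as.numeric(r$reg_ctrl)
      # when focal regulation is absent the target is handed to a decoy
      # regulator, so the focal in-edge is contrasted against a real one
      # rather than an empty column
      M_case[decoy, r$target] <- as.numeric(!r$reg_case)
      M_ctrl[decoy, r$target] <- as.numeric(!r$reg_ctrl)
      if (!is.null(truth$decoy_anchors)) {
        M_case[decoy, truth$decoy_anchors] <- 1
        M_ctrl[decoy, truth$decoy_anchors] <- 1
      }
      P_case[r$target, r$mechanism_protein] <- as.numeric(r$coop_case)
      P_case[r$mechanism_protein, r$target] <- as.numeric(r$coop_case)
      P_ctrl[r$target, r$mechanism_protein] <- as.numeric(r$coop_ctrl)
      P_ctrl[r$mechanism_protein, r$target] <- as.numeric(r$coop_ctrl)
      anchors <- r$anchors[[1]]
      if (length(anchors)) {
        M_case[r$target, anchors] <- 1
        M_ctrl[r$target, anchors] <- 1
        M_case[r$mechanism_protein, anchors] <- as.numeric(r$coop_case)
        M_ctrl[r$mechanism_protein, anchors] <- as.numeric(r$coop_ctrl)
      }
    }
  }
  cond <- truth$conditions
  list(
    motif = stats::setNames(list(M_case, M_ctrl), cond),
    ppi = stats::setNames(list(P_case, P_ctrl), cond),
    regulon = priors$regulon
  )
}

#' Simulate negative-binomial counts from a synthetic truth
#'
#' Per-gene means combine the baseline program, a x4 marker elevation in the
#' owning cell type, planted condition multipliers (DE genes: `2^lfc` in
#' case; active-TF targets: `2^(0.5 * mode)` in case), a per-sample lognormal
#' jitter (sigma = 0.1, three pseudo-replicates per condition), a per-cell
#' lognormal library-size factor (sigma = 0.3), and a case-only shared latent
#' factor over the planted module's genes in its cell type. Counts are drawn
#' NB(mean scaled to `depth` expected counts per cell, per-gene dispersion).
#'
#' @param truth planted or unplanted [synthetic_truth()].
#' @param cells_per_type_per_condition cells per (cell type, condition),
#'   >= 2.
#' @param depth expected total counts per cell.
#' @param seed integer seed.
#' @param regulon regulon table; required when an active TF is planted (to
#'   direct the mode-consistent shift).
#' @return a raw-layer [cell_expr()].
#' @export
simulate_counts <- function(truth, cells_per_type_per_condition = 100,
                            depth = 5000, seed = 1L, regulon = NULL) {
  validate_truth(truth)
  n_cells <- stopifnot_count(cells_per_type_per_condition,
                             "cells_per_type_per_condition", min = 2L)
  stopifnot_scalar_number(depth, "depth", positive = TRUE)
  genes <- truth$gene_names
  G <- length(genes)
  size <- 1 / truth$dispersion
  if (!is.null(truth$planted_active_tf) && is.null(regulon)) {
    warn("active TF planted but no regulon supplied; activity shift skipped.")
  }
  with_seed(seed, {
    blocks <- list()
    meta <- list()
    # per-sample baseline jitter: 3 pseudo-replicates per condition, paired
    # across conditions (replicate r shares its jitter in case and control,
    # like littermate pairs) so that the no-effect null is exchangeable
    n_rep <- 3L
    jit <- matrix(exp(stats::rnorm(G * n_rep, 0, 0.1)), G, n_rep)
    jitter <- stats::setNames(list(jit, jit), truth$conditions)
    for (ct in truth$cell_types) {
      base <- truth$baseline_means
      base[truth$markers[[ct]]] <- base[truth$markers[[ct]]] * 4
      for (cond in truth$conditions) {
        mult <- rep(1, G); names(mult) <- genes
        if (cond == truth$conditions[1]) {
          de <- truth$planted_de[[ct]]
          if (!is.null(de)) mult[de$gene] <- mult[de$gene] * 2^de$lfc
          atf <- truth$planted_active_tf
          if (!is.null(atf) && !is.null(regulon) && ct %in% atf$cell_types) {
            reg <- regulon[regulon$tf == atf$tf, ]
            mult[reg$target] <- mult[reg$target] *
              2^(atf$shift * atf$direction * reg$mode)
          }
        }
        rep_id <- rep_len(seq_len(n_rep), n_cells)
        mu_gene <- base * mult
        mu_cells <- Matrix::t(jitter[[cond]][, rep_id, drop = FALSE] * mu_gene)
        # case-only shared latent factor: correlated module overdispersion
        mod <- truth$planted_module
        if (!is.null(mod) && cond == truth$conditions[1] &&
            ct == mod$cell_type) {
          z <- stats::rnorm(n_cells, 0, 0.5 * mod$boost)
          mcols <- match(unique(mod$edges$gene), genes)
          mu_cells[, mcols] <- mu_cells[, mcols] * 2^z
        }
        # rewired regulation present in this condition: shared latent between
        # the target and the focal TF's curated targets, so the inferred
        # focal edge is supported by coexpression where (and only where) the
        # regulation is planted
        prw <- truth$planted_rewired
        if (!is.null(prw) && ct == prw$cell_type[1]) {
          extras <- setdiff(truth$focal_gene_set, prw$target)
          for (i in seq_len(nrow(prw))) {
            present <- if (cond == truth$conditions[1]) prw$reg_case[i] else prw$reg_ctrl[i]
            z <- stats::rnorm(n_cells, 0, 0.5)
            if (isTRUE(present)) {
              cols <- match(c(prw$target[i], extras), genes)
              mu_cells[, cols] <- mu_cells[, cols] * 2^z
            } else {
              # absent regulation: the target co-varies with the decoy
              # regulator's program, which runs counter to the focal TF's
              # program (mutually exclusive regulatory states)
              cols <- stats::na.omit(match(c(prw$target[i], truth$decoy_anchors), genes))
              mu_cells[, cols] <- mu_cells[, cols] * 2^z
              ecols <- match(extras, genes)
              mu_cells[, ecols] <- mu_cells[, ecols] * 2^(-0.5 * z)
            }
          }
        }
        lib <- depth * exp(stats::rnorm(n_cells, 0, 0.3)) /
          rowSums(mu_cells)
        mu_cells <- mu_cells * lib
        counts <- matrix(
          stats::rnbinom(n_cells * G, mu = as.vector(mu_cells),
                         size = rep(size, each = n_cells)),
          n_cells, G)
        colnames(counts) <- genes
        blocks[[paste(ct, cond, sep = "|")]] <- counts
        meta[[paste(ct, cond, sep = "|")]] <- tibble(
          cell_type = ct, condition = cond,
          sample_id = paste0(cond, "_rep", rep_id)
        )
      }
    }
    values <- do.call(rbind, blocks)
    cells <- bind_rows(meta) |>
      mutate(cell_id = sprintf("cell%05d", row_number())) |>
      relocate("cell_id")
    rownames(values) <- cells$cell_id
    cell_expr(values, cells, layer = "raw", conditions = truth$conditions)
  })
}

#' Directly synthesize condition networks embodying the planted truth
#'
#' Builds per-condition regulatory (TF x gene) and cooperativity (TF x TF)
#' weight matrices around Gaussian background noise, with the planted rewired
#' pairs' regulatory and cooperativity entries set to +/-`signal` exactly per
#' their intended presence flags, and the planted module's edges boosted by
#' the module boost in the case network. Used to exercise downstream stages
#' against exact, known edge weights.
#'
#' @param truth planted [synthetic_truth()].
#' @param noise_sd background weight s.d.
#' @param signal magnitude of planted present (+) / absent (-) edges.
#' @param seed integer seed.
#' @return list `case`, `control` of `grn` objects (cooperativity in `$ppi`).
#' @export
synthesize_networks <- function(truth, noise_sd = 0.1, signal = 0.8,
                                seed = 1L) {
  validate_truth(truth)
  tfs <- truth$tf_names; genes <- truth$gene_names
  with_seed(seed, {
    out <- list()
    for (cond in truth$conditions) {
      W <- matrix(stats::rnorm(length(tfs) * length(genes), 0, noise_sd),
                  length(tfs), length(genes), dimnames = list(tfs, genes))
      P <- matrix(stats::rnorm(length(tfs)^2, 0, noise_sd),
                  length(tfs), length(tfs), dimnames = list(tfs, tfs))
      P <- (P + Matrix::t(P)) / 2
      is_case <- cond == truth$conditions[1]
      pr <- truth$planted_rewired
      if (!is.null(pr)) {
        for (i in seq_len(nrow(pr))) {
          r <- pr[i, ]
          reg_flag <- if (is_case) r$reg_case else r$reg_ctrl
          coop_flag <- if (is_case) r$coop_case else r$coop_ctrl
          W[truth$focal_tf, r$target] <- ifelse(reg_flag, signal, -signal)
          P[r$target, r$mechanism_protein] <- ifelse(coop_flag, signal, -signal)
          P[r$mechanism_protein, r$target] <- P[r$target, r$mechanism_protein]
        }
      }
      mod <- truth$planted_module
      if (!is.null(mod) && is_case) {
        ii <- cbind(match(mod$edges$tf, tfs), match(mod$edges$gene, genes))
        W[ii] <- W[ii] + mod$boost
      }
      out[[cond]] <- new_grn(W, P, NULL, truth$planted_module$cell_type %||%
                               truth$cell_types[1], cond, 0L, TRUE, numeric(0))
    }
    stats::setNames(out, truth$conditions)
  })
}

#' Planted 4-block bipartite stochastic block model
#'
#' TFs and genes are split into `n_blocks` aligned groups; an edge appears
#' with probability `p_in` inside a block pair and `p_out` outside.
#'
#' @param n_tfs,n_genes node counts (divisible by `n_blocks`).
#' @param n_blocks planted community count (default 4).
#' @param p_in,p_out within/between-block edge probabilities.
#' @param seed integer seed.
#' @return list: `edges` tibble (`tf`, `gene`, `weight`), `truth` tibble
#'   (`node`, `role`, `block`).
#' @export
synthesize_sbm <- function(n_tfs = 20, n_genes = 40, n_blocks = 4,
                           p_in = 0.9, p_out = 0.05, seed = 1L) {
  tf_block <- rep(seq_len(n_blocks), each = ceiling(n_tfs / n_blocks))[seq_len(n_tfs)]
  gene_block <- rep(seq_len(n_blocks), each = ceiling(n_genes / n_blocks))[seq_len(n_genes)]
  tfs <- sprintf("t%03d", seq_len(n_tfs)); genes <- sprintf("g%03d", seq_len(n_genes))
  with_seed(seed, {
    P <- ifelse(outer(tf_block, gene_block, `==`), p_in, p_out)
    A <- matrix(stats::rbinom(length(P), 1, P), n_tfs, n_genes,
                dimnames = list(tfs, genes))
    idx <- which(A == 1, arr.ind = TRUE)
    list(
      edges = tibble(tf = tfs[idx[, 1]], gene = genes[idx[, 2]], weight = 1),
      truth = bind_rows(tibble(node = tfs, role = "tf", block = tf_block),
                        tibble(node = genes, role = "gene", block = gene_block))
    )
  })
}

#' Planted case-only dense module benchmark
#'
#' A diffuse bipartite background (Bernoulli(`p_bg`) edges with
#' Uniform(0.3, 0.6) weights) shared by both conditions; the case network
#' additionally contains a dense `module_tfs` x `module_genes` biclique of
#' unit-weight edges.
#'
#' @param n_tfs,n_genes background size.
#' @param p_bg background edge probability.
#' @param module_tfs,module_genes planted biclique dimensions.
#' @param seed integer seed.
#' @return list: `case_edges`, `ctrl_edges`, `truth_nodes` (the planted
#'   module's node set).
#' @export
synthesize_module_benchmark <- function(n_tfs = 10, n_genes = 20, p_bg = 0.2,
                                        module_tfs = 4, module_genes = 8,
                                        seed = 1L) {
  tfs <- sprintf("t%03d", seq_len(n_tfs)); genes <- sprintf("g%03d", seq_len(n_genes))
  with_seed(seed, {
    base <- matrix(stats::rbinom(n_tfs * n_genes, 1, p_bg) *
                     stats::runif(n_tfs * n_genes, 0.3, 0.6),
                   n_tfs, n_genes, dimnames = list(tfs, genes))
    case <- base
    case[seq_len(module_tfs), seq_len(module_genes)] <- 1
    to_edges <- function(M) {
      idx <- which(M > 0, arr.ind = TRUE)
      tibble(tf = rownames(M)[idx[, 1]], gene = colnames(M)[idx[, 2]],
             weight = M[idx])
    }
    list(case_edges = to_edges(case), ctrl_edges = to_edges(base),
         truth_nodes = c(tfs[seq_len(module_tfs)], genes[seq_len(module_genes)]))
  })
}

#' Configuration-model-like null network pair
#'
#' Both conditions share the same expected-strength network
#' `w_ij = k_i d_j / m` built from lognormal strengths with mild
#' multiplicative noise: degree structure without any community structure,
#' the null control for differential-community detection.
#'
#' @param n_tfs,n_genes size.
#' @param noise_sd lognormal noise s.d. on the expected weights.
#' @param seed integer seed.
#' @return list `case_edges`, `ctrl_edges` (identical).
#' @export
synthesize_null_pair <- function(n_tfs = 10, n_genes = 20, noise_sd = 0.05,
                                 seed = 1L) {
  tfs <- sprintf("t%03d", seq_len(n_tfs)); genes <- sprintf("g%03d", seq_len(n_genes))
  with_seed(seed, {
    k <- exp(stats::rnorm(n_tfs, 0, 0.5)); d <- exp(stats::rnorm(n_genes, 0, 0.5))
    W <- outer(k, d) / sum(d) * exp(stats::rnorm(n_tfs * n_genes, 0, noise_sd))
    dimnames(W) <- list(tfs, genes)
    idx <- which(W > 0, arr.ind = TRUE)
    edges <- tibble(tf = tfs[idx[, 1]], gene = genes[idx[, 2]], weight = W[idx])
    list(case_edges = edges, ctrl_edges = edges)
  })
}
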