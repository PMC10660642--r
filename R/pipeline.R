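#' Pipeline configuration
#'
#' Single configuration object for the end-to-end synthetic run: generator
#' sizes, the (case, control) pair, focal TF machinery, and the analysis
#' thresholds (log2FC gate 0.1, adjusted-p gate 0.05, minimum 5 regulon
#' targets).
#'
#' @param n_tfs,n_genes,cell_types,n_markers_per_type generator universe.
#' @param conditions character(2): (case, control).
#' @param cells_per_type_per_condition,depth count simulation scale.
#' @param motif_density,ppi_density prior densities.
#' @param de_lfc,module_boost,n_de_per_type,module_size planted effects.
#' @param lfc_min,alpha,min_targets analysis thresholds.
#' @param panda a [panda_config()].
#' @param seed master seed; all stage seeds derive from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_tfs = 10, n_genes = 100,
                            cell_types = c("neuron", "astrocyte", "microglia"),
                            conditions = c("case", "control"),
                            n_markers_per_type = 5,
                            cells_per_type_per_condition = 60, depth = 5000,
                            motif_density = 0.2, ppi_density = 0.3,
                            de_lfc = 1, module_boost = 1,
                            n_de_per_type = 10, module_size = 8,
                            lfc_min = 0.1, alpha = 0.05, min_targets = 5,
                            panda = panda_config(), seed = 1L) {
  if (length(conditions) != 2L || conditions[1] == conditions[2]) {
    abort("`conditions` must be two distinct labels.")
  }
  stopifnot_scalar_number(lfc_min, "lfc_min", positive = TRUE)
  stopifnot_scalar_number(alpha, "alpha", positive = TRUE)
  structure(
    list(n_tfs = n_tfs, n_genes = n_genes, cell_types = cell_types,
         conditions = conditions, n_markers_per_type = n_markers_per_type,
         cells_per_type_per_condition = cells_per_type_per_condition,
         depth = depth, motif_density = motif_density,
         ppi_density = ppi_density, de_lfc = de_lfc,
         module_boost = module_boost, n_de_per_type = n_de_per_type,
         module_size = module_size, lfc_min = lfc_min, alpha = alpha,
         min_targets = min_targets, panda = panda, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; `panda:` keys map to [panda_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  panda <- do.call(panda_config, y$panda %||% list())
  y$panda <- NULL
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  do.call(pipeline_config, c(y, list(panda = panda)))
}

#' Run the full synthetic analysis pipeline
#'
#' Generates priors and counts with planted ground truth, then runs every
#' stage: log-normalization, per-cell-type Wilcoxon DE, regulon-based TF
#' activity with quartile prioritization, per-(cell type, condition)
#' message-passing network inference, differential gene targeting with
#' third-quartile selection and focal-set enrichment, bipartite and
#' differential community detection with focal-TF Jaccard comparison, and
#' regulation x cooperation rewiring classification. Fully deterministic
#' given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, all result tables and a
#'   run manifest (parameters, seeds, file checksums) are written there.
#' @return list with `truth`, `priors`, `counts`, `de`, `activity`, `grns`,
#'   `targeting`, `enrichment`, `partitions`, `diff_communities`,
#'   `ji_matrix`, `rewiring`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config().")
  }
  case <- config$conditions[1]; ctrl <- config$conditions[2]

  inform("stage synth: generating truth, priors, counts")
  truth <- synthetic_truth(
    n_tfs = config$n_tfs, n_genes = config$n_genes,
    cell_types = config$cell_types, conditions = config$conditions,
    n_markers_per_type = config$n_markers_per_type,
    seed = child_seed(config$seed, 1L))
  truth <- plant_perturbation(
    truth, de_lfc = config$de_lfc, module_boost = config$module_boost,
    n_de_per_type = config$n_de_per_type, module_size = config$module_size)
  priors <- generate_priors(
    config$n_tfs, config$n_genes, config$motif_density, config$ppi_density,
    seed = child_seed(config$seed, 3L),
    tf_names = truth$tf_names, gene_names = truth$gene_names)
  cpriors <- apply_truth_to_priors(truth, priors)
  counts <- simulate_counts(
    truth, cells_per_type_per_condition = config$cells_per_type_per_condition,
    depth = config$depth, seed = child_seed(config$seed, 4L),
    regulon = priors$regulon)
  lognorm <- log_normalize(counts)

  inform("stage de: Wilcoxon differential expression")
  de <- bind_rows(lapply(config$cell_types, function(ct) {
    wilcoxon_de(lognorm, ct, lfc_min = config$lfc_min, alpha = config$alpha)
  }))

  inform("stage activity: regulon-based TF activity")
  act_cells <- tf_activity(lognorm, priors$regulon,
                           min_targets = config$min_targets)
  activity <- summarize_activity(act_cells, lognorm$cells, config$conditions)

  inform("stage grn: message-passing network inference")
  grns <- list()
  for (ct in config$cell_types) {
    for (cond in config$conditions) {
      keep <- lognorm$cells$cell_type == ct & lognorm$cells$condition == cond
      coexpr <- coexpression_network(subset_cells(lognorm, keep))
      grns[[paste(ct, cond, sep = "|")]] <- panda_infer(
        cpriors$motif[[cond]], cpriors$ppi[[cond]], coexpr,
        cfg = config$panda, cell_type = ct, condition = cond)
    }
  }

  inform("stage targeting: differential gene targeting")
  targeting <- list(); enrichment <- list()
  for (ct in config$cell_types) {
    tt <- differential_targeting(grns[[paste(ct, case, sep = "|")]],
                                 grns[[paste(ct, ctrl, sep = "|")]],
                                 focal_set = truth$focal_gene_set)
    targeting[[ct]] <- tt
    enrichment[[ct]] <- hypergeometric_enrichment(
      tt$gene[tt$selected], intersect(truth$focal_gene_set, tt$gene), tt$gene) |>
      mutate(cell_type = ct, .before = 1)
  }
  targeting_tbl <- bind_rows(targeting)
  enrichment_tbl <- bind_rows(enrichment)

  inform("stage communities: bipartite + differential communities")
  partitions <- list(); diffcomms <- list()
  for (ct in config$cell_types) {
    case_edges <- positive_projection(grns[[paste(ct, case, sep = "|")]])
    ctrl_edges <- positive_projection(grns[[paste(ct, ctrl, sep = "|")]])
    partitions[[paste(ct, case, sep = "|")]] <-
      condor_partition(case_edges, seed = child_seed(config$seed, 5L))
    partitions[[paste(ct, ctrl, sep = "|")]] <-
      condor_partition(ctrl_edges, seed = child_seed(config$seed, 5L))
    diffcomms[[ct]] <- alpaca_differential(
      case_edges, ctrl_edges, focal_tf = truth$focal_tf,
      seed = child_seed(config$seed, 6L),
      baseline = partitions[[paste(ct, ctrl, sep = "|")]])
  }
  ji <- focal_community_similarity(diffcomms)

  inform("stage rewiring: regulation x cooperation classification")
  rewiring <- bind_rows(lapply(config$cell_types, function(ct) {
    extract_focal_subnetwork(
      grns[[paste(ct, case, sep = "|")]], grns[[paste(ct, ctrl, sep = "|")]],
      focal_tf = truth$focal_tf,
      focal_gene_set = truth$focal_gene_set,
      mechanism_proteins = truth$mechanism_proteins,
      cell_type = ct)
  }))

  result <- list(
    truth = truth, priors = priors, condition_priors = cpriors,
    counts = counts, de = de, activity = activity, grns = grns,
    targeting = targeting_tbl, enrichment = enrichment_tbl,
    partitions = partitions, diff_communities = diffcomms, ji_matrix = ji,
    rewiring = rewiring
  )
  result$manifest <- build_manifest(config, result)
  if (!is.null(outdir)) write_result_bundle(result, config, outdir)
  invisible(result)
}

build_manifest <- function(config, result) {
  cfg <- unclass(config)
  cfg$panda <- unclass(cfg$panda)
  list(
    package = "rewirenet",
    version = as.character(utils::packageVersion("rewirenet")),
    parameters = cfg,
    stage_seeds = list(truth = child_seed(config$seed, 1L),
                       priors = child_seed(config$seed, 3L),
                       counts = child_seed(config$seed, 4L),
                       condor = child_seed(config$seed, 5L),
                       alpaca = child_seed(config$seed, 6L)),
    n_cells = nrow(result$counts$values),
    n_significant_de = sum(result$de$significant),
    grn_converged = vapply(result$grns, `[[`, logical(1), "converged")
  )
}

#' Write all pipeline result tables plus a manifest
#'
#' @param result list returned by [run_pipeline()].
#' @param config the `pipeline_config` used.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_result_bundle <- function(result, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_expression(result$counts, file.path(outdir, "counts"))
  readr::write_tsv(result$de, file.path(outdir, "de.tsv"))
  readr::write_tsv(result$activity, file.path(outdir, "activity.tsv"))
  for (nm in names(result$grns)) {
    write_grn(result$grns[[nm]],
              file.path(outdir, paste0("grn_", gsub("\\|", "_", nm), ".tsv")))
  }
  readr::write_tsv(result$targeting, file.path(outdir, "targeting.tsv"))
  readr::write_tsv(result$enrichment, file.path(outdir, "enrichment.tsv"))
  for (nm in names(result$partitions)) {
    readr::write_tsv(tidy(result$partitions[[nm]]),
                     file.path(outdir, paste0("partition_",
                                              gsub("\\|", "_", nm), ".tsv")))
  }
  for (nm in names(result$diff_communities)) {
    readr::write_tsv(tidy(result$diff_communities[[nm]]),
                     file.path(outdir, paste0("diffcomm_", nm, ".tsv")))
  }
  ji <- as_tibble(result$ji_matrix, rownames = "cell_type")
  readr::write_tsv(ji, file.path(outdir, "jaccard.tsv"))
  readr::write_tsv(result$rewiring, file.path(outdir, "rewiring.tsv"))
  files <- sort(setdiff(list.files(outdir, recursive = TRUE), "manifest.json"))
  manifest <- result$manifest
  manifest$checksums <- as.list(
    stats::setNames(unname(tools::md5sum(file.path(outdir, files))), files))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
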