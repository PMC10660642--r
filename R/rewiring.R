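#' Extract the focal TF's regulation/cooperation record pairs
#'
#' One record per (target in `focal_gene_set` that is also a node of the
#' cooperativity network, mechanism protein): the focal TF -> target
#' regulatory weight and the target <-> mechanism cooperativity weight in
#' both conditions. Absent edges are looked up as 0 and reported.
#'
#' @param grn_case,grn_ctrl `grn` objects (focal TF must be a row of both).
#' @param coop_case,coop_ctrl symmetric protein x protein cooperativity
#'   matrices (defaults to the TF-TF layer of the network model:
#'   `grn$ppi`).
#' @param focal_tf the perturbed TF under study.
#' @param focal_gene_set its curated target gene set.
#' @param mechanism_proteins proteins of the candidate mechanisms (e.g. DNA
#'   damage, cell cycle effectors).
#' @param cell_type label stamped on the records.
#' @param presence_threshold weight above which an edge counts as present
#'   (default 0, the natural null of the z-score-like networks).
#' @return tibble of rewiring records (one per target x mechanism pair) with
#'   presence flags and a category from [classify_rewiring()].
#' @export
extract_focal_subnetwork <- function(grn_case, grn_ctrl,
                                     coop_case = grn_case$ppi,
                                     coop_ctrl = grn_ctrl$ppi,
                                     focal_tf, focal_gene_set,
                                     mechanism_proteins,
                                     cell_type = grn_case$cell_type %||% NA_character_,
                                     presence_threshold = 0) {
  if (!inherits(grn_case, "grn") || !inherits(grn_ctrl, "grn")) {
    abort("`grn_case` and `grn_ctrl` must be grn objects.")
  }
  if (!focal_tf %in% grn_case$tfs || !focal_tf %in% grn_ctrl$tfs) {
    abort(sprintf("focal TF '%s' missing from the regulatory networks.", focal_tf))
  }
  if (!length(mechanism_proteins)) abort("`mechanism_proteins` must be non-empty.")
  coop_case <- as.matrix(coop_case); coop_ctrl <- as.matrix(coop_ctrl)
  coop_nodes <- intersect(rownames(coop_case), rownames(coop_ctrl))
  targets <- intersect(focal_gene_set, coop_nodes)
  targets <- intersect(targets, intersect(grn_case$genes, grn_ctrl$genes))
  if (!length(targets)) {
    warn("focal gene set has no overlap with the cooperativity network; no records.")
    return(tibble(cell_type = character(), target = character(),
                  mechanism_protein = character(),
                  reg_case = numeric(), reg_ctrl = numeric(),
                  coop_case = numeric(), coop_ctrl = numeric(),
                  reg_present_case = logical(), reg_present_ctrl = logical(),
                  coop_present_case = logical(), coop_present_ctrl = logical(),
                  regulation_change = character(), cooperation_change = character(),
                  category = character()))
  }
  lookup <- function(M, i, j) {
    if (i %in% rownames(M) && j %in% colnames(M)) M[i, j] else 0
  }
  grid <- tidyr::expand_grid(target = targets,
                             mechanism_protein = mechanism_proteins)
  recs <- grid |>
    mutate(
      cell_type = cell_type,
      reg_case = map_dbl(.data$target, ~ lookup(grn_case$weights, focal_tf, .x)),
      reg_ctrl = map_dbl(.data$target, ~ lookup(grn_ctrl$weights, focal_tf, .x)),
      coop_case = purrr::map2_dbl(.data$target, .data$mechanism_protein,
                                  ~ lookup(coop_case, .x, .y)),
      coop_ctrl = purrr::map2_dbl(.data$target, .data$mechanism_protein,
                                  ~ lookup(coop_ctrl, .x, .y))
    ) |>
    relocate("cell_type")
  absent_mech <- setdiff(mechanism_proteins, coop_nodes)
  if (length(absent_mech)) {
    inform(paste0("mechanism protein(s) absent from the cooperativity network",
                  " (weights taken as 0): ", paste(absent_mech, collapse = ", ")))
  }
  classify_rewiring(recs, presence_threshold = presence_threshold)
}

axis_change <- function(present_ctrl, present_case) {
  dplyr::case_when(
    !present_ctrl & present_case ~ "gained",
    present_ctrl & !present_case ~ "lost",
    TRUE ~ "stable"
  )
}

#' Classify regulation x cooperation rewiring
#'
#' Presence of an edge is `weight > presence_threshold` (strictly). Each axis
#' (regulation: focal TF -> target; cooperation: target <-> mechanism
#' protein) changes to "gained", "lost", or stays "stable" between control
#' and case. The four reported categories combine a cooperation change with
#' the regulation status:
#' `regulation_altered_cooperation_gained`,
#' `regulation_altered_cooperation_lost`,
#' `regulation_stable_cooperation_gained`,
#' `regulation_stable_cooperation_lost`.
#' Pairs whose cooperation is stable are labeled `regulation_only_change`
#' when regulation changed, else `unchanged`; neither enters the
#' four-category report.
#'
#' @param records tibble with `reg_case`, `reg_ctrl`, `coop_case`,
#'   `coop_ctrl` (e.g. from [extract_focal_subnetwork()]).
#' @param presence_threshold presence cutoff (default 0).
#' @return `records` with presence flags, per-axis changes, and `category`.
#' @export
classify_rewiring <- function(records, presence_threshold = 0) {
  records <- as_tibble(records)
  needed <- c("reg_case", "reg_ctrl", "coop_case", "coop_ctrl")
  if (!all(needed %in% names(records))) {
    abort(paste0("records need columns: ", paste(needed, collapse = ", ")))
  }
  records |>
    mutate(
      reg_present_case = .data$reg_case > presence_threshold,
      reg_present_ctrl = .data$reg_ctrl > presence_threshold,
      coop_present_case = .data$coop_case > presence_threshold,
      coop_present_ctrl = .data$coop_ctrl > presence_threshold,
      regulation_change = axis_change(.data$reg_present_ctrl,
                                      .data$reg_present_case),
      cooperation_change = axis_change(.data$coop_present_ctrl,
                                       .data$coop_present_case),
      category = dplyr::case_when(
        .data$cooperation_change == "gained" & .data$regulation_change != "stable"
          ~ "regulation_altered_cooperation_gained",
        .data$cooperation_change == "lost" & .data$regulation_change != "stable"
          ~ "regulation_altered_cooperation_lost",
        .data$cooperation_change == "gained"
          ~ "regulation_stable_cooperation_gained",
        .data$cooperation_change == "lost"
          ~ "regulation_stable_cooperation_lost",
        .data$regulation_change != "stable" ~ "regulation_only_change",
        TRUE ~ "unchanged"
      )
    )
}

#' The four reported rewiring categories
#' @return character(4) of category labels.
#' @export
rewiring_categories <- function() {
  c("regulation_altered_cooperation_gained",
    "regulation_altered_cooperation_lost",
    "regulation_stable_cooperation_gained",
    "regulation_stable_cooperation_lost")
}

#' Sign-change and magnitude summaries of rewiring records
#'
#' @param records classified rewiring records.
#' @return list of two tibbles: `sign_changes` (per-axis change codes) and
#'   `magnitudes` (case-minus-control weight differences), both ordered by
#'   cell type then target.
#' @export
rewiring_summary <- function(records) {
  records <- as_tibble(records)
  if (!nrow(records)) abort("need >= 1 rewiring record.")
  ord <- records |> arrange(.data$cell_type, .data$target, .data$mechanism_protein)
  list(
    sign_changes = ord |>
      select(all_of(c("cell_type", "target", "mechanism_protein",
                      "regulation_change", "cooperation_change", "category"))),
    magnitudes = ord |>
      mutate(reg_delta = .data$reg_case - .data$reg_ctrl,
             coop_delta = .data$coop_case - .data$coop_ctrl) |>
      select(all_of(c("cell_type", "target", "mechanism_protein",
                      "reg_delta", "coop_delta")))
  )
}
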