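# the committed truth table over all 16 presence-flag combinations
rewiring_truth_table <- tibble::tribble(
  ~reg_ctrl, ~reg_case, ~coop_ctrl, ~coop_case, ~category,
  FALSE, FALSE, FALSE, FALSE, "unchanged",
  TRUE,  TRUE,  FALSE, FALSE, "unchanged",
  FALSE, TRUE,  FALSE, FALSE, "regulation_only_change",
  TRUE,  FALSE, FALSE, FALSE, "regulation_only_change",
  FALSE, TRUE,  TRUE,  TRUE,  "regulation_only_change",
  TRUE,  FALSE, TRUE,  TRUE,  "regulation_only_change",
  FALSE, FALSE, TRUE,  TRUE,  "unchanged",
  TRUE,  TRUE,  TRUE,  TRUE,  "unchanged",
  FALSE, TRUE,  FALSE, TRUE,  "regulation_altered_cooperation_gained",
  TRUE,  FALSE, FALSE, TRUE,  "regulation_altered_cooperation_gained",
  FALSE, TRUE,  TRUE,  FALSE, "regulation_altered_cooperation_lost",
  TRUE,  FALSE, TRUE,  FALSE, "regulation_altered_cooperation_lost",
  FALSE, FALSE, FALSE, TRUE,  "regulation_stable_cooperation_gained",
  TRUE,  TRUE,  FALSE, TRUE,  "regulation_stable_cooperation_gained",
  FALSE, FALSE, TRUE,  FALSE, "regulation_stable_cooperation_lost",
  TRUE,  TRUE,  TRUE,  FALSE, "regulation_stable_cooperation_lost"
)

flags_to_weights <- function(tt) {
  dplyr::mutate(tt,
    reg_ctrl_w = ifelse(reg_ctrl, 0.6, -0.6),
    reg_case_w = ifelse(reg_case, 0.6, -0.6),
    coop_ctrl_w = ifelse(coop_ctrl, 0.6, -0.6),
    coop_case_w = ifelse(coop_case, 0.6, -0.6)
  )
}

test_that("classification reproduces the committed 16-row truth table", {
  w <- flags_to_weights(rewiring_truth_table)
  recs <- tibble::tibble(
    cell_type = "A", target = sprintf("p%02d", 1:16), mechanism_protein = "M",
    reg_case = w$reg_case_w, reg_ctrl = w$reg_ctrl_w,
    coop_case = w$coop_case_w, coop_ctrl = w$coop_ctrl_w
  )
  out <- classify_rewiring(recs)
  expect_identical(out$category, rewiring_truth_table$category)
  expect_identical(out$reg_present_case, rewiring_truth_table$reg_case)
  expect_identical(out$coop_present_ctrl, rewiring_truth_table$coop_ctrl)
})

test_that("swapping case and control maps gained to lost on both axes", {
  w <- flags_to_weights(rewiring_truth_table)
  fwd <- classify_rewiring(tibble::tibble(
    reg_case = w$reg_case_w, reg_ctrl = w$reg_ctrl_w,
    coop_case = w$coop_case_w, coop_ctrl = w$coop_ctrl_w))
  bwd <- classify_rewiring(tibble::tibble(
    reg_case = w$reg_ctrl_w, reg_ctrl = w$reg_case_w,
    coop_case = w$coop_ctrl_w, coop_ctrl = w$coop_case_w))
  flip <- c(gained = "lost", lost = "gained", stable = "stable")
  expect_identical(unname(flip[fwd$regulation_change]), bwd$regulation_change)
  expect_identical(unname(flip[fwd$cooperation_change]), bwd$cooperation_change)
})

test_that("focal subnetwork extraction enumerates target x mechanism pairs with exact weights", {
  tr <- synthetic_truth(seed = 11)
  tr <- plant_perturbation(tr, de_lfc = 1, module_boost = 1, n_de_per_type = 5)
  nets <- synthesize_networks(tr, signal = 0.8, seed = 2)
  recs <- suppressMessages(extract_focal_subnetwork(
    nets$case, nets$control,
    focal_tf = tr$focal_tf,
    focal_gene_set = tr$planted_rewired$target[1:2],
    mechanism_proteins = tr$mechanism_proteins,
    cell_type = "A"))
  # 2 targets x 2 mechanism proteins
  expect_equal(nrow(recs), 4)
  for (i in seq_len(nrow(recs))) {
    expect_equal(recs$reg_case[i],
                 nets$case$weights[tr$focal_tf, recs$target[i]])
    expect_equal(recs$coop_ctrl[i],
                 nets$control$ppi[recs$target[i], recs$mechanism_protein[i]])
  }

  # all planted categories classify correctly against generator truth
  full <- suppressMessages(extract_focal_subnetwork(
    nets$case, nets$control, focal_tf = tr$focal_tf,
    focal_gene_set = tr$planted_rewired$target,
    mechanism_proteins = tr$mechanism_proteins[1]))
  merged <- dplyr::inner_join(
    full, dplyr::select(tr$planted_rewired, target, mechanism_protein,
                        planted = category),
    by = c("target", "mechanism_protein"))
  expect_equal(nrow(merged), 4)
  expect_identical(merged$category, merged$planted)

  expect_warning(
    empty <- extract_focal_subnetwork(
      nets$case, nets$control, focal_tf = tr$focal_tf,
      focal_gene_set = "not_a_protein",
      mechanism_proteins = tr$mechanism_proteins),
    "no overlap")
  expect_equal(nrow(empty), 0)

  expect_error(extract_focal_subnetwork(
    nets$case, nets$control, focal_tf = "ghost",
    focal_gene_set = tr$planted_rewired$target,
    mechanism_proteins = tr$mechanism_proteins), "missing")
})

test_that("rewiring summaries report sign changes and exact magnitudes", {
  recs <- classify_rewiring(tibble::tibble(
    cell_type = c("B", "A"), target = c("p2", "p1"), mechanism_protein = "M",
    reg_case = c(0.5, -0.1), reg_ctrl = c(0.5, 0.4),
    coop_case = c(0.3, 0.2), coop_ctrl = c(-0.2, 0.2)))
  s <- rewiring_summary(recs)
  expect_equal(nrow(s$sign_changes), 2)
  expect_equal(nrow(s$magnitudes), 2)
  # ordered by cell type then target
  expect_identical(s$magnitudes$cell_type, c("A", "B"))
  expect_equal(s$magnitudes$reg_delta, c(-0.5, 0))
  expect_equal(s$magnitudes$coop_delta, c(0, 0.5))
  # unchanged pair has zero magnitudes and neutral codes
  expect_identical(s$sign_changes$category[2],
                   "regulation_stable_cooperation_gained")
  expect_error(rewiring_summary(recs[0, ]), ">= 1")
})
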