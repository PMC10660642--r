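test_that("regulon design matrix honors the minimum-target filter", {
  reg <- tibble::tibble(
    tf = c(rep("TF_A", 5), rep("TF_B", 4)),
    target = c(paste0("g", 1:5), paste0("g", 1:4)),
    mode = rep(c(1, -1), length.out = 9)
  )
  genes <- paste0("g", 1:10)
  d <- build_design(reg, genes, min_targets = 5)
  expect_identical(colnames(d), "TF_A")
  expect_identical(attr(d, "dropped"), "TF_B")

  d1 <- build_design(tibble::tibble(tf = "T1", target = "g2", mode = -1),
                     genes, min_targets = 1)
  expect_equal(sum(d1 != 0), 1)
  expect_equal(d1["g2", "T1"], -1)

  # column support equals per-TF matched-target tally
  set.seed(11)
  reg2 <- tibble::tibble(
    tf = sample(paste0("T", 1:6), 60, replace = TRUE),
    target = paste0("g", sample(1:40, 60, replace = TRUE)),
    mode = sample(c(-1, 1), 60, replace = TRUE)
  ) |> dplyr::distinct(tf, target, .keep_all = TRUE)
  d2 <- build_design(reg2, paste0("g", 1:30), min_targets = 1)
  tally <- table(reg2$tf[reg2$target %in% paste0("g", 1:30)])
  expect_equal(colSums(d2 != 0)[names(tally)], unclass(tally)[names(tally)],
               ignore_attr = TRUE)

  expect_error(build_design(reg, paste0("x", 1:3), min_targets = 5), "no TF")
  expect_error(build_design(rbind(reg, reg[1, ]), genes), "duplicate")
})

test_that("multivariate linear model activities match the closed-form OLS oracle", {
  # 6 genes, 2 disjoint +/-1 regulons
  design <- cbind(TFa = c(1, 1, -1, 0, 0, 0), TFb = c(0, 0, 0, 1, -1, 1))
  rownames(design) <- paste0("g", 1:6)
  y <- c(2.0, 1.5, -1.0, 0.5, 0.2, 0.9)
  X <- cbind(1, design)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (6 - 3)
  se <- sqrt(diag(solve(t(X) %*% X)) * s2)
  want <- (beta / se)[-1]
  got <- mlm_activity(y, design)
  expect_equal(unname(got), unname(want), tolerance = 1e-10)

  # centered profile orthogonal to every regulon column -> zero activity
  y0 <- c(1, 1, 2, 0, -2, -2) # orthogonal to both columns, sums to 0
  expect_true(all(abs(c(y0 %*% design)) < 1e-12) && sum(y0) == 0)
  got0 <- mlm_activity(y0, design)
  expect_equal(unname(got0), c(0, 0), tolerance = 1e-10)

  # duplicated TF column -> rank deficiency naming the column
  expect_error(mlm_activity(y, cbind(design, TFa2 = design[, 1])), "TFa2")

  # perfect fit -> NA, not infinity
  yp <- X %*% c(0.3, 1, -2)
  expect_true(all(is.na(mlm_activity(as.numeric(yp), design))))
})

test_that("activity t-statistics are invariant to profile rescaling", {
  set.seed(21)
  design <- matrix(sample(c(-1, 0, 1), 80, replace = TRUE), 40, 2,
                   dimnames = list(paste0("g", 1:40), c("T1", "T2")))
  Y <- matrix(rnorm(40 * 6), 40, 6)
  expect_equal(mlm_activity(Y, design), mlm_activity(Y * 7.5, design),
               tolerance = 1e-9)
})

test_that("activity summaries compute percent change and quartile flags", {
  # 8 TFs x 1 cell type, hand-built per-cell activities
  set.seed(5)
  tfs <- paste0("T", 1:8)
  acts <- tidyr::expand_grid(cell_id = sprintf("c%02d", 1:12), tf = tfs) |>
    dplyr::mutate(activity = rnorm(dplyr::n()))
  cells <- tibble::tibble(cell_id = sprintf("c%02d", 1:12), cell_type = "A",
                          condition = rep(c("case", "control"), each = 6),
                          sample_id = "s")
  out <- summarize_activity(acts, cells, c("case", "control"), pct_on = "mean")
  # means per (tf, condition) from first principles
  merged <- dplyr::inner_join(acts, cells, by = "cell_id")
  man <- merged |>
    dplyr::group_by(tf, condition) |>
    dplyr::summarise(m = mean(activity), .groups = "drop") |>
    tidyr::pivot_wider(names_from = condition, values_from = m) |>
    dplyr::mutate(pct = 100 * (case - control) / pmax(abs(control), 1e-8))
  got <- out |> dplyr::distinct(tf, pct_change) |> dplyr::arrange(tf)
  expect_equal(got$pct_change, man$pct[order(man$tf)], tolerance = 1e-9)

  # quartile flags match a linear-interpolation quantile oracle
  q1 <- unname(quantile(man$pct, 0.25, type = 7))
  q3 <- unname(quantile(man$pct, 0.75, type = 7))
  flags <- ifelse(man$pct > q3, "above_Q3",
                  ifelse(man$pct < q1, "below_Q1", "none"))
  got_f <- out |> dplyr::distinct(tf, priority) |> dplyr::arrange(tf)
  expect_equal(got_f$priority, flags[order(man$tf)])

  # equal case/control means -> zero change, no priority
  acts0 <- acts |> dplyr::mutate(activity = rep(seq_len(8), times = 12))
  out0 <- summarize_activity(acts0, cells, c("case", "control"), pct_on = "mean")
  expect_true(all(out0$pct_change == 0))
  expect_true(all(out0$priority == "none"))
})

test_that("activities under a global null are centered near zero", {
  set.seed(31)
  means <- replicate(3, {
    design <- matrix(sample(c(-1, 0, 1), 500 * 20, replace = TRUE,
                            prob = c(0.05, 0.9, 0.05)), 500, 20,
                     dimnames = list(paste0("g", 1:500), paste0("T", 1:20)))
    Y <- matrix(rnorm(500 * 30), 500, 30)
    mean(mlm_activity(Y, design), na.rm = TRUE)
  })
  expect_true(all(abs(means) < 0.1))
})
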