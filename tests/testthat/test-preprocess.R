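test_that("log normalization matches the elementwise formula", {
  set.seed(1)
  counts <- matrix(rpois(20, 5), 5, 4,
                   dimnames = list(NULL, paste0("g", 1:4)))
  counts[1, 1] <- 0
  cells <- tibble::tibble(cell_id = paste0("c", 1:5), cell_type = "A",
                          condition = rep(c("case", "control"), length.out = 5),
                          sample_id = "s1")
  rownames(counts) <- cells$cell_id
  expr <- cell_expr(counts, cells, layer = "raw")
  ln <- log_normalize(expr, scale = 1e4)
  manual <- log(1 + 1e4 * counts / rowSums(counts))
  expect_lt(max(abs(as.matrix(ln$values) - manual)), 1e-12)
  expect_equal(as.numeric(ln$values[1, 1]), 0)   # zero count stays zero

  # single-gene cell: count 10, total 10
  one <- matrix(10, 1, 1, dimnames = list("c1", "g1"))
  e1 <- cell_expr(one, tibble::tibble(cell_id = "c1", cell_type = "A",
                                      condition = "case", sample_id = "s1"),
                  layer = "raw", conditions = c("case", "control"))
  expect_equal(as.numeric(log_normalize(e1, 1e4)$values[1, 1]), log(1 + 1e4))

  counts0 <- counts; counts0[2, ] <- 0
  e0 <- cell_expr(counts0, cells, layer = "raw")
  expect_error(log_normalize(e0), "c2")
})

test_that("rank-sum p-values agree with enumeration and the base oracle", {
  expect_equal(rank_sum_p(c(4, 5, 6), c(1, 2, 3)), 0.1)
  expect_equal(rank_sum_p(c(1, 2, 3), c(1, 2, 3)), 1)

  set.seed(42)
  for (i in 1:20) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    expect_equal(rank_sum_p(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
    # with ties, compare against the independent enumeration oracle
    xt <- sample(1:4, nx, replace = TRUE); yt <- sample(1:4, ny, replace = TRUE)
    expect_equal(rank_sum_p(xt, yt), oracle_rank_sum_p(xt, yt),
                 tolerance = 1e-12)
  }
  # large groups: normal approximation tracks the base implementation
  for (i in 1:10) {
    x <- rnorm(40); y <- rnorm(35) + 0.3
    expect_equal(rank_sum_p(x, y),
                 stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("differential expression applies the fold-change gate and Bonferroni", {
  set.seed(7)
  case <- matrix(rnorm(20 * 30, 1), 20, 30)
  ctrl <- matrix(rnorm(20 * 30, 1), 20, 30)
  case[, 1] <- case[, 1] + 1.5          # strong planted shift
  colnames(case) <- colnames(ctrl) <- paste0("g", 1:30)
  expr <- expr_from_groups(pmax(case, 0), pmax(ctrl, 0))
  de <- wilcoxon_de(expr, "A", lfc_min = 0.1, alpha = 0.05)
  expect_true(all(abs(de$log2fc) >= 0.1))
  expect_true(all(de$p_adj >= de$p))
  expect_true(all(de$p_adj <= 1) && all(de$p >= 0))
  expect_true("g1" %in% de$gene[de$significant])
  expect_true(all(de$direction[de$log2fc < 0] == "down"))

  # gate: a gene with |log2fc| below 0.1 is never tested
  lo <- de$gene
  all_lfc <- sapply(paste0("g", 1:30), function(g) {
    i <- match(g, colnames(case))
    log2(mean(expm1(pmax(case[, i], 0))) + 1) -
      log2(mean(expm1(pmax(ctrl[, i], 0))) + 1)
  })
  expect_setequal(lo, names(all_lfc)[abs(all_lfc) >= 0.1])

  # Bonferroni nesting: significant set at 0.01 is a subset of at 0.05
  s01 <- de$gene[de$p_adj < 0.01]
  s05 <- de$gene[de$p_adj < 0.05]
  expect_true(all(s01 %in% s05))

  expect_error(wilcoxon_de(expr, "missing"), "missing")
})

test_that("module scores subtract binned controls correctly", {
  set.seed(3)
  vals <- matrix(abs(rnorm(4 * 30)), 4, 30,
                 dimnames = list(NULL, paste0("g", 1:30)))
  expr <- tiny_expr(vals)
  # set = all genes, controls = whole pool -> exactly zero
  s_all <- module_score(expr, paste0("g", 1:30), n_bins = 5, n_ctrl = 30, seed = 1)
  expect_true(all(abs(s_all$score) < 1e-12))

  # adding a constant shifts nothing
  expr2 <- expr; expr2$values <- expr2$values + 3
  gs <- c("g1", "g5", "g9")
  s1 <- module_score(expr, gs, n_bins = 4, n_ctrl = 10, seed = 2)
  s2 <- module_score(expr2, gs, n_bins = 4, n_ctrl = 10, seed = 2)
  expect_equal(s1$score, s2$score, tolerance = 1e-12)

  # hand-computed: single bin means controls = sampled pool
  s3a <- module_score(expr, gs, n_bins = 1, n_ctrl = 30, seed = 3)
  manual <- rowMeans(vals[, gs]) - rowMeans(vals)
  expect_equal(s3a$score, unname(manual), tolerance = 1e-12)

  expect_error(module_score(expr, c("nope")), "no member")
})

test_that("signature scores are signed centered means", {
  set.seed(8)
  vals <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  expr <- tiny_expr(vals)
  s_one <- signature_score(expr, data.frame(gene = "a", sign = 1))
  expect_equal(s_one$score, unname(vals[, "a"] - mean(vals[, "a"])),
               tolerance = 1e-12)
  sgn <- data.frame(gene = c("a", "b"), sign = c(1, -1))
  s <- signature_score(expr, sgn)
  manual <- ((vals[, "a"] - mean(vals[, "a"])) -
               (vals[, "b"] - mean(vals[, "b"]))) / 2
  expect_equal(s$score, unname(manual), tolerance = 1e-12)
  s_flip <- signature_score(expr, transform(sgn, sign = -sign))
  expect_equal(s_flip$score, -s$score, tolerance = 1e-12)
})

test_that("detection fractions count nonzero cells per condition", {
  vals <- matrix(c(1, 0, 2, 3,   0, 0, 0, 0,   1, 1, 1, 1), 4, 3,
                 dimnames = list(NULL, c("some", "none", "all")))
  expr <- tiny_expr(vals)  # conditions alternate case/control
  expect_equal(detection_fraction(expr, "A", "none")$pct_case, 0)
  expect_equal(detection_fraction(expr, "A", "none")$pct_ctrl, 0)
  expect_equal(detection_fraction(expr, "A", "all")$pct_case, 1)
  d <- detection_fraction(expr, "A", "some")   # case cells: rows 1,3 -> 1, 2
  expect_equal(d$pct_case, 1)
  expect_equal(d$pct_ctrl, 0.5)
  expect_error(detection_fraction(expr, "A", "nope"), "unknown gene")
})
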