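test_that("positive projection keeps strictly positive edges and reports drops", {
  W <- matrix(c(-1, 0, 2, 0.5), 2, 2,
              dimnames = list(c("t1", "t2"), c("g1", "g2")))
  edges <- suppressMessages(positive_projection(W))
  expect_equal(nrow(edges), 2)
  expect_true(all(edges$weight > 0))

  W2 <- matrix(c(-1, 0, 2, -3), 2, 2,
               dimnames = list(c("t1", "t2"), c("g1", "g2")))
  e2 <- suppressMessages(positive_projection(W2))
  expect_equal(e2$weight, 2)
  expect_true("t2" %in% attr(e2, "dropped_nodes"))

  Wneg <- matrix(-abs(rnorm(6)), 2, 3,
                 dimnames = list(paste0("t", 1:2), paste0("g", 1:3)))
  expect_error(positive_projection(Wneg), "no positive")

  set.seed(3)
  R <- matrix(rnorm(30), 5, 6,
              dimnames = list(paste0("t", 1:5), paste0("g", 1:6)))
  expect_equal(nrow(suppressMessages(positive_projection(R))), sum(R > 0))
})

test_that("Barber modularity matches hand-computed instances", {
  # all nodes in one community -> 0
  edges <- tibble::tibble(tf = c("t1", "t1", "t2"), gene = c("g1", "g2", "g2"),
                          weight = c(1, 0.5, 2))
  one <- tibble::tibble(node = c("t1", "t2", "g1", "g2"),
                        role = c("tf", "tf", "gene", "gene"), community = 1L)
  expect_equal(barber_modularity(one, edges), 0, tolerance = 1e-14)

  # two disjoint unit edges, each its own community -> 0.5
  e2 <- tibble::tibble(tf = c("t1", "t2"), gene = c("g1", "g2"), weight = 1)
  p2 <- tibble::tibble(node = c("t1", "g1", "t2", "g2"),
                       role = c("tf", "gene", "tf", "gene"),
                       community = c(1L, 1L, 2L, 2L))
  expect_equal(barber_modularity(p2, e2), 0.5, tolerance = 1e-14)

  expect_error(barber_modularity(p2[-1, ], e2), "unassigned")
})

test_that("the partition optimizer attains the enumeration optimum on tiny graphs", {
  # all 2x3 unweighted bipartite graphs (non-isolated nodes only)
  for (mask in 1:63) {
    A <- matrix(as.integer(intToBits(mask))[1:6], 2, 3,
                dimnames = list(c("t1", "t2"), c("g1", "g2", "g3")))
    idx <- which(A == 1, arr.ind = TRUE)
    edges <- tibble::tibble(tf = rownames(A)[idx[, 1]],
                            gene = colnames(A)[idx[, 2]], weight = 1)
    got <- condor_partition(edges)$modularity
    expect_equal(got, oracle_best_modularity(edges), tolerance = 1e-9,
                 label = sprintf("mask %d", mask))
  }
  # random weighted 3x3 graphs
  for (s in 1:10) {
    set.seed(s)
    A <- matrix(round(runif(9), 2) * rbinom(9, 1, 0.6), 3, 3,
                dimnames = list(paste0("t", 1:3), paste0("g", 1:3)))
    if (sum(A) == 0) next
    edges <- matrix_to_edge_tbl(A)
    expect_equal(condor_partition(edges)$modularity,
                 oracle_best_modularity(edges), tolerance = 1e-9)
  }
})

test_that("community detection recovers planted bicliques and trivial cases", {
  e1 <- tibble::tibble(tf = "t1", gene = "g1", weight = 1)
  p1 <- condor_partition(e1)
  expect_equal(p1$n_communities, 1L)
  expect_equal(p1$modularity, 0, tolerance = 1e-14)

  # two disjoint K(2,3) bicliques
  edges <- dplyr::bind_rows(
    tidyr::expand_grid(tf = c("a1", "a2"), gene = c("x1", "x2", "x3")),
    tidyr::expand_grid(tf = c("b1", "b2"), gene = c("y1", "y2", "y3"))
  ) |> dplyr::mutate(weight = 1)
  p <- condor_partition(edges)
  asg <- p$assignment
  expect_equal(p$n_communities, 2L)
  expect_equal(p$modularity, 0.5, tolerance = 1e-12)
  ca <- unique(asg$community[asg$node %in% c("a1", "a2", "x1", "x2", "x3")])
  cb <- unique(asg$community[asg$node %in% c("b1", "b2", "y1", "y2", "y3")])
  expect_length(ca, 1); expect_length(cb, 1); expect_false(ca == cb)

  expect_error(condor_partition(e1[0, ]), "empty")
})

test_that("differential communities are scale-invariant and anchored to the focal TF", {
  bm <- synthesize_module_benchmark(seed = 3)
  d1 <- alpaca_differential(bm$case_edges, bm$ctrl_edges, focal_tf = "t001")
  d2 <- alpaca_differential(
    dplyr::mutate(bm$case_edges, weight = weight * 2),
    dplyr::mutate(bm$ctrl_edges, weight = weight * 5),
    focal_tf = "t001")
  expect_equal(d1$dscore, d2$dscore, tolerance = 1e-12)
  expect_identical(d1$assignment, d2$assignment)
  expect_true("t001" %in% d1$focal_members)
  expect_true(all(is.finite(d1$node_scores$score)))

  expect_error(alpaca_differential(bm$case_edges, bm$ctrl_edges,
                                   focal_tf = "zz"), "absent")
})

test_that("Jaccard similarity and the focal-community matrix behave as set arithmetic", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard("a", "b"), 0)
  expect_equal(jaccard(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_warning(j0 <- jaccard(character(0), character(0)), "empty")
  expect_equal(j0, 0)

  bm1 <- synthesize_module_benchmark(seed = 1)
  bm2 <- synthesize_module_benchmark(seed = 2)
  res <- list(
    typeA = alpaca_differential(bm1$case_edges, bm1$ctrl_edges, focal_tf = "t001"),
    typeB = alpaca_differential(bm2$case_edges, bm2$ctrl_edges, focal_tf = "t001")
  )
  M <- focal_community_similarity(res)
  expect_identical(M, t(M))
  expect_equal(unname(diag(M)), c(1, 1))
  expect_equal(M["typeA", "typeB"],
               jaccard(res$typeA$focal_members, res$typeB$focal_members))
  # identical inputs -> JI 1 off-diagonal
  M2 <- focal_community_similarity(list(a = res$typeA, b = res$typeA))
  expect_equal(unname(M2["a", "b"]), 1)
})

test_that("partitions are reproducible and tidiers expose them", {
  bm <- synthesize_module_benchmark(seed = 5)
  p1 <- condor_partition(bm$case_edges, seed = 42)
  p2 <- condor_partition(bm$case_edges, seed = 42)
  expect_identical(p1$assignment, p2$assignment)

  td <- tidy(p1)
  expect_named(td, c("node", "role", "community"))
  g <- glance(p1)
  expect_equal(g$n_communities, p1$n_communities)
  expect_gte(g$modularity, 0)
})
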