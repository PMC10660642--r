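test_that("coexpression networks are exact Pearson correlations with safe degenerate handling", {
  m <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(5, 1, 2))
  cc <- coexpression_network(m)
  expect_equal(diag(cc), c(a = 1, b = 1, c = 1))
  expect_equal(cc["a", "b"], 1)

  set.seed(2)
  X <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("g", 1:5)))
  cc2 <- coexpression_network(X)
  manual <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    manual[i, j] <- cov(X[, i], X[, j]) / (sd(X[, i]) * sd(X[, j]))
  }
  expect_lt(max(abs(cc2 - manual)), 1e-12)

  Xz <- cbind(X, flat = rep(1, 8))
  cc3 <- coexpression_network(Xz)
  expect_true(all(cc3["flat", colnames(X)] == 0))
  expect_equal(cc3["flat", "flat"], 1)

  expect_error(coexpression_network(X[1:2, ]), ">= 3 cells")
})

test_that("continuous Tanimoto similarity matches the defining formula", {
  e <- matrix(c(1, 0), 1, 2)
  expect_equal(as.numeric(continuous_tanimoto(e, e)), 1)
  expect_equal(as.numeric(continuous_tanimoto(matrix(c(1, 0), 1), matrix(c(0, 1), 1))), 0)
  expect_equal(as.numeric(continuous_tanimoto(matrix(c(1, 2), 1), matrix(c(2, 1), 1))),
               4 / sqrt(6), tolerance = 1e-14)
  z <- matrix(0, 1, 2)
  expect_equal(as.numeric(continuous_tanimoto(z, z)), 0)
  expect_error(continuous_tanimoto(matrix(1, 1, 2), matrix(1, 1, 3)), "mismatch")
})

test_that("prior normalization averages row and column z-scores", {
  expect_true(all(normalize_prior(matrix(5, 3, 4)) == 0))

  W <- matrix(c(0, 1, 1, 0), 2, 2)
  zr <- t(apply(W, 1, scale))     # row z-scores
  zc <- apply(W, 2, scale)
  expect_equal(normalize_prior(W), (zr + zc) / 2, ignore_attr = TRUE,
               tolerance = 1e-12)

  set.seed(4)
  R <- matrix(rnorm(100), 10, 10)
  expect_lt(abs(mean(normalize_prior(R))), 1e-10)
})

test_that("message passing reproduces the straight-line reference loop", {
  toy <- panda_toy()
  for (iters in c(5, 50)) {
    got <- panda_infer(toy$motif, toy$ppi, toy$coexpr,
                       panda_config(alpha = 0.1, tol = 1e-300, max_iter = iters))
    want <- oracle_panda(toy$motif, toy$ppi, toy$coexpr, 0.1, iters)
    expect_lt(max(abs(got$weights - want)), 1e-10)
  }
})

test_that("alpha = 0 freezes the network at the normalized motif prior", {
  toy <- panda_toy()
  g0 <- panda_infer(toy$motif, toy$ppi, toy$coexpr,
                    panda_config(alpha = 0, max_iter = 7))
  expect_equal(g0$weights, normalize_prior(toy$motif), tolerance = 1e-14)
  expect_true(g0$converged)
})

test_that("network inference is deterministic and permutation-equivariant", {
  toy <- panda_toy()
  g1 <- panda_infer(toy$motif, toy$ppi, toy$coexpr, panda_config())
  g2 <- panda_infer(toy$motif, toy$ppi, toy$coexpr, panda_config())
  expect_identical(g1$weights, g2$weights)

  perm <- c(3, 1, 2)
  gp <- panda_infer(toy$motif[perm, ], toy$ppi[perm, perm], toy$coexpr,
                    panda_config())
  expect_equal(gp$weights, g1$weights[perm, ], tolerance = 1e-12)
})

test_that("a coexpression-boosted motif-linked block gains edge weight", {
  # planted module: TF t1 motif-linked to genes 1-4; case coexpression
  # boosted inside that block, control not
  wins <- sapply(1:20, function(s) {
    set.seed(s)
    motif <- matrix(0, 3, 12,
                    dimnames = list(paste0("t", 1:3), paste0("g", 1:12)))
    motif["t1", 1:4] <- 1   # boosted block
    motif["t1", 5:8] <- 1   # matched unboosted block (identical prior)
    motif["t2", 9:12] <- rbinom(4, 1, 0.5)
    motif["t3", 9:12] <- rbinom(4, 1, 0.5)
    P <- diag(3); dimnames(P) <- list(paste0("t", 1:3), paste0("t", 1:3))
    z <- rnorm(30)
    base <- matrix(rnorm(30 * 12), 30, 12)
    base[, 1:4] <- base[, 1:4] + 2 * z   # shared factor -> high coexpression
    C <- stats::cor(base)
    dimnames(C) <- list(paste0("g", 1:12), paste0("g", 1:12))
    g <- panda_infer(motif, P, C, panda_config())
    mean(g$weights["t1", 1:4]) > mean(g$weights["t1", 5:8])
  })
  expect_equal(sum(wins), 20)
})

test_that("divergence and invalid inputs raise informative errors", {
  toy <- panda_toy()
  bad <- toy$motif; rownames(bad) <- NULL
  expect_error(panda_infer(bad, toy$ppi, toy$coexpr), "rownames")
  expect_error(panda_infer(toy$motif, toy$coexpr, toy$coexpr), "TF names")
  expect_error(panda_config(alpha = 1.5), "alpha")
  expect_error(panda_config(max_iter = 0), "max_iter")
})
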