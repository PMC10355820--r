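test_that("bicor honors affine invariance and antisymmetry", {
  set.seed(1)
  x <- runif(8, 0.1, 0.9)
  b <- make_beta(rbind(x, 0.05 + 0.9 * x, 1 - x, runif(8, 0.1, 0.9)))
  r <- bicor_matrix(b)
  expect_equal(unname(r[1, 2]), 1, tolerance = 1e-12)
  expect_equal(unname(r[1, 3]), -1, tolerance = 1e-12)
  expect_identical(diag(unclass(r)), setNames(rep(1, 4), rownames(b)))
  expect_error(bicor_matrix(random_beta(3, 3)), ">= 4 samples")
})

test_that("bicor matches the straight-from-formula pairwise oracle", {
  b <- random_beta(5, 8, seed = 2)
  r <- bicor_matrix(b)
  for (i in 1:5) for (j in 1:5)
    expect_equal(unname(r[i, j]),
                 bicor_brute(b[i, ], b[j, ]), tolerance = 1e-10)
})

test_that("zero-MAD profiles fall back to Pearson", {
  set.seed(3)
  x <- runif(10, 0.2, 0.8)
  y <- c(rep(0.5, 8), 0.6, 0.7)      # MAD = 0, not constant
  b <- make_beta(rbind(x, y))
  r <- bicor_matrix(b)
  expect_equal(unname(r[1, 2]), bicor_brute(x, y), tolerance = 1e-10)
  # fully constant profile warns and gets zero correlations
  b2 <- make_beta(rbind(x, rep(0.4, 10)))
  expect_warning(r2 <- bicor_matrix(b2), "constant")
  expect_equal(unname(r2[1, 2]), 0)
})

test_that("soft-threshold adjacency follows its closed form", {
  b <- random_beta(4, 10, seed = 4)
  r <- bicor_matrix(b)
  a <- adjacency(r, power = 6)
  off <- upper.tri(r)
  expect_equal(a[off], abs(r[off])^6, tolerance = 1e-12)
  expect_identical(unname(diag(unclass(a))), rep(1, 4))

  # perfect correlations map to 1, zero to 0; signed mode downweights
  # negative correlations
  rr <- unclass(r); rr[1, 2] <- rr[2, 1] <- 1
  rr[1, 3] <- rr[3, 1] <- 0; rr[1, 4] <- rr[4, 1] <- -1
  rr <- sim_matrix(rr, "correlation")
  au <- adjacency(rr, 4, "unsigned")
  expect_equal(unname(au[1, 2]), 1)
  expect_equal(unname(au[1, 3]), 0)
  expect_equal(unname(au[1, 4]), 1)
  as_ <- adjacency(rr, 4, "signed")
  expect_equal(unname(as_[1, 4]), 0)
  expect_equal(unname(as_[1, 2]), 1)

  expect_error(adjacency(rr, 0), "positive")
  expect_error(adjacency(au, 2), "correlation")
})

test_that("topological overlap matches closed forms and the brute force", {
  # empty graph: no overlap off-diagonal
  e <- sim_matrix(diag(4), "adjacency")
  dimnames(e) <- list(letters[1:4], letters[1:4])
  te <- tom(e)
  expect_equal(unclass(te), diag(4), ignore_attr = TRUE)

  # two isolated fully linked nodes: w_12 = (0 + 1) / (1 + 1 - 1) = 1
  a2 <- diag(2); a2[1, 2] <- a2[2, 1] <- 1
  dimnames(a2) <- list(c("a", "b"), c("a", "b"))
  t2 <- tom(sim_matrix(a2, "adjacency"))
  expect_equal(unname(t2[1, 2]), 1)

  # complete graph with unit adjacencies: identical neighborhoods, w = 1
  k5 <- matrix(1, 5, 5)
  dimnames(k5) <- list(paste0("n", 1:5), paste0("n", 1:5))
  expect_equal(unclass(tom(sim_matrix(k5, "adjacency"))),
               matrix(1, 5, 5), ignore_attr = TRUE)

  # random adjacencies against the triple-loop oracle
  for (seed in 1:3) {
    set.seed(seed)
    a <- matrix(runif(400), 20, 20)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    dimnames(a) <- list(paste0("n", 1:20), paste0("n", 1:20))
    w <- tom(sim_matrix(a, "adjacency"))
    expect_equal(unclass(w), tom_brute(a), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(w >= 0 & w <= 1 + 1e-12))
  }

  bad <- sim_matrix(matrix(c(1, 2, 2, 1), 2, 2), "adjacency")
  expect_error(tom(bad), "\\[0, 1\\]")
})

test_that("consensus TOM is the elementwise minimum after scaling", {
  b1 <- random_beta(15, 10, seed = 5)
  b2 <- random_beta(15, 12, seed = 6)
  t1 <- tom(adjacency(bicor_matrix(b1)))
  t2 <- tom(adjacency(bicor_matrix(b2)))

  # idempotence: identical inputs pass through
  expect_equal(unclass(consensus_tom(t1, t1)), unclass(t1),
               tolerance = 1e-12)

  # unscaled consensus equals a naive elementwise min loop
  cons <- consensus_tom(t1, t2, scale_quantile = NULL)
  naive <- unclass(t1)
  for (i in 1:15) for (j in 1:15)
    naive[i, j] <- min(t1[i, j], t2[i, j])
  diag(naive) <- 1
  expect_equal(unclass(cons), naive, tolerance = 1e-15)

  # scaled consensus never exceeds the first input
  cons_s <- consensus_tom(t1, t2)
  expect_true(all(unclass(cons_s) <= unclass(t1) + 1e-12))

  t3 <- t2[1:10, 1:10]
  attr(t3, "kind") <- "tom"
  class(t3) <- class(t2)
  expect_error(consensus_tom(t1, t3), "different CpG sets")
})

test_that("module cutting recovers planted blocks and handles bounds", {
  # two planted blocks with high within, low between overlap
  n <- 30
  a <- matrix(0.02, n, n)
  a[1:15, 1:15] <- 0.8
  a[16:30, 16:30] <- 0.8
  diag(a) <- 1
  dimnames(a) <- list(paste0("n", 1:n), paste0("n", 1:n))
  part <- cluster_modules(tom(sim_matrix(a, "adjacency")),
                          cutHeight = 0.95, minClusterSize = 10)
  expect_equal(length(part$sizes), 2)
  expect_equal(length(unique(part$labels[1:15])), 1)
  expect_equal(length(unique(part$labels[16:30])), 1)
  expect_true(part$labels[1] != part$labels[16])

  # CpG order invariance (identical labels after permutation)
  perm <- sample(n)
  part2 <- cluster_modules(tom(sim_matrix(a[perm, perm], "adjacency")),
                           cutHeight = 0.95, minClusterSize = 10)
  expect_identical(part2$labels[names(part$labels)], part$labels)

  # all-identical profiles collapse into one module
  one <- matrix(1, 12, 12)
  dimnames(one) <- list(paste0("c", 1:12), paste0("c", 1:12))
  p1 <- cluster_modules(tom(sim_matrix(one, "adjacency")),
                        minClusterSize = 5)
  expect_equal(length(p1$sizes), 1)
  expect_true(all(p1$labels == 1))

  # minClusterSize beyond n leaves everything unassigned
  p0 <- cluster_modules(tom(sim_matrix(one, "adjacency")),
                        minClusterSize = 50)
  expect_true(all(p0$labels == 0))

  expect_error(cluster_modules(tom(sim_matrix(one, "adjacency")),
                               cutHeight = 1.5), "cutHeight")
})

test_that("eigengenes summarize modules and recover latent factors", {
  # module of identical profiles: eigengene is the z-scored profile with
  # full explained variance
  set.seed(7)
  prof <- runif(10, 0.2, 0.8)
  b <- make_beta(matrix(rep(prof, each = 6), 6, 10, byrow = FALSE))
  part <- list(labels = setNames(rep(1L, 6), rownames(b)))
  class(part) <- "module_partition"
  eig <- module_eigengenes(b, part)
  expect_equal(unname(eig$eigengenes[, "ME1"]),
               as.numeric(scale(prof)), tolerance = 1e-10)
  expect_equal(unname(eig$var_explained["ME1"]), 1, tolerance = 1e-12)
  expect_equal(sd(eig$eigengenes[, 1]), 1, tolerance = 1e-12)

  # sample-shuffle equivariance
  shuffle <- sample(10)
  b_sh <- beta_matrix(unclass(b)[, shuffle])
  eig_sh <- module_eigengenes(b_sh, part)
  expect_equal(abs(unname(eig_sh$eigengenes[, 1])),
               abs(unname(eig$eigengenes[shuffle, 1])), tolerance = 1e-10)

  # planted 60-CpG module with the coherence factor disabled: the only
  # shared variation is the drift latent, so the eigengene must track it
  cfg0 <- sim_config(module_factor_sd = 0, seed = 8L)
  tr0 <- simulate_passaging(cfg0)
  truth0 <- tr0$truth
  tp <- list(labels = truth0$modules[truth0$modules == 1])
  class(tp) <- "module_partition"
  eig2 <- module_eigengenes(tr0$beta, tp)
  expect_gte(abs(cor(eig2$eigengenes[, 1], truth0$latent)), 0.9)

  # zero-variance members are dropped with a warning
  b_zv <- make_beta(rbind(unclass(b)[1:4, ], rep(0.3, 10)))
  part_zv <- list(labels = setNames(rep(1L, 5), rownames(b_zv)))
  class(part_zv) <- "module_partition"
  expect_warning(module_eigengenes(b_zv, part_zv), "zero-variance")
})

test_that("kME is the CpG-eigengene Pearson correlation", {
  s <- sim_triple(1)
  part <- sim_partition(1)
  eig <- module_eigengenes(s$train$beta, part)
  k <- kme(s$train$beta, eig)

  # loop oracle on a slice
  for (cg in rownames(s$train$beta)[c(1, 61, 200, 500)])
    for (m in colnames(k))
      expect_equal(k[cg, m],
                   cor(s$train$beta[cg, ], eig$eigengenes[, m]),
                   tolerance = 1e-12)

  # a pseudo-CpG equal to an eigengene has kME 1 (after squashing into
  # (0, 1) by an affine map, which preserves Pearson correlation)
  e <- eig$eigengenes[, 1]
  fake <- (e - min(e) + 0.1) / (max(e) - min(e) + 0.2)
  b2 <- make_beta(rbind(unclass(s$train$beta)[1:3, ], fake),
                  cpgs = c(rownames(s$train$beta)[1:3], "cg_fake"),
                  samples = colnames(s$train$beta))
  k2 <- kme(b2, eig)
  expect_equal(unname(k2["cg_fake", 1]), 1, tolerance = 1e-12)

  # top_kme returns exactly the module members when n = module size,
  # on a well-separated planted module
  mod1 <- names(part$labels)[part$labels == 1]
  top <- top_kme(k, 1, length(mod1))
  expect_gte(mean(top %in% mod1), 0.95)
  expect_error(top_kme(k, 99, 5), "unknown module")
})
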