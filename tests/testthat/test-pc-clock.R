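test_that("fit_pca keeps all min(n, p) components, orthonormal, ordered", {
  b <- random_beta(40, 10, seed = 5)
  p <- fit_pca(b)
  expect_equal(ncol(p$loadings), 10)
  expect_equal(crossprod(p$loadings), diag(10), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(p$component_variances) <= 1e-12))
  # trailing component of a centered decomposition is degenerate
  expect_lt(p$component_variances[10] / p$component_variances[1], 1e-20)
  expect_error(fit_pca(random_beta(5, 2)), "at least 3 samples")
})

test_that("fit_pca reconstructs its input (center + scores * loadings')", {
  b <- random_beta(5, 4, seed = 6)
  p <- fit_pca(b)
  recon <- p$center + p$loadings %*% t(p$scores)
  expect_equal(recon, unclass(b), tolerance = 1e-10, ignore_attr = TRUE)

  # duplicated sample profiles get identical scores (up to nothing: the
  # decomposition is deterministic in the samples)
  b2 <- make_beta(cbind(unclass(b), unclass(b)[, 4, drop = FALSE]),
                  samples = c(colnames(b), "s_dup"))
  p2 <- fit_pca(b2)
  expect_equal(p2$scores["s04", ], p2$scores["s_dup", ], tolerance = 1e-8)
})

test_that("planted linear signal in component 1 is recovered", {
  set.seed(7)
  b <- random_beta(60, 20, seed = 7)
  p <- fit_pca(b)
  target <- 3 + 2 * p$scores[, 1]
  clock <- fit_pc_clock(p, target, folds = 5, seed = 1)
  # component 1 dominates and in-sample fit is essentially exact
  expect_equal(which.max(abs(clock$coefficients)), 1L, ignore_attr = TRUE)
  expect_gt(cor(predict_score(clock, b), target), 0.999)
  # chosen lambda sits at the recorded CV minimum
  expect_equal(clock$lambda,
               clock$cv_curve$lambda[which.min(clock$cv_curve$mse)])
})

test_that("vanishing penalty reproduces unpenalized least squares", {
  set.seed(8)
  b <- random_beta(30, 20, seed = 8)
  p <- fit_pca(b)
  x <- p$scores[, 1:5]
  target <- drop(x %*% c(1, -2, 0.5, 0, 1)) + rnorm(20, 0, 0.1)
  pc5 <- p
  pc5$loadings <- p$loadings[, 1:5]
  pc5$scores <- x
  pc5$component_variances <- p$component_variances[1:5]
  clock <- fit_pc_clock(pc5, target, lambda = 1e-9)
  ols <- lm.fit(cbind(1, x), target)$coefficients
  pred_ols <- drop(cbind(1, x) %*% ols)
  expect_equal(unname(predict_score(clock, b)), unname(pred_ols),
               tolerance = 1e-6)
})

test_that("degenerate targets and fold settings are rejected", {
  b <- random_beta(20, 8, seed = 9)
  p <- fit_pca(b)
  expect_error(fit_pc_clock(p, rep(1, 8), folds = 4), "constant")
  expect_error(fit_pc_clock(p, rnorm(8), folds = 10), "exceed")
  expect_error(fit_pc_clock(p, rnorm(8), folds = 2), ">= 3")
  expect_error(fit_pc_clock(p, c(rnorm(7), NA), folds = 4), "finite")
})

test_that("scores are invariant to CpG and sample order", {
  b <- random_beta(50, 12, seed = 10)
  set.seed(2); target <- rnorm(12)
  clock <- fit_pc_clock(fit_pca(b), target, folds = 4, seed = 3)
  newdata <- random_beta(50, 6, seed = 11)
  s1 <- predict_score(clock, newdata)
  shuffled <- beta_matrix(unclass(newdata)[sample(50), ])
  expect_equal(predict_score(clock, shuffled), s1)

  # extra CpGs ignored; missing CpGs named in the error
  extra <- make_beta(rbind(unclass(newdata),
                           matrix(0.5, 2, 6,
                                  dimnames = list(c("zz1", "zz2"), NULL))),
                     cpgs = c(rownames(newdata), "zz1", "zz2"))
  expect_equal(predict_score(clock, extra), s1)
  expect_error(predict_score(clock, beta_matrix(unclass(newdata)[-1, ])),
               "cg001")
})

test_that("explicit loop projection matches the matrix path", {
  b <- random_beta(25, 10, seed = 12)
  set.seed(3); target <- rnorm(10)
  clock <- fit_pc_clock(fit_pca(b), target, folds = 3, seed = 4)
  newdata <- random_beta(25, 4, seed = 13)
  fast <- predict_score(clock, newdata)
  slow <- vapply(colnames(newdata), function(s) {
    total <- clock$intercept
    for (k in seq_along(clock$coefficients)) {
      proj <- 0
      for (cg in clock$cpg_ids)
        proj <- proj + (newdata[cg, s] - clock$center[cg]) *
          clock$loadings[cg, k]
      total <- total + clock$coefficients[k] * proj
    }
    total
  }, numeric(1))
  expect_equal(fast, slow, tolerance = 1e-10)
})

test_that("training-sample scores equal in-sample fitted values", {
  b <- random_beta(30, 10, seed = 14)
  p <- fit_pca(b)
  set.seed(4); target <- rnorm(10)
  clock <- fit_pc_clock(p, target, folds = 3, seed = 5)
  fitted <- drop(clock$intercept + p$scores %*% clock$coefficients)
  expect_equal(unname(predict_score(clock, b)), unname(fitted),
               tolerance = 1e-10)
})

test_that("driver selection reduces to top |loading| for one component", {
  b <- random_beta(40, 8, seed = 15)
  p <- fit_pca(b)
  # the fitted coefficients are overwritten below; the small-fold CV
  # grouping warning is irrelevant here
  clock <- suppressWarnings(fit_pc_clock(p, rnorm(8), folds = 4, seed = 6))
  clock$coefficients[] <- 0
  clock$coefficients[2] <- 1.5
  sel <- select_driver_cpgs(clock, 7)
  expected <- rownames(b)[order(-abs(p$loadings[, 2]), rownames(b))][1:7]
  expect_identical(sel, expected)
  # sign convention independence: flipping a loading column changes nothing
  clock2 <- clock
  clock2$loadings[, 2] <- -clock2$loadings[, 2]
  expect_identical(select_driver_cpgs(clock2, 7), sel)
  # exhaustive case and error paths
  expect_setequal(select_driver_cpgs(clock, 40), rownames(b))
  expect_error(select_driver_cpgs(clock, 41), "exceeds")
  clock$coefficients[] <- 0
  expect_error(select_driver_cpgs(clock, 5), "no active components")
})

test_that("top-ranked driver CpGs are planted module members", {
  # the extraction claims high precision at the top of the importance
  # ranking, not full recall of every planted CpG
  for (seed in 1:3) {
    s <- sim_triple(seed)
    truth <- s$train$truth
    clock <- fit_pc_clock(fit_pca(s$train$beta), s$train$sheet$cpd,
                          folds = 10, seed = seed)
    planted <- names(truth$modules)[truth$modules > 0]
    sel <- select_driver_cpgs(clock, 60)
    expect_gte(mean(sel %in% planted), 0.95)
  }
})

test_that("increasing the penalty never adds active components", {
  b <- random_beta(30, 15, seed = 16)
  p <- fit_pca(b)
  set.seed(5); target <- p$scores[, 1] + rnorm(15, 0, 0.5)
  grid <- 10^seq(-3, 2, length.out = 8)
  active <- vapply(grid, function(l)
    sum(fit_pc_clock(p, target, lambda = l)$coefficients != 0),
    numeric(1))
  expect_true(all(diff(active) <= 0))
})

test_that("permuted targets yield no held-out predictive skill", {
  s <- sim_triple(1)
  p <- fit_pca(s$train$beta)
  rs <- vapply(1:20, function(i) {
    set.seed(100 + i)
    perm <- sample(s$train$sheet$cpd)
    clock <- fit_pc_clock(p, perm, folds = 10, seed = i)
    sc <- predict_score(clock, s$val$beta)
    if (sd(sc) == 0) 0 else cor(sc, s$val$sheet$cpd)
  }, numeric(1))
  expect_gt(t.test(rs, alternative = "greater")$p.value, 0.05)
})
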