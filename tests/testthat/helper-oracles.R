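# Independent straight-from-formula oracles and small fixture builders.
# These deliberately avoid the package's vectorized code paths.

# Biweight midcorrelation of two vectors, straight from the defining
# formula: u = (x - med) / (9 * MAD), w = (1 - u^2)^2 * 1(|u| < 1),
# correlation of weighted deviations; Pearson fallback when MAD = 0.
bicor_brute <- function(x, y) {
  dev1 <- function(v) {
    med <- median(v)
    madv <- median(abs(v - med))
    if (madv == 0) return(v - mean(v))
    u <- (v - med) / (9 * madv)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (v - med) * w
  }
  a <- dev1(x); b <- dev1(y)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Topological overlap by triple loop, straight from the definition.
tom_brute <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  w <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    w[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  w
}

# Small labelled beta matrix from a numeric matrix.
make_beta <- function(values, cpgs = NULL, samples = NULL) {
  if (is.null(cpgs)) cpgs <- sprintf("cg%03d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  rownames(values) <- cpgs
  colnames(values) <- samples
  beta_matrix(values)
}

# Random beta matrix with values safely inside (0, 1).
random_beta <- function(p, n, seed = 1) {
  set.seed(seed)
  make_beta(matrix(runif(p * n, 0.05, 0.95), p, n))
}

# One standard simulated training/tissue/validation triple, memoised per
# seed so several tests can share it without re-simulating.
sim_triple <- local({
  cache <- list()
  function(seed = 1L) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      cfg <- sim_config(seed = seed)
      tr <- simulate_passaging(cfg)
      ts <- simulate_tissue(cfg, tr$truth)
      val <- simulate_passaging(cfg, seed = seed + 500L, n = 14,
                                sample_prefix = "val", truth = tr$truth)
      cache[[key]] <<- list(cfg = cfg, train = tr, tissue = ts, val = val)
    }
    cache[[key]]
  }
})

# Consensus partition for the standard pair, memoised.
sim_partition <- local({
  cache <- list()
  function(seed = 1L) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      s <- sim_triple(seed)
      cons <- consensus_tom(tom(adjacency(bicor_matrix(s$train$beta))),
                            tom(adjacency(bicor_matrix(s$tissue$beta))))
      cache[[key]] <<- cluster_modules(cons)
    }
    cache[[key]]
  }
})

# Adjusted Rand index from the contingency-table formula.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab)
  exp_idx <- sum_comb(rowSums(tab)) * sum_comb(colSums(tab)) / choose(n, 2)
  max_idx <- (sum_comb(rowSums(tab)) + sum_comb(colSums(tab))) / 2
  if (max_idx == exp_idx) return(1)
  (idx - exp_idx) / (max_idx - exp_idx)
}

# Run the full two-dataset consensus pipeline for one seed and report
# module recovery plus physiological-module selection.
run_consensus_pipeline <- function(seed) {
  cfg <- sim_config(seed = seed)
  tr <- simulate_passaging(cfg)
  ts <- simulate_tissue(cfg, tr$truth)
  val <- simulate_passaging(cfg, seed = seed + 500L, n = 14,
                            sample_prefix = "val", truth = tr$truth)
  cons <- consensus_tom(tom(adjacency(bicor_matrix(tr$beta))),
                        tom(adjacency(bicor_matrix(ts$beta))))
  part <- cluster_modules(cons, deepSplit = 1, cutHeight = 0.95,
                          minClusterSize = 50)
  truth <- tr$truth
  physio_mods <- names(truth$module_type)[truth$module_type == "physio"]
  phys_cpgs <- names(truth$modules)[
    truth$modules %in% as.integer(physio_mods)]
  ari_physio <- ari(truth$modules[phys_cpgs], part$labels[phys_cpgs])

  selection_exact <- FALSE
  if (length(part$sizes) > 0) {
    clocks <- fit_module_clocks(tr$beta, tr$sheet, part, seed = seed)
    sel <- tryCatch(
      select_modules(clocks,
                     list(beta = val$beta, sheet = val$sheet),
                     list(beta = ts$beta, sheet = ts$sheet),
                     r_min = 0.5),
      error = function(e) NULL)
    if (!is.null(sel)) {
      # map each selected consensus module to the planted module holding
      # the majority of its CpGs
      mapped <- vapply(sel$selected, function(lab) {
        cpgs <- names(part$labels)[part$labels == as.integer(lab)]
        tt <- table(truth$modules[cpgs])
        best <- names(tt)[which.max(tt)]
        if (tt[best] / length(cpgs) >= 0.8) best else NA_character_
      }, character(1))
      selection_exact <- !anyNA(mapped) &&
        setequal(mapped, physio_mods)
    }
  }
  list(ari = ari_physio, selection_exact = selection_exact,
       part = part, train = tr, tissue = ts, val = val, cfg = cfg)
}
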