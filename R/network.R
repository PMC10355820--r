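sim_matrix <- function(values, kind) {
  stopifnot(kind %in% c("correlation", "adjacency", "tom"))
  attr(values, "kind") <- kind
  class(values) <- c("sim_matrix", "matrix", "array")
  values
}

sim_kind <- function(x) attr(x, "kind")

#' @export
print.sim_matrix <- function(x, ...) {
  cat(sprintf("sim_matrix (%s): %d x %d\n", sim_kind(x), nrow(x), ncol(x)))
  invisible(x)
}

#' Biweight midcorrelation matrix between CpG profiles
#'
#' Robust correlation used for comethylation adjacencies. For each CpG
#' profile `x` across samples, deviations from the median are weighted
#' by `w = (1 - u^2)^2 * 1(|u| < 1)` with
#' `u = (x - median(x)) / (9 * MAD)` (MAD unscaled); the biweight
#' midcorrelation of two CpGs is the correlation of their weighted
#' deviations. CpGs with zero MAD fall back to ordinary (Pearson)
#' centered deviations, so pairs involving them reduce to Pearson
#' correlation.
#'
#' @param m A [beta_matrix()] (CpGs x samples), at least 4 samples.
#' @return A symmetric CpGs x CpGs `sim_matrix` of kind `"correlation"`
#'   with unit diagonal.
#' @export
bicor_matrix <- function(m) {
  if (ncol(m) < 4) stop("biweight midcorrelation requires >= 4 samples")
  d <- t(apply(m, 1, bicor_deviations))
  nrm <- sqrt(rowSums(d^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sum(zero), " constant CpG profile(s); correlations set to 0")
    nrm[zero] <- 1
  }
  d <- d / nrm
  r <- tcrossprod(d)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(rownames(m), rownames(m))
  sim_matrix(r, "correlation")
}

# Weighted (or Pearson-fallback) deviations for one profile.
bicor_deviations <- function(x) {
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  if (mad0 == 0) return(x - mean(x))
  u <- (x - med) / (9 * mad0)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  (x - med) * w
}

#' Soft-threshold adjacency from a correlation matrix
#'
#' @param corr A `sim_matrix` of kind `"correlation"`.
#' @param power Soft-threshold exponent, positive (default 6).
#' @param mode `"unsigned"`: `a = |r|^power`; `"signed"`:
#'   `a = ((1 + r) / 2)^power`.
#' @return A `sim_matrix` of kind `"adjacency"`, unit diagonal (the
#'   diagonal is excluded inside topological-overlap sums).
#' @export
adjacency <- function(corr, power = 6, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  if (!identical(sim_kind(corr), "correlation"))
    stop("`corr` must be a correlation sim_matrix")
  if (power <= 0) stop("power must be positive")
  a <- if (mode == "unsigned") abs(corr)^power
       else ((1 + corr) / 2)^power
  diag(a) <- 1
  sim_matrix(unclass(a), "adjacency")
}

#' Topological overlap matrix
#'
#' `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`,
#' where `l_ij = sum_{u != i,j} a_iu * a_uj` counts shared neighbors and
#' `k_i = sum_{u != i} a_iu` is the connectivity; the diagonal is 1.
#' Nodes with identical neighborhoods and `a_ij = 1` attain overlap 1.
#'
#' @param a A `sim_matrix` of kind `"adjacency"` with values in
#'   `[0, 1]`.
#' @return A `sim_matrix` of kind `"tom"`, values in `[0, 1]`.
#' @export
tom <- function(a) {
  if (!identical(sim_kind(a), "adjacency"))
    stop("`a` must be an adjacency sim_matrix")
  if (min(a) < 0 || max(a) > 1)
    stop("adjacency values must lie in [0, 1]")
  a0 <- unclass(a)
  diag(a0) <- 0
  l <- a0 %*% a0           # diag(a0) = 0 removes the u = i, j terms
  k <- rowSums(a0)
  denom <- outer(k, k, pmin) + 1 - a0
  w <- (l + a0) / denom
  diag(w) <- 1
  dimnames(w) <- dimnames(a)
  sim_matrix(w, "tom")
}

#' Consensus topological overlap of two datasets
#'
#' Rescales the second TOM so its off-diagonal `scale_quantile` quantile
#' matches the first's (a power transform, standard consensus scaling),
#' then takes the elementwise minimum: structure must be present in both
#' datasets to survive. The consensus dissimilarity used for clustering
#' is `1 - consensus`.
#'
#' @param tom_a,tom_b `sim_matrix` objects of kind `"tom"` over the same
#'   CpGs.
#' @param scale_quantile Quantile in `(0, 1]` matched between the two
#'   TOMs; `NULL` disables scaling.
#' @return A `sim_matrix` of kind `"tom"`, the consensus TOM.
#' @export
consensus_tom <- function(tom_a, tom_b, scale_quantile = 0.95) {
  if (!identical(sim_kind(tom_a), "tom") ||
      !identical(sim_kind(tom_b), "tom"))
    stop("inputs must be TOM sim_matrix objects")
  if (!identical(rownames(tom_a), rownames(tom_b)))
    stop("TOMs are over different CpG sets")
  b <- unclass(tom_b)
  if (!is.null(scale_quantile)) {
    off <- upper.tri(tom_a)
    qa <- stats::quantile(tom_a[off], scale_quantile, names = FALSE)
    qb <- stats::quantile(b[off], scale_quantile, names = FALSE)
    if (qa > 0 && qa < 1 && qb > 0 && qb < 1) {
      b <- b^(log(qa) / log(qb))
    } else {
      warning("degenerate scaling quantile; consensus computed unscaled")
    }
  }
  cons <- pmin(unclass(tom_a), b)
  diag(cons) <- 1
  dimnames(cons) <- dimnames(tom_a)
  sim_matrix(cons, "tom")
}

#' Cut a consensus TOM dendrogram into modules
#'
#' Average-linkage hierarchical clustering on `1 - consensus TOM`, cut
#' statically at `cutHeight`; clusters smaller than `minClusterSize` are
#' unassigned (label 0). Labels are integers ordered by decreasing
#' module size (1 = largest). The `deepSplit` parameter is accepted and
#' recorded for provenance but the cut applies height and minimum-size
#' semantics only (no hybrid dynamic refinement); fixtures and defaults
#' are chosen so module recovery does not hinge on hybrid refinements.
#'
#' @param consensus A `sim_matrix` of kind `"tom"`.
#' @param deepSplit Recorded split-sensitivity setting (default 1).
#' @param cutHeight Static cut height on the dissimilarity dendrogram,
#'   in `(0, 1]` (default 0.95).
#' @param minClusterSize Minimum module size (default 50).
#' @return A `module_partition`: `labels` (named integer vector, 0 =
#'   unassigned), `sizes`, the `dendrogram` (an `hclust`), and the cut
#'   `params`.
#' @export
cluster_modules <- function(consensus, deepSplit = 1, cutHeight = 0.95,
                            minClusterSize = 50) {
  if (!identical(sim_kind(consensus), "tom"))
    stop("`consensus` must be a TOM sim_matrix")
  if (cutHeight <= 0 || cutHeight > 1)
    stop("cutHeight must lie in (0, 1]")
  d <- stats::as.dist(1 - unclass(consensus))
  dend <- stats::hclust(d, method = "average")
  # average linkage is monotone; ties can leave float-level height
  # inversions that cutree rejects
  dend$height <- cummax(dend$height)
  raw <- stats::cutree(dend, h = cutHeight)
  tab <- table(raw)
  keep <- names(tab)[tab >= minClusterSize]
  labels <- rep(0L, length(raw))
  names(labels) <- rownames(consensus)
  if (length(keep) > 0) {
    keep <- keep[order(-tab[keep], as.integer(keep))]
    for (i in seq_along(keep))
      labels[raw == as.integer(keep[i])] <- i
  }
  sizes <- table(labels[labels > 0])
  structure(list(labels = labels, sizes = sizes, dendrogram = dend,
                 params = list(deepSplit = deepSplit,
                               cutHeight = cutHeight,
                               minClusterSize = minClusterSize)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules, %d/%d CpGs assigned\n",
              length(x$sizes), sum(x$labels > 0), length(x$labels)))
  if (length(x$sizes) > 0) print(x$sizes)
  invisible(x)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' member CpG profiles after per-CpG standardization, scaled to unit
#' sample variance, with sign fixed so the mean correlation of members
#' with their eigengene (mean kME) is non-negative.
#'
#' @param m A [beta_matrix()] covering the partition's CpGs.
#' @param part A `module_partition` (labels > 0 are modules).
#' @return An `eigengene_set`: `eigengenes` (samples x modules matrix,
#'   columns `ME<label>`) and `var_explained` (per-module fraction of
#'   standardized variance carried by the eigengene).
#' @export
module_eigengenes <- function(m, part) {
  labs <- sort(unique(part$labels[part$labels > 0]))
  if (length(labs) == 0) stop("partition has no assigned modules")
  eg <- matrix(NA_real_, ncol(m), length(labs),
               dimnames = list(colnames(m), paste0("ME", labs)))
  ve <- stats::setNames(numeric(length(labs)), paste0("ME", labs))
  for (j in seq_along(labs)) {
    members <- names(part$labels)[part$labels == labs[j]]
    members <- intersect(members, rownames(m))
    if (length(members) == 0) stop("module ", labs[j], " is empty")
    x <- m[members, , drop = FALSE]
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0)) {
      warning(sum(sds == 0), " zero-variance CpG(s) dropped in module ",
              labs[j])
      x <- x[sds > 0, , drop = FALSE]
    }
    if (nrow(x) < 2) stop("module ", labs[j], " has fewer than 2 usable CpGs")
    z <- t(scale(t(x)))
    s <- svd(z, nu = 0, nv = 1)
    e <- s$v[, 1]
    e <- e / stats::sd(e)
    if (mean(stats::cor(t(x), e)) < 0) e <- -e
    eg[, j] <- e
    ve[j] <- s$d[1]^2 / sum(s$d^2)
  }
  structure(list(eigengenes = eg, var_explained = ve),
            class = "eigengene_set")
}

#' Eigengene-based connectivity (kME)
#'
#' Pearson correlation of every CpG profile with every module eigengene.
#'
#' @param m A [beta_matrix()].
#' @param eig An `eigengene_set` over the same samples.
#' @return CpGs x modules matrix of correlations; zero-variance CpGs get
#'   kME 0 with a warning.
#' @export
kme <- function(m, eig) {
  if (!identical(colnames(m), rownames(eig$eigengenes)))
    stop("sample sets of beta matrix and eigengenes differ")
  sds <- apply(m, 1, stats::sd)
  k <- matrix(0, nrow(m), ncol(eig$eigengenes),
              dimnames = list(rownames(m), colnames(eig$eigengenes)))
  ok <- sds > 0
  if (!all(ok)) warning(sum(!ok), " zero-variance CpG(s); kME set to 0")
  k[ok, ] <- stats::cor(t(m[ok, , drop = FALSE]), eig$eigengenes)
  k
}

#' Top CpGs of a module by kME
#'
#' Hub membership is ranked by `|kME|`: modules mix CpGs that gain and
#' lose methylation along the same latent factor, so the sign of the
#' eigengene correlation reflects methylation direction, not connection
#' strength.
#'
#' @param kme_matrix Output of [kme()].
#' @param module Module label (integer or `"ME<label>"` column name).
#' @param n Number of CpGs to return.
#' @return Character vector of `n` CpG ids by descending `|kME|`, ties
#'   broken lexicographically.
#' @export
top_kme <- function(kme_matrix, module, n) {
  col <- if (is.numeric(module)) paste0("ME", module) else module
  if (!col %in% colnames(kme_matrix)) stop("unknown module: ", module)
  if (n > nrow(kme_matrix)) stop("n exceeds the number of CpGs")
  ord <- order(-abs(kme_matrix[, col]), rownames(kme_matrix))
  rownames(kme_matrix)[ord[seq_len(n)]]
}
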