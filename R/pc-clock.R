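#' Principal-component decomposition of a beta matrix
#'
#' Centers each CpG by its training mean (no variance scaling, following
#' the PC-clock convention) and retains all `min(n_samples, n_CpGs)`
#' components, including the degenerate trailing component implied by
#' centering. Samples are the observations; loadings are an orthonormal
#' CpGs x components matrix.
#'
#' @param m A [beta_matrix()] (CpGs x samples), at least 3 samples, no
#'   missing values.
#' @return A `pc_model`: `cpg_ids`, `center` (per-CpG mean), `loadings`
#'   (CpGs x components, orthonormal columns), `component_variances`
#'   (non-increasing), and the training `scores` (samples x components).
#' @export
fit_pca <- function(m) {
  if (ncol(m) < 3) stop("PCA requires at least 3 samples")
  if (anyNA(m)) stop("beta matrix contains missing values")
  center <- rowMeans(m)
  xc <- m - center
  k <- min(dim(m))
  s <- svd(xc, nu = k, nv = k)
  loadings <- s$u
  scores <- s$v %*% diag(s$d[seq_len(k)], k, k)
  rownames(loadings) <- rownames(m)
  colnames(loadings) <- paste0("PC", seq_len(k))
  rownames(scores) <- colnames(m)
  colnames(scores) <- colnames(loadings)
  structure(list(cpg_ids = rownames(m), center = center,
                 loadings = loadings,
                 component_variances = s$d[seq_len(k)]^2 / (ncol(m) - 1),
                 scores = scores),
            class = "pc_model")
}

# Project samples of a beta matrix onto a fitted PC basis.
project_scores <- function(pcm, m) {
  missing <- setdiff(pcm$cpg_ids, rownames(m))
  if (length(missing) > 0)
    stop("beta matrix lacks ", length(missing), " model CpG(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ..." else "")
  x <- m[pcm$cpg_ids, , drop = FALSE]
  crossprod(x - pcm$center, pcm$loadings)
}

# Elastic-net fit over a score matrix: lambda chosen at minimum mean
# 10-fold CV MSE unless an explicit lambda is supplied; folds drawn
# deterministically from `seed`.
fit_enet <- function(scores, target, alpha, folds, seed, lambda = NULL) {
  if (!all(is.finite(target))) stop("target must be finite")
  if (stats::sd(target) == 0) stop("target is constant")
  n <- nrow(scores)
  # Numerically constant columns (e.g. the degenerate trailing component
  # of a centered PCA) blow up under internal standardization; they carry
  # no information and get coefficient 0, keeping the full coefficient
  # length.
  sds <- apply(scores, 2, stats::sd)
  live <- sds > max(sds) * 1e-8
  full_coef <- stats::setNames(numeric(ncol(scores)), colnames(scores))
  restore <- function(en) {
    full_coef[live] <- en$coefficients
    en$coefficients <- full_coef
    en
  }
  scores <- scores[, live, drop = FALSE]
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(scores, target, alpha = alpha)
    cf <- as.matrix(stats::coef(fit, s = lambda, exact = TRUE,
                                x = scores, y = target, alpha = alpha))
    return(restore(list(alpha = alpha, lambda = lambda,
                        intercept = cf[1, 1], coefficients = cf[-1, 1],
                        cv_folds = NA_integer_, cv_seed = NA_integer_,
                        cv_curve = NULL)))
  }
  if (folds < 3) stop("folds must be >= 3")
  if (folds > n) stop("folds exceed sample count")
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = n))
  cvfit <- glmnet::cv.glmnet(scores, target, alpha = alpha,
                             foldid = foldid)
  cf <- as.matrix(stats::coef(cvfit, s = "lambda.min"))
  restore(list(alpha = alpha, lambda = cvfit$lambda.min,
               intercept = cf[1, 1], coefficients = cf[-1, 1],
               cv_folds = folds, cv_seed = seed,
               cv_curve = data.frame(lambda = cvfit$lambda,
                                     mse = cvfit$cvm)))
}

#' Train a PC clock against a continuous target
#'
#' Fits an elastic net over the component scores of a fitted PC basis,
#' with the penalty chosen at the minimum mean cross-validated squared
#' error over a descending log-spaced lambda grid. The trained clock
#' predicts a drift score (e.g. cumulative population doublings, or age)
#' from any beta matrix containing its CpGs.
#'
#' @param pcm A `pc_model` from [fit_pca()].
#' @param target Per-sample numeric target (cPD or age), in the order of
#'   the training samples.
#' @param target_name Label recorded in the clock (`"cpd"` or `"age"`).
#' @param alpha Elastic-net mixing parameter in `[0, 1]`; 0.5 by default
#'   (equal L1/L2 mix).
#' @param folds Cross-validation folds (default 10).
#' @param seed Integer seed for the deterministic fold assignment.
#' @param lambda Optional explicit penalty; skips cross-validation.
#' @return A `pc_clock`: the PC basis plus elastic-net coefficients over
#'   component scores, intercept, chosen lambda, and the CV curve.
#' @export
fit_pc_clock <- function(pcm, target, target_name = "cpd", alpha = 0.5,
                         folds = 10, seed = 1L, lambda = NULL) {
  if (length(target) != nrow(pcm$scores))
    stop("target length must match training samples")
  en <- fit_enet(pcm$scores, target, alpha, folds, seed, lambda)
  structure(c(list(cpg_ids = pcm$cpg_ids, center = pcm$center,
                   loadings = pcm$loadings,
                   component_variances = pcm$component_variances,
                   target_name = target_name), en),
            class = "pc_clock")
}

#' @export
print.pc_clock <- function(x, ...) {
  cat(sprintf(
    "pc_clock (%s): %d CpGs, %d components, %d active (lambda = %.4g)\n",
    x$target_name, length(x$cpg_ids), length(x$coefficients),
    sum(x$coefficients != 0), x$lambda))
  invisible(x)
}

#' Score samples with a trained PC clock
#'
#' `score = intercept + sum_k coef_k * ((beta - center)' loading_k)`.
#' Invariant to CpG row order; extra CpGs in `m` are ignored; a missing
#' clock CpG is an error.
#'
#' @param clock A `pc_clock`.
#' @param m A [beta_matrix()] containing all clock CpGs.
#' @return Named numeric vector of per-sample scores.
#' @export
predict_score <- function(clock, m) {
  sc <- project_scores(clock, m)
  drop(clock$intercept + sc %*% clock$coefficients)
}

#' Extract driver CpGs from a PC clock's loadings
#'
#' For each component with a non-zero elastic-net coefficient, the
#' absolute loadings are z-normalized across CpGs; a CpG's importance is
#' the sum (or maximum) of these normalized loadings, each weighted by
#' the component's contribution to the predicted score,
#' `|coef_k| * sd(score_k)` (raw coefficients alone would overweight
#' low-variance trailing components, which need large raw coefficients
#' to contribute at all). The `top_k` CpGs by importance are returned,
#' ties broken lexicographically by CpG id.
#'
#' @param clock A `pc_clock` with at least one non-zero coefficient.
#' @param top_k Number of CpGs to return (at most the clock's CpG
#'   count).
#' @param aggregate `"sum"` (default): importance
#'   `sum_k |coef_k| * sd_k * z_k(cpg)`; `"max"`: max over components of
#'   the same terms.
#' @return Character vector of `top_k` CpG ids in decreasing importance.
#' @export
select_driver_cpgs <- function(clock, top_k,
                               aggregate = c("sum", "max")) {
  aggregate <- match.arg(aggregate)
  if (top_k > length(clock$cpg_ids))
    stop("top_k exceeds the number of clock CpGs")
  active <- which(clock$coefficients != 0)
  if (length(active) == 0) stop("clock has no active components")
  zmat <- vapply(active, function(k) {
    a <- abs(clock$loadings[, k])
    w <- abs(clock$coefficients[k]) *
      sqrt(clock$component_variances[k])
    w * (a - mean(a)) / stats::sd(a)
  }, numeric(length(clock$cpg_ids)))
  importance <- if (aggregate == "sum") rowSums(zmat)
                else apply(zmat, 1, max)
  ord <- order(-importance, clock$cpg_ids)
  clock$cpg_ids[ord[seq_len(top_k)]]
}
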