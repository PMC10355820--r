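#' Base-2 logit (M-value) and inverse
#'
#' Methylation beta values are generated through the standard M-value
#' convention `M = log2(beta / (1 - beta))`; additive Gaussian latent
#' structure lives on the M scale and is mapped back through the strictly
#' monotone base-2 logistic.
#'
#' @param beta Beta values in (0, 1).
#' @param m M-values.
#' @return `logit2()` returns M-values; `expit2()` returns betas in (0, 1).
#' @export
logit2 <- function(beta) log2(beta / (1 - beta))

#' @rdname logit2
#' @export
expit2 <- function(m) {
  e <- 2^m
  e / (1 + e)
}

#' Simulation configuration
#'
#' Defaults mirror the scale of a telomerase-immortalized astrocyte
#' passaging series paired with an aging-liver cohort: 31 training
#' samples spanning roughly 43 to 75 cumulative population doublings
#' (cPD), and 85 tissue samples aged 23 to 83 years. Two physiological
#' modules (drifting with cPD in vitro and with age in vivo) and two
#' culture-artifact modules (driven by a factor correlated with cPD in
#' vitro only) are planted, each of 60 CpGs, against unstructured
#' background CpGs.
#'
#' On the M-value (base-2 logit) scale, a module CpG is
#' `m = mu + lambda * f + gamma * h + noise`, where `f` is the module's
#' primary driver (`slope * cPD` for physiological modules in vitro,
#' `slope * age` in vivo; a cPD-correlated culture factor for artifact
#' modules in vitro, nothing in vivo) and `h` is a module-specific
#' comethylation coherence factor, independent of the drift covariate
#' and redrawn per dataset, which makes distinct modules identifiable as
#' distinct comethylation blocks (real comethylation modules cohere
#' beyond their age association). `lambda = sign * loading_scale`;
#' `gamma = sign * weight` with the per-CpG weight drawn from
#' `factor_weight_range`, the sign shared with `lambda` so each module
#' stays internally coherent.
#'
#' @param n_physio_modules Number of modules driven by cPD/age.
#' @param n_artifact_modules Number of modules driven only in vitro.
#' @param module_size CpGs per module; keep at or above the
#'   `minClusterSize` of the intended clustering run.
#' @param n_background Unstructured CpGs.
#' @param loading_scale Drift-factor loading magnitude, M-value units.
#' @param noise_sd Residual SD, M-value units.
#' @param slope Drift per cPD unit (or per year of age), M-value units.
#' @param artifact_cor Correlation between each artifact factor and cPD
#'   in the passaging dataset -- the confound the two-dataset consensus
#'   must break.
#' @param module_factor_sd SD of the per-module coherence factor,
#'   M-value units (0 disables it).
#' @param factor_weight_range Per-CpG weight support for the coherence
#'   factor.
#' @param n_train,n_tissue Sample counts for the passaging and tissue
#'   datasets.
#' @param cpd_range,age_range Covariate supports (uniform draws).
#' @param seed Integer seed; all randomness in a simulation call flows
#'   from one seed through one generator stream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_physio_modules = 2, n_artifact_modules = 2,
                       module_size = 60, n_background = 280,
                       loading_scale = 1, noise_sd = 0.25, slope = 0.05,
                       artifact_cor = 0.8, module_factor_sd = 0.6,
                       factor_weight_range = c(0.5, 1.5),
                       n_train = 31, n_tissue = 85,
                       cpd_range = c(43, 75), age_range = c(23, 83),
                       seed = 1L) {
  cfg <- list(n_physio_modules = n_physio_modules,
              n_artifact_modules = n_artifact_modules,
              module_size = module_size, n_background = n_background,
              loading_scale = loading_scale, noise_sd = noise_sd,
              slope = slope, artifact_cor = artifact_cor,
              module_factor_sd = module_factor_sd,
              factor_weight_range = factor_weight_range,
              n_train = n_train, n_tissue = n_tissue,
              cpd_range = cpd_range, age_range = age_range,
              seed = as.integer(seed))
  counts <- c(cfg$n_physio_modules, cfg$n_artifact_modules,
              cfg$module_size, cfg$n_background, cfg$n_train,
              cfg$n_tissue)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$module_factor_sd < 0) stop("module_factor_sd must be >= 0")
  if (cfg$n_physio_modules + cfg$n_artifact_modules < 1)
    stop("at least one module must be planted")
  class(cfg) <- "sim_config"
  cfg
}

# Draw the fixed CpG universe: baseline M-values, module assignment,
# drift loadings (lambda) and coherence-factor loadings (gamma), with
# one sign per CpG shared between the two. Consumes the active RNG
# stream.
draw_universe <- function(config) {
  n_mod <- config$n_physio_modules + config$n_artifact_modules
  p <- n_mod * config$module_size + config$n_background
  cpg_ids <- sprintf("cg%07d", seq_len(p))
  modules <- c(rep(seq_len(n_mod), each = config$module_size),
               rep(0L, config$n_background))
  names(modules) <- cpg_ids
  module_type <- c(rep("physio", config$n_physio_modules),
                   rep("artifact", config$n_artifact_modules))
  names(module_type) <- as.character(seq_len(n_mod))
  mu <- stats::runif(p, logit2(0.1), logit2(0.9))
  sgn <- sample(c(-1, 1), p, replace = TRUE)
  lambda <- ifelse(modules > 0, sgn * config$loading_scale, 0)
  in_physio <- modules > 0 &
    module_type[as.character(pmax(modules, 1))] == "physio"
  gamma <- ifelse(in_physio,
                  sgn * stats::runif(p, config$factor_weight_range[1],
                                     config$factor_weight_range[2]),
                  0)
  names(mu) <- names(lambda) <- names(gamma) <- cpg_ids
  list(cpg_ids = cpg_ids, modules = modules, module_type = module_type,
       mu = mu, lambda = lambda, gamma = gamma)
}

# M = mu + lambda * driver + gamma * coherence + noise, mapped to beta.
# `drivers` and `coherence` are per-module-label lists of per-sample
# latent values (NULL entries mean no factor).
emit_beta <- function(universe, drivers, coherence, n, noise_sd,
                      sample_ids) {
  p <- length(universe$cpg_ids)
  D <- matrix(0, p, n)
  H <- matrix(0, p, n)
  for (lab in names(universe$module_type)) {
    idx <- which(universe$modules == as.integer(lab))
    if (!is.null(drivers[[lab]]))
      D[idx, ] <- matrix(drivers[[lab]], length(idx), n, byrow = TRUE)
    if (!is.null(coherence[[lab]]))
      H[idx, ] <- matrix(coherence[[lab]], length(idx), n, byrow = TRUE)
  }
  M <- universe$mu + universe$lambda * D + universe$gamma * H +
    matrix(stats::rnorm(p * n, 0, noise_sd), p, n)
  b <- expit2(M)
  rownames(b) <- universe$cpg_ids
  colnames(b) <- sample_ids
  beta_matrix(b)
}

# Factor with target correlation r to x, same mean and SD as x. A
# constant x (e.g. zero drift slope) admits no correlated partner and
# passes through unchanged.
correlated_factor <- function(x, r) {
  if (stats::sd(x) == 0) return(x)
  z <- (x - mean(x)) / stats::sd(x)
  g <- r * z + sqrt(1 - r^2) * stats::rnorm(length(x))
  mean(x) + stats::sd(x) * g
}

# Coherence factors are drawn orthogonal in-sample to the drift
# covariate and to each other, then rescaled to module_factor_sd: planted
# modules are exactly uncorrelated comethylation blocks beyond their
# shared drift component, so module identity does not hinge on the luck
# of a finite-sample draw.
draw_coherence <- function(universe, config, n, drift) {
  co <- list()
  basis <- cbind(1, drift)
  for (lab in names(universe$module_type)) {
    if (universe$module_type[lab] == "physio" &&
        config$module_factor_sd > 0) {
      h <- stats::rnorm(n)
      h <- stats::lm.fit(basis, h)$residuals
      h <- h / stats::sd(h) * config$module_factor_sd
      co[[lab]] <- h
      basis <- cbind(basis, h)
    } else co[[lab]] <- NULL
  }
  co
}

#' Simulate a replicative-passaging methylation dataset
#'
#' Emulates a longitudinal passaging series: each sample carries a
#' cumulative population doubling (cPD) drawn uniformly on
#' `config$cpd_range`; physiological-module CpGs drift with cPD while
#' artifact-module CpGs follow an independent latent factor correlated
#' with cPD (correlation `config$artifact_cor`) -- mimicking culture
#' artifacts that accumulate with time in vitro and are therefore
#' confounded with replication in any single passaging dataset.
#' Background CpGs are pure noise. See [sim_config()] for the generative
#' model.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param n Number of samples (defaults to `config$n_train`).
#' @param sample_prefix Prefix for sample identifiers.
#' @param truth Optional ground truth from a previous call: reuses that
#'   CpG universe (baselines and loadings), e.g. to draw an independent
#'   validation passaging series.
#' @return A list with `beta` ([beta_matrix()]), `sheet` (sample sheet
#'   with `sample_id`, `cpd`, `passage`), and `truth` (ground truth:
#'   `modules` (CpG to module map, 0 = background), `module_type`
#'   (physio/artifact per module), per-sample `latent` drift, and the
#'   generator state needed to extend the universe to other datasets).
#' @export
simulate_passaging <- function(config, seed = config$seed,
                               n = config$n_train,
                               sample_prefix = "train", truth = NULL) {
  set.seed(seed)
  uni <- if (is.null(truth)) draw_universe(config) else truth
  cpd <- sort(stats::runif(n, config$cpd_range[1], config$cpd_range[2]))
  latent <- config$slope * cpd
  drivers <- list()
  for (lab in names(uni$module_type)) {
    drivers[[lab]] <-
      if (uni$module_type[lab] == "physio") latent
      else correlated_factor(latent, config$artifact_cor)
  }
  coherence <- draw_coherence(uni, config, n, latent)
  ids <- sprintf("%s_%02d", sample_prefix, seq_len(n))
  beta <- emit_beta(uni, drivers, coherence, n, config$noise_sd, ids)
  sheet <- data.frame(sample_id = ids, cpd = cpd,
                      passage = as.integer(round(cpd / 2.7)))
  out_truth <- structure(
    list(cpg_ids = uni$cpg_ids, modules = uni$modules,
         module_type = uni$module_type, mu = uni$mu,
         lambda = uni$lambda, gamma = uni$gamma,
         latent = stats::setNames(latent, ids), slope = config$slope),
    class = "sim_truth")
  list(beta = beta, sheet = sheet, truth = out_truth)
}

#' Simulate an aging-tissue methylation dataset sharing the CpG universe
#'
#' Emulates the in-vivo consensus partner (e.g. an aging-liver cohort):
#' physiological-module CpGs drift with chronological age using the same
#' per-CpG loadings as the passaging dataset, while artifact-module CpGs
#' carry no latent factor at all (pure noise) -- the structure the
#' two-dataset consensus exploits to segregate replication signal from
#' culture artifacts.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_passaging()] (shared CpG
#'   universe).
#' @param seed Integer seed.
#' @param n Number of samples (defaults to `config$n_tissue`).
#' @param sample_prefix Prefix for sample identifiers.
#' @return A list with `beta`, `sheet` (`sample_id`, `age`), `truth`.
#' @export
simulate_tissue <- function(config, truth, seed = config$seed + 1000L,
                            n = config$n_tissue,
                            sample_prefix = "tissue") {
  if (!inherits(truth, "sim_truth"))
    stop("`truth` must be a sim_truth from simulate_passaging()")
  set.seed(seed)
  age <- sort(stats::runif(n, config$age_range[1], config$age_range[2]))
  latent <- config$slope * age
  drivers <- list()
  for (lab in names(truth$module_type)) {
    drivers[[lab]] <-
      if (truth$module_type[lab] == "physio") latent else NULL
  }
  coherence <- draw_coherence(truth, config, n, latent)
  ids <- sprintf("%s_%03d", sample_prefix, seq_len(n))
  beta <- emit_beta(truth, drivers, coherence, n, config$noise_sd, ids)
  sheet <- data.frame(sample_id = ids, age = age)
  out_truth <- truth
  out_truth$latent <- stats::setNames(latent, ids)
  list(beta = beta, sheet = sheet, truth = out_truth)
}

#' Simulate a downstream evaluation cohort keyed to the planted drift
#'
#' Generates in-vivo cohorts whose group structure is driven by the
#' planted latent drift factor (artifact modules stay inactive, as in
#' any tissue dataset):
#' \describe{
#'   \item{`tumor_normal`}{two groups whose latent drift differs by
#'     `shift` (M-value latent units); independent age/sex/tissue
#'     covariates for residualization.}
#'   \item{`survival`}{latent drift standardized within the cohort;
#'     event hazard `base_hazard * exp(b * z(drift))`, exponential event
#'     times, independent exponential censoring.}
#'   \item{`multi_tissue`}{per-tissue mean drift proportional to a
#'     division-rate covariate (`dr_slope`), several samples per
#'     tissue.}
#' }
#'
#' @param kind One of `"tumor_normal"`, `"survival"`, `"multi_tissue"`.
#' @param truth Ground truth from [simulate_passaging()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param n Total samples (tumor_normal, survival).
#' @param shift Latent drift difference between tumor and normal.
#' @param drift_sd Within-group latent drift SD.
#' @param b Log-hazard per SD of latent drift (survival).
#' @param base_hazard Baseline exponential hazard (survival).
#' @param censor_hazard Independent censoring hazard (survival).
#' @param n_tissues,per_tissue Multi-tissue design size.
#' @param dr_slope Latent drift per unit division rate.
#' @return A list with `beta`, `sheet`, and `latent` (the per-sample
#'   planted drift, for validation only).
#' @export
simulate_cohort <- function(kind = c("tumor_normal", "survival",
                                     "multi_tissue"),
                            truth, config, seed = config$seed + 2000L,
                            n = 60, shift = 0.5, drift_sd = 0.25,
                            b = log(2), base_hazard = 0.1,
                            censor_hazard = 0.05,
                            n_tissues = 8, per_tissue = 10,
                            dr_slope = 1) {
  kind <- match.arg(kind)
  if (!inherits(truth, "sim_truth"))
    stop("`truth` must be a sim_truth from simulate_passaging()")
  set.seed(seed)
  base <- config$slope * mean(config$cpd_range)
  if (kind == "tumor_normal") {
    group <- rep(c("normal", "tumor"), length.out = n)
    latent <- base + stats::rnorm(n, 0, drift_sd) +
      ifelse(group == "tumor", shift, 0)
    sheet <- data.frame(
      sample_id = sprintf("tn_%03d", seq_len(n)),
      group = group,
      age = stats::runif(n, 30, 80),
      sex = sample(c("F", "M"), n, replace = TRUE),
      tissue = sample(c("breast", "colon", "lung"), n, replace = TRUE))
  } else if (kind == "survival") {
    latent <- base + stats::rnorm(n, 0, drift_sd)
    z <- (latent - mean(latent)) / stats::sd(latent)
    haz <- base_hazard * exp(b * z)
    t_event <- stats::rexp(n, haz)
    t_cens <- stats::rexp(n, censor_hazard)
    sheet <- data.frame(
      sample_id = sprintf("sv_%03d", seq_len(n)),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      age = stats::runif(n, 40, 80),
      sex = sample(c("F", "M"), n, replace = TRUE))
  } else {
    n <- n_tissues * per_tissue
    division_rate <- stats::runif(n_tissues, 0.1, 1)
    tissue <- rep(sprintf("tissue%02d", seq_len(n_tissues)),
                  each = per_tissue)
    latent <- base + dr_slope * rep(division_rate, each = per_tissue) +
      stats::rnorm(n, 0, drift_sd / 2)
    sheet <- data.frame(
      sample_id = sprintf("mt_%03d", seq_len(n)),
      tissue = tissue,
      division_rate = rep(division_rate, each = per_tissue),
      age = stats::runif(n, 30, 80))
  }
  drivers <- list()
  for (lab in names(truth$module_type)) {
    drivers[[lab]] <-
      if (truth$module_type[lab] == "physio") latent else NULL
  }
  coherence <- draw_coherence(truth, config, length(latent), latent)
  beta <- emit_beta(truth, drivers, coherence, length(latent),
                    config$noise_sd, sheet$sample_id)
  list(beta = beta, sheet = sheet,
       latent = stats::setNames(latent, sheet$sample_id))
}
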