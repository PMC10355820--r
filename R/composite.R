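# Order a sample sheet to match a beta matrix's columns.
align_sheet <- function(sheet, m) {
  idx <- match(colnames(m), sheet$sample_id)
  if (anyNA(idx)) stop("sample sheet is missing samples present in the ",
                       "beta matrix")
  sheet[idx, , drop = FALSE]
}

#' Train one PC clock per module
#'
#' For every assigned module in a partition, runs [fit_pca()] on that
#' module's CpGs only and trains a [fit_pc_clock()] against the target
#' covariate (cumulative population doublings by default). Modules with
#' fewer than 2 CpGs in the training matrix are skipped with a warning.
#'
#' @param train A [beta_matrix()] of training samples.
#' @param sheet Sample sheet containing `sample_id` and the target
#'   column.
#' @param part A `module_partition`.
#' @param target_name Target column name (default `"cpd"`).
#' @param alpha,folds,seed Passed to [fit_pc_clock()].
#' @return A named list of `pc_clock` objects (names are module labels),
#'   class `module_clock_set`.
#' @export
fit_module_clocks <- function(train, sheet, part, target_name = "cpd",
                              alpha = 0.5, folds = 10, seed = 1L) {
  sheet <- align_sheet(sheet, train)
  target <- sheet[[target_name]]
  if (is.null(target) || anyNA(target))
    stop("training sheet lacks a complete `", target_name, "` column")
  labs <- sort(unique(part$labels[part$labels > 0]))
  clocks <- list()
  for (lab in labs) {
    members <- intersect(names(part$labels)[part$labels == lab],
                         rownames(train))
    if (length(members) < 2) {
      warning("module ", lab, " has fewer than 2 CpGs; skipped")
      next
    }
    pcm <- fit_pca(beta_matrix(train[members, , drop = FALSE]))
    clocks[[as.character(lab)]] <-
      fit_pc_clock(pcm, target, target_name = target_name, alpha = alpha,
                   folds = folds, seed = seed)
  }
  structure(clocks, class = "module_clock_set")
}

#' Select physiologically relevant modules
#'
#' A module clock trained on replicative passaging is physiologically
#' relevant when its score tracks replication in an independent in-vitro
#' dataset *and* chronological age in an in-vivo tissue dataset. A
#' module is selected iff its Pearson correlation with cPD on the
#' in-vitro evaluation set and with age on the in-vivo set both reach
#' `r_min`.
#'
#' @param clocks A `module_clock_set`.
#' @param invitro_eval List with `beta` and `sheet` (sheet needs `cpd`);
#'   must be disjoint from training.
#' @param invivo_eval List with `beta` and `sheet` (sheet needs `age`).
#' @param r_min Minimum Pearson correlation on both axes (default 0.5).
#' @return List with `selected` (character module labels) and
#'   `correlations` (per-module data.frame with `r_invitro`,
#'   `r_invivo`). No module passing is an error that reports the table.
#' @export
select_modules <- function(clocks, invitro_eval, invivo_eval,
                           r_min = 0.5) {
  vitro_sheet <- align_sheet(invitro_eval$sheet, invitro_eval$beta)
  vivo_sheet <- align_sheet(invivo_eval$sheet, invivo_eval$beta)
  tab <- data.frame(module = names(clocks),
                    r_invitro = NA_real_, r_invivo = NA_real_)
  for (i in seq_along(clocks)) {
    s_vitro <- predict_score(clocks[[i]], invitro_eval$beta)
    s_vivo <- predict_score(clocks[[i]], invivo_eval$beta)
    tab$r_invitro[i] <- stats::cor(s_vitro, vitro_sheet$cpd)
    tab$r_invivo[i] <- stats::cor(s_vivo, vivo_sheet$age)
  }
  sel <- tab$module[tab$r_invitro >= r_min & tab$r_invivo >= r_min]
  if (length(sel) == 0) {
    stop("no module passes r_min = ", r_min, ":\n",
         paste(utils::capture.output(print(tab)), collapse = "\n"))
  }
  list(selected = sel, correlations = tab)
}

#' Fit the pooled-PC composite drift score
#'
#' Rather than recomputing a single PCA on the union of selected-module
#' CpGs, each selected module keeps its own PC decomposition (all
#' `min(n, p)` components); the component scores are concatenated across
#' modules and one elastic net is fit on the pooled scores against the
#' target, so each module's signal enters with equal weight regardless
#' of its CpG count. A provenance map records which pooled coefficient
#' belongs to which module and component.
#'
#' @param train A [beta_matrix()] of training samples.
#' @param sheet Sample sheet with `sample_id` and the target column.
#' @param part A `module_partition`.
#' @param selected Module labels to pool (character or integer).
#' @param target_name Target column (default `"cpd"`).
#' @param alpha,folds,seed,lambda Passed to the pooled elastic net.
#' @return A `composite_model`: per-module `pc_models`, pooled
#'   elastic-net `coefficients`/`intercept`, `provenance`, CV metadata.
#' @export
fit_composite <- function(train, sheet, part, selected,
                          target_name = "cpd", alpha = 0.5, folds = 10,
                          seed = 1L, lambda = NULL) {
  if (length(selected) < 1) stop("at least one module must be selected")
  selected <- as.character(selected)
  sheet <- align_sheet(sheet, train)
  target <- sheet[[target_name]]
  if (is.null(target) || anyNA(target))
    stop("training sheet lacks a complete `", target_name, "` column")
  member_sets <- lapply(selected, function(lab)
    intersect(names(part$labels)[part$labels == as.integer(lab)],
              rownames(train)))
  names(member_sets) <- selected
  all_members <- unlist(member_sets)
  if (anyDuplicated(all_members))
    stop("selected modules share CpGs; the partition must be disjoint")
  pc_models <- list()
  score_blocks <- list()
  prov <- list()
  for (lab in selected) {
    if (length(member_sets[[lab]]) < 2)
      stop("module ", lab, " has fewer than 2 CpGs")
    pcm <- fit_pca(beta_matrix(train[member_sets[[lab]], , drop = FALSE]))
    pc_models[[lab]] <- pcm
    score_blocks[[lab]] <- pcm$scores
    prov[[lab]] <- data.frame(module = lab,
                              component = seq_len(ncol(pcm$scores)))
  }
  pooled <- do.call(cbind, score_blocks)
  provenance <- do.call(rbind, prov)
  rownames(provenance) <- NULL
  colnames(pooled) <- paste0(provenance$module, ".PC",
                             provenance$component)
  en <- fit_enet(pooled, target, alpha, folds, seed, lambda)
  structure(c(list(module_ids = selected,
                   pc_models = lapply(pc_models, function(p) {
                     p$scores <- NULL; p
                   }),
                   target_name = target_name, provenance = provenance),
              en),
            class = "composite_model")
}

#' @export
print.composite_model <- function(x, ...) {
  cat(sprintf(
    "composite_model (%s): %d modules, %d pooled components, %d active\n",
    x$target_name, length(x$module_ids), length(x$coefficients),
    sum(x$coefficients != 0)))
  invisible(x)
}

#' Score samples with a composite drift model
#'
#' Projects each selected module's CpGs onto that module's PC basis,
#' concatenates the component scores in provenance order, and applies
#' the pooled elastic-net coefficients. Deterministic and invariant to
#' CpG and sample order; CpGs outside the selected modules are ignored.
#'
#' @param model A `composite_model`.
#' @param m A [beta_matrix()] containing all selected modules' CpGs.
#' @return Named numeric vector of per-sample composite scores.
#' @export
score_composite <- function(model, m) {
  blocks <- lapply(model$module_ids, function(lab) {
    tryCatch(project_scores(model$pc_models[[lab]], m),
             error = function(e)
               stop("module ", lab, ": ", conditionMessage(e),
                    call. = FALSE))
  })
  pooled <- do.call(cbind, blocks)
  drop(model$intercept + pooled %*% model$coefficients)
}
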