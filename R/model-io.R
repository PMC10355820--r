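MODEL_SCHEMA_VERSION <- 1L

# Matrices are stored flat (column-major) with explicit dims and dimnames
# so the JSON round trip is exact and independent of jsonlite's matrix
# simplification heuristics.
pack_matrix <- function(m) {
  list(dim = dim(m), rownames = rownames(m), colnames = colnames(m),
       data = as.vector(m))
}

unpack_matrix <- function(p) {
  m <- matrix(p$data, nrow = p$dim[1], ncol = p$dim[2])
  rownames(m) <- p$rownames
  colnames(m) <- p$colnames
  m
}

#' Serialize a trained model to JSON
#'
#' Writes a self-describing JSON archive (schema-versioned, kind-tagged)
#' holding every numeric array needed to re-score: CpG list, centering
#' vector, component loadings, selected coefficients, and intercept.
#' Doubles are written at full precision so that
#' `load_model(save_model(m))` predicts bit-identically to `m`.
#'
#' @param model A `pc_clock` or `composite_model` object.
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @seealso [load_model()]
#' @export
save_model <- function(model, path) {
  kind <- if (inherits(model, "pc_clock")) "pc_clock"
          else if (inherits(model, "composite_model")) "composite_model"
          else stop("unsupported model class: ",
                    paste(class(model), collapse = "/"))
  payload <- list(schema_version = MODEL_SCHEMA_VERSION, kind = kind,
                  model = pack_model(model))
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

pack_model <- function(model) UseMethod("pack_model")

pack_model.pc_clock <- function(model) {
  list(cpg_ids = model$cpg_ids, center = model$center,
       loadings = pack_matrix(model$loadings),
       component_variances = model$component_variances,
       alpha = model$alpha, lambda = model$lambda,
       coefficients = model$coefficients, intercept = model$intercept,
       target_name = model$target_name, cv_folds = model$cv_folds,
       cv_seed = model$cv_seed,
       cv_curve = if (is.null(model$cv_curve)) NULL else
         list(lambda = model$cv_curve$lambda, mse = model$cv_curve$mse))
}

pack_model.composite_model <- function(model) {
  list(module_ids = model$module_ids,
       pc_models = lapply(model$pc_models, function(pm)
         list(cpg_ids = pm$cpg_ids, center = pm$center,
              loadings = pack_matrix(pm$loadings),
              component_variances = pm$component_variances)),
       alpha = model$alpha, lambda = model$lambda,
       coefficients = model$coefficients, intercept = model$intercept,
       target_name = model$target_name,
       provenance = list(module = model$provenance$module,
                         component = model$provenance$component),
       cv_folds = model$cv_folds, cv_seed = model$cv_seed,
       cv_curve = if (is.null(model$cv_curve)) NULL else
         list(lambda = model$cv_curve$lambda, mse = model$cv_curve$mse))
}

#' Load a serialized model
#'
#' @param path Path written by [save_model()].
#' @return The restored `pc_clock` or `composite_model`; an archive with
#'   an unknown schema version is an explicit error, never a silent
#'   fallback.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyMatrix = FALSE)
  if (is.null(payload$schema_version) ||
      payload$schema_version != MODEL_SCHEMA_VERSION)
    stop("model archive schema version ",
         payload$schema_version %||% "<missing>",
         " not supported (expected ", MODEL_SCHEMA_VERSION, ")")
  m <- payload$model
  if (payload$kind == "pc_clock") {
    structure(list(
      cpg_ids = m$cpg_ids, center = m$center,
      loadings = unpack_matrix(m$loadings),
      component_variances = m$component_variances,
      alpha = m$alpha, lambda = m$lambda,
      coefficients = m$coefficients, intercept = m$intercept,
      target_name = m$target_name, cv_folds = m$cv_folds,
      cv_seed = m$cv_seed,
      cv_curve = if (is.null(m$cv_curve)) NULL else
        data.frame(lambda = m$cv_curve$lambda, mse = m$cv_curve$mse)),
      class = "pc_clock")
  } else if (payload$kind == "composite_model") {
    pms <- lapply(m$pc_models, function(pm)
      structure(list(cpg_ids = pm$cpg_ids, center = pm$center,
                     loadings = unpack_matrix(pm$loadings),
                     component_variances = pm$component_variances),
                class = "pc_model"))
    structure(list(
      module_ids = m$module_ids, pc_models = pms,
      alpha = m$alpha, lambda = m$lambda,
      coefficients = m$coefficients, intercept = m$intercept,
      target_name = m$target_name,
      provenance = data.frame(module = m$provenance$module,
                              component = m$provenance$component),
      cv_folds = m$cv_folds, cv_seed = m$cv_seed,
      cv_curve = if (is.null(m$cv_curve)) NULL else
        data.frame(lambda = m$cv_curve$lambda, mse = m$cv_curve$mse)),
      class = "composite_model")
  } else stop("unknown model kind: ", payload$kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
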