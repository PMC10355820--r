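#' Construct a validated beta-value matrix
#'
#' A beta matrix stores methylation fractions (beta values) with CpGs in
#' rows and samples in columns. Values must be finite and lie in
#' \eqn{[0, 1]}; CpG and sample identifiers must be unique. Objects of
#' class `beta_matrix` are ordinary numeric matrices carrying these
#' guarantees.
#'
#' @param values Numeric matrix, CpGs x samples, with rownames (CpG ids)
#'   and colnames (sample ids).
#' @param tol Tolerance for the \eqn{[0, 1]} bound check. Values within
#'   `tol` of the bounds are clamped; values beyond it are an error.
#' @return A `beta_matrix` (numeric matrix with class attribute).
#' @export
beta_matrix <- function(values, tol = 1e-9) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("beta matrix requires CpG rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate CpG identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("beta matrix contains missing or non-finite values; ",
         "imputation is not performed")
  lo <- min(values); hi <- max(values)
  if (lo < -tol || hi > 1 + tol) {
    bad <- which(values < -tol | values > 1 + tol, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "beta value %.6g at CpG '%s', sample '%s' outside [0, 1]",
      values[bad[1], bad[2]], rownames(values)[bad[1]],
      colnames(values)[bad[2]]))
  }
  values[values < 0] <- 0
  values[values > 1] <- 1
  structure(values, class = c("beta_matrix", class(matrix())))
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d CpGs x %d samples\n", nrow(x), ncol(x)))
  cat(sprintf("  beta range: [%.4f, %.4f]\n", min(x), max(x)))
  invisible(x)
}

#' Read a beta matrix from delimited text
#'
#' Reads a TSV (`.tsv`, `.txt`) or CSV (`.csv`) file with one header row
#' and one leading identifier column. The on-disk convention is rows =
#' CpGs, columns = samples; a transposed file can be read with
#' `orientation = "samples"`.
#'
#' @param path File path. The delimiter is chosen from the extension
#'   (`.csv` is comma-separated, anything else tab-separated).
#' @param orientation `"cpgs"` if rows are CpGs (default), `"samples"`
#'   if rows are samples; the result is always CpGs x samples.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, orientation = c("cpgs", "samples")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, colClasses = NULL)
  if (ncol(dt) < 2) stop("expected an identifier column plus data columns")
  ids <- as.character(dt[[1]])
  num <- dt[, -1, drop = FALSE]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric values in column(s): ",
         paste(names(num)[bad], collapse = ", "))
  m <- as.matrix(num)
  rownames(m) <- ids
  if (orientation == "samples") m <- t(m)
  beta_matrix(m)
}

#' Write a beta matrix to delimited text
#'
#' Inverse of [read_beta_matrix()]: rows are CpGs, the first column holds
#' CpG identifiers, and values are written at full double precision so a
#' write/read round trip is lossless.
#'
#' @param m A [beta_matrix()] or compatible matrix.
#' @param path Output path; `.csv` writes comma-separated, otherwise tabs.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(m, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  dt <- data.table::data.table(cpg_id = rownames(m))
  for (j in colnames(m)) dt[[j]] <- m[, j]
  data.table::fwrite(dt, path, sep = sep)
  invisible(path)
}

#' Read a sample sheet
#'
#' A sample sheet is a CSV with one row per sample and at least a
#' `sample_id` column. Recognized optional columns: `cpd` (cumulative
#' population doublings), `passage`, `age` (years), `tissue`, `sex`,
#' `bmi`, `group`, `time` (survival time), `event` (0/1).
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- data.table::fread(path, data.table = FALSE)
  validate_sample_sheet(sheet)
}

#' Validate a sample sheet
#'
#' @param sheet data.frame with a `sample_id` column.
#' @param beta Optional [beta_matrix()]; if given, the sample sets must
#'   match exactly.
#' @return `sheet`, invisibly checked, with `sample_id` as character.
#' @export
validate_sample_sheet <- function(sheet, beta = NULL) {
  if (!"sample_id" %in% names(sheet)) stop("sample sheet lacks `sample_id`")
  sheet$sample_id <- as.character(sheet$sample_id)
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id in sheet")
  if ("time" %in% names(sheet) && !"event" %in% names(sheet))
    stop("`event` must accompany `time`")
  if ("event" %in% names(sheet)) {
    ev <- stats::na.omit(sheet$event)
    if (!all(ev %in% c(0, 1))) stop("`event` must be 0/1")
  }
  if (!is.null(beta) && !setequal(sheet$sample_id, colnames(beta)))
    stop("sample sheet and beta matrix sample sets differ")
  sheet
}

#' Drop sex-chromosome CpGs
#'
#' Removes CpGs annotated to chromosome X or Y. CpGs absent from the
#' annotation are retained (with a message), so an incomplete map never
#' silently discards probes.
#'
#' @param m A [beta_matrix()].
#' @param annotation Named character vector mapping CpG id to chromosome
#'   (labels like `"chrX"`, `"X"`, `"chrY"`, `"Y"` are treated as sex
#'   chromosomes), or a data.frame with columns `cpg_id` and `chr`.
#' @return A [beta_matrix()] restricted to autosomal (or unannotated)
#'   CpGs.
#' @export
exclude_sex_chromosome_cpgs <- function(m, annotation) {
  if (is.data.frame(annotation)) {
    ann <- stats::setNames(as.character(annotation$chr),
                           as.character(annotation$cpg_id))
  } else ann <- annotation
  chr <- ann[rownames(m)]
  n_unann <- sum(is.na(chr))
  if (n_unann > 0)
    message(n_unann, " CpG(s) without chromosome annotation retained")
  sexchr <- c("X", "Y", "chrX", "chrY")
  keep <- is.na(chr) | !(chr %in% sexchr)
  if (!any(keep)) stop("no autosomal CpGs remain")
  beta_matrix(m[keep, , drop = FALSE])
}

#' Align a beta matrix to a reference CpG list
#'
#' Restricts and reorders rows to the intersection with a reference CpG
#' list (e.g. the 450k array content), in reference order. Used to
#' harmonize datasets before consensus network analysis. Idempotent.
#'
#' @param m A [beta_matrix()].
#' @param reference_cpgs Ordered character vector of CpG ids.
#' @return A [beta_matrix()] whose rows are
#'   `reference_cpgs` intersected with `rownames(m)`, in reference order.
#' @export
align_to_reference <- function(m, reference_cpgs) {
  keep <- reference_cpgs[reference_cpgs %in% rownames(m)]
  if (length(keep) == 0) stop("no CpGs shared with the reference")
  beta_matrix(m[keep, , drop = FALSE])
}

#' Population doublings between two cell densities
#'
#' Solves `2^x = final_density / initial_density` for the number of
#' population doublings `x`. Cumulative population doublings (cPD) across
#' a passaging series are the running sum of per-passage doublings; see
#' [cumulative_cpd()].
#'
#' @param initial_density,final_density Strictly positive cell densities
#'   (cells per area); vectorized.
#' @return Population doublings, `log2(final_density / initial_density)`.
#' @export
compute_cpd <- function(initial_density, final_density) {
  if (any(initial_density <= 0) || any(final_density <= 0))
    stop("cell densities must be strictly positive")
  log2(final_density / initial_density)
}

#' Cumulative population doublings across passages
#'
#' @param initial_density,final_density Per-passage densities, in passage
#'   order.
#' @return Running sum of per-passage doublings.
#' @export
cumulative_cpd <- function(initial_density, final_density) {
  cumsum(compute_cpd(initial_density, final_density))
}
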