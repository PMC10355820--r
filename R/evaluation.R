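test_result <- function(statistic, value, p, n, ...) {
  structure(list(statistic = statistic, value = value, p = p, n = n, ...),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s = %.4g, p = %.3g (n = %d)\n", x$statistic, x$value,
              x$p, x$n))
  extra <- setdiff(names(x), c("statistic", "value", "p", "n"))
  for (e in extra)
    if (is.numeric(x[[e]]))
      cat(sprintf("  %s: %s\n", e,
                  paste(signif(x[[e]], 4), collapse = ", ")))
  invisible(x)
}

# Match a (possibly named) score vector against a sample sheet.
align_scores <- function(scores, sheet) {
  if (!is.null(names(scores))) {
    idx <- match(sheet$sample_id, names(scores))
    if (anyNA(idx)) stop("scores are missing for some sheet samples")
    scores <- scores[idx]
  } else if (length(scores) != nrow(sheet)) {
    stop("unnamed scores must match the sheet row count")
  }
  unname(scores)
}

#' Residualize scores on covariates
#'
#' Ordinary least squares of the score on an intercept plus the named
#' covariates (categoricals expanded to one-hot contrasts dropping one
#' level); residuals are returned for downstream group comparisons, so
#' group differences are assessed net of e.g. age, sex, and tissue.
#'
#' @param scores Per-sample numeric scores, named by sample id or in
#'   sheet order.
#' @param sheet Sample sheet containing the covariate columns.
#' @param covariates Character vector of covariate names; may be empty
#'   (intercept-only: residual = score - mean).
#' @return A `score_table` data.frame with `sample_id`, `score`,
#'   `residual`; covariates used are recorded as an attribute.
#' @export
residualize <- function(scores, sheet, covariates = character()) {
  scores <- align_scores(scores, sheet)
  if (length(covariates) == 0) {
    res <- scores - mean(scores)
  } else {
    missing <- setdiff(covariates, names(sheet))
    if (length(missing) > 0)
      stop("sheet lacks covariate(s): ", paste(missing, collapse = ", "))
    df <- sheet[covariates]
    for (j in names(df)) {
      if (anyNA(df[[j]])) stop("covariate `", j, "` has missing values")
      if (is.character(df[[j]]) || is.logical(df[[j]]))
        df[[j]] <- factor(df[[j]])
      if (is.factor(df[[j]]) && nlevels(droplevels(df[[j]])) < 2)
        stop("categorical covariate `", j, "` has fewer than 2 levels")
    }
    x <- stats::model.matrix(~ ., data = df)
    qx <- qr(x)
    if (qx$rank < ncol(x)) {
      drop_cols <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
      stop("rank-deficient design; collinear column(s): ",
           paste(drop_cols, collapse = ", "))
    }
    res <- stats::lm.fit(x, scores)$residuals
  }
  out <- data.frame(sample_id = sheet$sample_id, score = scores,
                    residual = unname(res))
  attr(out, "covariates") <- covariates
  class(out) <- c("score_table", "data.frame")
  out
}

#' Kruskal-Wallis group comparison
#'
#' Rank-based test for location differences across two or more groups,
#' with the standard tie correction and a chi-square p-value on
#' `k - 1` degrees of freedom. Invariant to strictly monotone transforms
#' of the scores.
#'
#' @param x Numeric scores or a `score_table` (its `residual` column is
#'   used).
#' @param groups Group labels, one per sample; every group needs at
#'   least 2 samples.
#' @return A `test_result` with the H statistic, p-value, `df`, and `n`.
#' @export
group_test <- function(x, groups) {
  if (inherits(x, "score_table")) x <- x$residual
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 samples")
  kt <- stats::kruskal.test(x, g)
  test_result("Kruskal-Wallis H", unname(kt$statistic),
              unname(kt$p.value), length(x),
              df = unname(kt$parameter))
}

#' Pearson correlation with t-based test
#'
#' @param x,y Per-sample numeric vectors (n >= 3, finite, non-constant).
#' @return A `test_result` with `r` as value, two-sided p, and `n`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in input")
  ct <- stats::cor.test(x, y, method = "pearson")
  test_result("Pearson r", unname(ct$estimate), unname(ct$p.value),
              length(x), conf_int = unname(ct$conf.int))
}

#' Per-SD Cox proportional-hazards fit
#'
#' Partial-likelihood fit (Efron ties) of survival on the score, entered
#' after z-scoring by the sample SD so the hazard ratio is per SD of
#' score; any adjuster named `age` is entered as `age / 10` so its
#' hazard ratio reads as risk per 10 years of life.
#'
#' @param scores Per-sample scores (named or in sheet order).
#' @param sheet Sample sheet with `time` (> 0) and `event` (0/1, at
#'   least one event), plus any adjuster columns.
#' @param adjusters Covariate names entered alongside the score.
#' @return A `test_result` with the per-SD hazard ratio as value, Wald
#'   p, `log_hr`, `se`, 95% `conf_int`, and per-adjuster hazard ratios.
#' @export
cox_hazard <- function(scores, sheet, adjusters = character()) {
  scores <- align_scores(scores, sheet)
  if (!all(c("time", "event") %in% names(sheet)))
    stop("sheet must contain `time` and `event`")
  if (any(sheet$time <= 0)) stop("survival times must be positive")
  if (!all(sheet$event %in% c(0, 1))) stop("`event` must be 0/1")
  if (sum(sheet$event) < 1) stop("no events in the data")
  df <- data.frame(time = sheet$time, event = sheet$event,
                   score_sd = as.numeric(scale(scores)))
  for (a in adjusters) {
    if (!a %in% names(sheet)) stop("sheet lacks adjuster `", a, "`")
    v <- sheet[[a]]
    if (is.character(v) || is.logical(v)) v <- factor(v)
    df[[a]] <- if (a == "age") v / 10 else v
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ .,
                         data = df, ties = "efron")
  if (any(!is.finite(stats::coef(fit))))
    stop("Cox fit did not converge; iterations: ", fit$iter)
  sm <- summary(fit)
  co <- sm$coefficients["score_sd", ]
  ci <- sm$conf.int["score_sd", c("lower .95", "upper .95")]
  adj_hr <- if (length(adjusters) > 0)
    exp(stats::coef(fit)[setdiff(names(stats::coef(fit)), "score_sd")])
    else NULL
  test_result("Cox HR per SD", unname(co["exp(coef)"]),
              unname(co["Pr(>|z|)"]), nrow(df),
              log_hr = unname(co["coef"]), se = unname(co["se(coef)"]),
              conf_int = unname(ci), adjuster_hr = adj_hr)
}

#' Run a downstream evaluation design
#'
#' Dispatches the study's standard score evaluations:
#' \describe{
#'   \item{`tumor_normal`}{residualize by `config$covariates` (default:
#'     whichever of age/sex/tissue the sheet carries), then
#'     Kruskal-Wallis on `group`.}
#'   \item{`survival`}{[cox_hazard()] with `config$adjusters` (default
#'     `"age"` when present).}
#'   \item{`multi_tissue`}{Pearson correlation of per-tissue mean score
#'     with the per-tissue `division_rate` covariate.}
#'   \item{`trajectory`}{per-phase Pearson correlation of score vs the
#'     `time_index` column; phase boundaries come from an explicit
#'     `phase` column, never inferred. A degenerate phase (zero
#'     variance) is reported as an error message while other phases are
#'     still computed.}
#' }
#'
#' @param kind Design name.
#' @param scores Per-sample scores.
#' @param sheet Sample sheet with the columns the design needs.
#' @param config Optional list: `covariates`, `adjusters`.
#' @return A list with `design` and `results` (one or more
#'   `test_result`s, or per-phase entries for `trajectory`).
#' @export
run_design <- function(kind = c("tumor_normal", "survival",
                                "multi_tissue", "trajectory"),
                       scores, sheet, config = list()) {
  kind <- match.arg(kind)
  need <- switch(kind,
                 tumor_normal = "group",
                 survival = c("time", "event"),
                 multi_tissue = c("tissue", "division_rate"),
                 trajectory = c("phase", "time_index"))
  missing <- setdiff(need, names(sheet))
  if (length(missing) > 0)
    stop("sheet lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (kind == "tumor_normal") {
    covs <- config$covariates %||%
      intersect(c("age", "sex", "tissue"), names(sheet))
    st <- residualize(scores, sheet, covs)
    res <- group_test(st, sheet$group)
    list(design = kind, covariates = covs, results = res)
  } else if (kind == "survival") {
    adj <- config$adjusters %||% intersect("age", names(sheet))
    res <- cox_hazard(scores, sheet, adj)
    list(design = kind, adjusters = adj, results = res)
  } else if (kind == "multi_tissue") {
    scores <- align_scores(scores, sheet)
    agg <- tapply(scores, sheet$tissue, mean)
    dr <- tapply(sheet$division_rate, sheet$tissue, unique)
    if (is.list(dr)) stop("division_rate must be constant within tissue")
    res <- correlate(as.numeric(agg), as.numeric(dr))
    list(design = kind, results = res)
  } else {
    scores <- align_scores(scores, sheet)
    phases <- unique(sheet$phase)
    res <- lapply(phases, function(ph) {
      i <- sheet$phase == ph
      tryCatch(correlate(scores[i], sheet$time_index[i]),
               error = function(e) conditionMessage(e))
    })
    names(res) <- phases
    list(design = kind, results = res)
  }
}
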