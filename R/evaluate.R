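#' Coefficient-of-determination score
#'
#' `1 - SS_res / SS_tot` with the total sum of squares taken about the mean
#' of the observed values. Ranges over (-Inf, 1]; 1 is a perfect match and
#' the mean predictor scores 0. Constant truth is not evaluable and returns
#' `NA` with a warning.
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 2).
#' @return Scalar score, or `NA` for constant `y_true`.
#' @export
r2_score <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  ok <- !is.na(y_true) & !is.na(y_pred)
  y_true <- y_true[ok]; y_pred <- y_pred[ok]
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    warning("constant y_true: score not evaluable")
    return(NA_real_)
  }
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Mean absolute percentage error
#'
#' Mean over entries of `|y_true - y_pred| / |y_true|`; 0 is a perfect
#' match. Entries with `y_true == 0` are excluded (a warning reports how
#' many); if all entries are zero the metric is not evaluable.
#'
#' @param y_true,y_pred numeric vectors of equal length (original abundance
#'   scale).
#' @return Nonnegative scalar, or `NA` when not evaluable.
#' @export
mape <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  ok <- !is.na(y_true) & !is.na(y_pred)
  y_true <- y_true[ok]; y_pred <- y_pred[ok]
  zero <- y_true == 0
  if (any(zero)) warning(sprintf("excluding %d zero-truth entries from MAPE", sum(zero)))
  if (all(zero)) return(NA_real_)
  mean(abs(y_true[!zero] - y_pred[!zero]) / abs(y_true[!zero]))
}

#' Threshold summary of per-metabolite metrics
#'
#' Counts and percentages of evaluable metabolites with R-squared above each
#' cut-off and MAPE below each cut-off, the standard way of summarizing
#' imputation performance over a metabolite panel. Not-evaluable metabolites
#' (`NA`) are excluded from the denominators and counted separately.
#'
#' @param r2 per-metabolite R-squared values (may contain `NA`).
#' @param mape_values per-metabolite MAPE values (may contain `NA`).
#' @param r2_thresholds defaults `c(0.01, 0.05, 0.1, 0.15, 0.2)`.
#' @param mape_thresholds defaults `c(0.1, 0.15, 0.2, 0.3)`.
#' @return list of class `evaluation_report` with data.frames `r2_summary`
#'   (`threshold`, `count`, `percent`) and `mape_summary`, plus
#'   `n_evaluated` and `n_not_evaluable` per metric.
#' @export
threshold_summary <- function(r2, mape_values = numeric(),
                              r2_thresholds = c(0.01, 0.05, 0.1, 0.15, 0.2),
                              mape_thresholds = c(0.1, 0.15, 0.2, 0.3)) {
  if (!length(r2) && !length(mape_values)) stop_config("no metrics supplied")
  r2_eval <- r2[!is.na(r2)]
  mp_eval <- mape_values[!is.na(mape_values)]
  mk <- function(vals, thr, greater) {
    cnt <- vapply(thr, function(t) {
      if (greater) sum(vals > t) else sum(vals < t)
    }, numeric(1))
    data.frame(threshold = thr, count = cnt,
               percent = if (length(vals)) 100 * cnt / length(vals) else NA_real_)
  }
  structure(list(
    r2_summary = mk(r2_eval, r2_thresholds, greater = TRUE),
    mape_summary = mk(mp_eval, mape_thresholds, greater = FALSE),
    n_evaluated = c(r2 = length(r2_eval), mape = length(mp_eval)),
    n_not_evaluable = c(r2 = sum(is.na(r2)), mape = sum(is.na(mape_values)))
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("R2 thresholds:\n")
  print(x$r2_summary, row.names = FALSE)
  cat("MAPE thresholds:\n")
  print(x$mape_summary, row.names = FALSE)
  invisible(x)
}

#' Evaluate an imputation run on its test subjects
#'
#' Computes per-metabolite R-squared and MAPE of the imputed values against
#' the observed truth on the test split, plus the threshold summary.
#'
#' @param run an [train_all()] result.
#' @param imputed matrix from [impute_all()].
#' @param truth a [metabolite_panel()] holding the observed abundances.
#' @return list with `per_metabolite` (data.frame: `metabolite_id`, `r2`,
#'   `mape`, `n_test`) and `summary` (an `evaluation_report`).
#' @export
evaluate_imputation <- function(run, imputed, truth) {
  subj <- rownames(imputed)
  res <- lapply(colnames(imputed), function(mid) {
    yt <- truth$abundance[subj, mid]
    yp <- imputed[, mid]
    ok <- !is.na(yt) & !is.na(yp)
    if (sum(ok) < 2) {
      return(data.frame(metabolite_id = mid, r2 = NA_real_, mape = NA_real_,
                        n_test = sum(ok)))
    }
    data.frame(metabolite_id = mid,
               r2 = suppressWarnings(r2_score(yt[ok], yp[ok])),
               mape = suppressWarnings(mape(yt[ok], yp[ok])),
               n_test = sum(ok))
  })
  per <- do.call(rbind, res)
  list(per_metabolite = per,
       summary = threshold_summary(per$r2, per$mape))
}

#' Within-omics single-feature baseline regressors
#'
#' Baseline imputation from the single best-correlated template metabolite:
#' a k-nearest-neighbour regressor (`kind = "knn"`, default k = 5) or ridge
#' regression (`kind = "ridge"`, default penalty 1 on the slope, intercept
#' unpenalized). `kind = "custom"` accepts any function
#' `f(y_train, x_train, x_test) -> predictions`, the plug-in point for
#' other single-feature regressors.
#'
#' @param kind `"knn"`, `"ridge"` or `"custom"`.
#' @param y_train training target values.
#' @param template_train,template_test single-feature inputs (vectors).
#' @param k neighbours for knn.
#' @param lambda ridge penalty.
#' @param fun custom regressor function.
#' @return Predictions for `template_test`.
#' @export
baseline_impute <- function(kind, y_train, template_train, template_test,
                            k = 5, lambda = 1, fun = NULL) {
  stopifnot(length(y_train) == length(template_train))
  if (kind == "knn") {
    k <- min(k, length(y_train))
    vapply(template_test, function(x0) {
      d <- abs(template_train - x0)
      mean(y_train[order(d, seq_along(d))[seq_len(k)]])
    }, numeric(1))
  } else if (kind == "ridge") {
    xc <- template_train - mean(template_train)
    slope <- sum(xc * (y_train - mean(y_train))) / (sum(xc^2) + lambda)
    mean(y_train) + slope * (template_test - mean(template_train))
  } else if (kind == "custom") {
    if (!is.function(fun)) stop_config("custom baseline requires a function")
    fun(y_train, template_train, template_test)
  } else {
    stop_config("unknown baseline kind '%s'", kind)
  }
}
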