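#' Regression accuracy metrics (R2, RMSE, RPD)
#'
#' `r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`,
#' `rmse = sqrt(mean((y - yhat)^2))`, and the residual prediction deviation
#' `rpd = sd(y) / rmse` with the sample standard deviation (n - 1
#' denominator), so `rpd * rmse` recovers `sd(y)` exactly.  An alternative
#' "explained" R2 definition (`sum((yhat - mean(y))^2) / sum((y -
#' mean(y))^2)`, equal to the residual form only for least-squares fits) is
#' available for comparison.
#'
#' @param y Measured values (length >= 3, non-constant).
#' @param yhat Predicted values, same length.
#' @param definition `"residual"` (default) or `"explained"` R2 form.
#' @return One-row tibble with `r2`, `rmse`, `rpd`.
#' @export
#' @examples
#' regression_metrics(c(0, 2, 4), c(0.5, 2, 3.5))
regression_metrics <- function(y, yhat,
                               definition = c("residual", "explained")) {
  definition <- match.arg(definition)
  if (length(y) < 3) abort("need at least 3 observations")
  if (length(y) != length(yhat)) abort("length mismatch")
  if (sd(y) == 0) abort("zero variance reference")
  ss_tot <- sum((y - mean(y))^2)
  rmse <- sqrt(mean((y - yhat)^2))
  if (rmse == 0) abort("zero RMSE: RPD undefined for perfect predictions")
  r2 <- if (definition == "residual") {
    1 - sum((y - yhat)^2) / ss_tot
  } else {
    sum((yhat - mean(y))^2) / ss_tot
  }
  tibble::tibble(r2 = r2, rmse = rmse, rpd = sd(y) / rmse)
}

#' RPD reliability category
#'
#' `"reliable"` for RPD >= 3, `"general"` for 2.4 <= RPD < 3 (adequate only
#' for coarse prediction), `"poor"` otherwise.
#'
#' @param rpd Numeric RPD values.
#' @return Character vector of categories.
#' @export
rpd_category <- function(rpd) {
  dplyr::case_when(rpd >= 3 ~ "reliable",
                   rpd >= 2.4 ~ "general",
                   TRUE ~ "poor")
}

#' Paired t-test between predicted and measured values
#'
#' Tests whether predictions are systematically biased: `d = yhat - y`,
#' `t = mean(d) / (sd(d) / sqrt(n))`, compared against the two-sided
#' critical value of the t distribution at level `alpha`.  Degrees of
#' freedom are `n - 2`, the convention under which the critical value at
#' alpha = 0.01 for a 33-sample prediction set is 2.744.
#'
#' @param y Measured values (n >= 3).
#' @param yhat Predicted values.
#' @param alpha Two-sided significance level (default 0.01).
#' @return One-row tibble with `mean_difference`, `t`, `t_critical`, `df`,
#'   `significant`.
#' @export
#' @examples
#' paired_t_test(rnorm(33), rnorm(33))
paired_t_test <- function(y, yhat, alpha = 0.01) {
  n <- length(y)
  if (n < 3) abort("need at least 3 pairs")
  if (length(yhat) != n) abort("length mismatch")
  d <- yhat - y
  sdd <- sd(d)
  t_stat <- if (sdd == 0) {
    if (mean(d) == 0) 0 else Inf * sign(mean(d))
  } else {
    mean(d) / (sdd / sqrt(n))
  }
  df <- n - 2
  t_crit <- qt(1 - alpha / 2, df)
  tibble::tibble(mean_difference = mean(d), t = t_stat, t_critical = t_crit,
                 df = df, significant = abs(t_stat) > t_crit)
}

#' Build a model-comparison report from pooled predictions
#'
#' Takes a long tibble of predictions -- columns `model`, `band_set`,
#' `split` (e.g. `"training"`, `"validation"`, `"prediction"`), `observed`,
#' `predicted` -- and produces the per-model metric table used throughout:
#' R2 and RMSE per split, `delta_r2` (training R2 minus validation R2, the
#' overfitting gap), and RPD with its reliability category on the prediction
#' split.  The raw pairs are retained for 1:1 plotting.
#'
#' @param predictions Long tibble as described above (`band_set` optional).
#' @return An `eval_report`: list with `summary` (wide metric tibble) and
#'   `one_to_one` (the input pairs).
#' @export
build_report <- function(predictions) {
  need <- c("model", "split", "observed", "predicted")
  miss <- setdiff(need, names(predictions))
  if (length(miss)) abort(paste("missing prediction column:", miss[1]))
  if (!"band_set" %in% names(predictions)) predictions$band_set <- "all"
  per <- predictions |>
    dplyr::group_by(.data$model, .data$band_set, .data$split) |>
    dplyr::group_modify(~ regression_metrics(.x$observed, .x$predicted)) |>
    dplyr::ungroup()
  wide <- per |>
    tidyr::pivot_wider(names_from = "split",
                       values_from = c("r2", "rmse", "rpd"))
  if (all(c("r2_training", "r2_validation") %in% names(wide))) {
    wide$delta_r2 <- wide$r2_training - wide$r2_validation
  }
  if ("rpd_prediction" %in% names(wide)) {
    wide$rpd_class <- rpd_category(wide$rpd_prediction)
  }
  structure(list(summary = wide, one_to_one = predictions),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$summary)
  invisible(x)
}

#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$summary

#' Write / read an evaluation report as JSON
#'
#' @param report An `eval_report`.
#' @param path JSON file path.
#' @return `write_report()` returns `report` invisibly; `read_report()`
#'   returns the reconstructed `eval_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(list(summary = report$summary,
                            one_to_one = report$one_to_one),
                       path, digits = NA, na = "null")
  invisible(report)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(summary = tibble::as_tibble(obj$summary),
                 one_to_one = tibble::as_tibble(obj$one_to_one)),
            class = "eval_report")
}
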