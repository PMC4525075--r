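#' Cross-isolate correlation of magnetotactic performance with field parameters
#'
#' Wild C. elegans isolates from magnetically distinct locations differ in
#' magnetotactic performance. These functions relate each isolate's mean
#' magnetotaxis index to a local geomagnetic predictor (inclination,
#' vertical or horizontal intensity) by unweighted ordinary least squares
#' with a Pearson correlation, and predict a held-out isolate's index with
#' a 95% t-based prediction interval. Per-isolate SEMs are carried for
#' display but do not weight the fit.
#'
#' @name correlation
NULL

predictor_column <- function(predictor) {
  switch(match.arg(predictor[1], c("inclination", "vertical", "horizontal")),
         inclination = "inclination_deg",
         vertical    = "vertical_gauss",
         horizontal  = "horizontal_gauss")
}

check_isolates <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("strain", "mi_mean", "inclination_deg", "vertical_gauss",
            "horizontal_gauss", "holdout")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("isolate table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(abs(records$mi_mean) > 1))
    stop("mi_mean must lie in [-1, 1]")
  records
}

#' Correlate isolate performance with a geomagnetic predictor
#'
#' Fits mi_mean ~ predictor by OLS over the non-holdout isolates and
#' reports the Pearson correlation.
#'
#' @param records isolate table: data frame with columns `strain`,
#'   `mi_mean`, `mi_sem` (optional), `inclination_deg`, `vertical_gauss`,
#'   `horizontal_gauss`, `holdout` (logical).
#' @param predictor `"inclination"`, `"vertical"` or `"horizontal"`.
#' @return object of class `performance_fit`: list with `r`, `slope`,
#'   `intercept`, `p` (two-sided Pearson test), `n`, `predictor`, and the
#'   underlying `lm` fit in `$fit`.
#' @export
correlate_performance <- function(records,
                                  predictor = c("inclination", "vertical",
                                                "horizontal")) {
  records <- check_isolates(records)
  col <- predictor_column(predictor)
  train <- records[!records$holdout, , drop = FALSE]
  if (nrow(train) < 3)
    stop("need >= 3 non-holdout isolates to fit")
  x <- train[[col]]
  y <- train$mi_mean
  if (stats::sd(x) == 0)
    stop("degenerate fit: predictor '", col, "' is constant")
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(
    list(r = unname(ct$estimate), slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]), p = ct$p.value,
         n = nrow(train), predictor = predictor_column(predictor),
         fit = fit),
    class = "performance_fit"
  )
}

#' @export
print.performance_fit <- function(x, ...) {
  cat(sprintf(
    "Performance fit on %s (n = %d): r = %.3f (p = %.3g), mi = %.3g + %.3g x\n",
    x$predictor, x$n, x$r, x$p, x$intercept, x$slope))
  invisible(x)
}

#' Predict the held-out isolate's magnetotaxis index
#'
#' Fits on the non-holdout isolates and predicts the single isolate flagged
#' `holdout = TRUE`, with a 95% OLS prediction interval for a new
#' observation.
#'
#' @inheritParams correlate_performance
#' @param level coverage of the prediction interval. Default 0.95.
#' @return list with `predicted_mi`, `prediction_interval` (length-2),
#'   `observed_mi` (the holdout's tabulated value, for comparison),
#'   `strain`, and the `performance_fit` used.
#' @export
predict_holdout <- function(records,
                            predictor = c("inclination", "vertical",
                                          "horizontal"),
                            level = 0.95) {
  records <- check_isolates(records)
  holdout <- records[records$holdout, , drop = FALSE]
  if (nrow(holdout) != 1)
    stop("exactly one isolate must be flagged holdout; found ", nrow(holdout))
  pf <- correlate_performance(records, predictor)
  newx <- data.frame(x = holdout[[pf$predictor]])
  pr <- stats::predict(pf$fit, newdata = newx, interval = "prediction",
                       level = level)
  list(predicted_mi = unname(pr[1, "fit"]),
       prediction_interval = unname(c(pr[1, "lwr"], pr[1, "upr"])),
       observed_mi = holdout$mi_mean,
       strain = holdout$strain,
       fit = pf)
}
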