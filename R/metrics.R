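#' Regression performance metrics
#'
#' Computes the coefficient of determination, root mean squared error and
#' residual prediction deviation for a set of measured and predicted values:
#' `RMSE = sqrt(mean((y - yhat)^2))`,
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` and
#' `RPD = SD / RMSE` with `SD` the sample standard deviation (n - 1
#' denominator) of the measured values. An RPD above 2 is conventionally read
#' as good predictive ability. Constant measured values leave R2 and RPD
#' undefined; the report is then flagged degenerate. A perfect fit gives
#' RMSE 0 and infinite RPD, also flagged.
#'
#' @param y Measured values.
#' @param yhat Predicted values, same length (n >= 2).
#' @param label Partition label carried on the report.
#' @return Object of class `metrics_report` with fields `label`, `n`, `r2`,
#'   `rmse`, `sd`, `rpd`, `mean`, `degenerate`.
#' @export
regression_metrics <- function(y, yhat, label = "set") {
  vf_check(length(y) == length(yhat) && length(y) >= 2,
           "vibrofirm_domain_error", "need equal-length y, yhat with n >= 2")
  n <- length(y)
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  rmse <- sqrt(sse / n)
  sdv <- stats::sd(y)
  degenerate <- FALSE
  if (sst == 0) {
    r2 <- NA_real_; rpd <- NA_real_; degenerate <- TRUE
  } else {
    r2 <- 1 - sse / sst
    if (rmse == 0) { rpd <- Inf; degenerate <- TRUE } else rpd <- sdv / rmse
  }
  structure(list(label = label, n = n, r2 = r2, rmse = rmse, sd = sdv,
                 rpd = rpd, mean = mean(y), degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%s (n = %d): R2 = %.4f, RMSE = %.4f N/mm, RPD = %.4f\n",
              x$label, x$n, x$r2, x$rmse, x$rpd))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(label = x$label, n = x$n, r2 = x$r2, rmse = x$rmse, sd = x$sd,
             rpd = x$rpd, mean = x$mean)
}

#' Relative change between two metric values
#'
#' `(candidate - baseline) / baseline * 100`, rounded to `digits` decimals --
#' the convention used when reporting one model's improvement over another on
#' the same partition (positive means the candidate value is higher).
#'
#' @param baseline Reference value, nonzero.
#' @param candidate Comparison value.
#' @param digits Decimals in the reported percentage.
#' @return Percent change.
#' @export
relative_change <- function(baseline, candidate, digits = 2) {
  vf_check(all(baseline != 0), "vibrofirm_domain_error",
           "baseline must be nonzero")
  round((candidate - baseline) / baseline * 100, digits)
}

#' Model comparison report
#'
#' Tabulates a candidate model's metrics against a baseline's on the same
#' partition, with relative changes on the printed scale.
#'
#' @param baseline,candidate `metrics_report` objects for the same partition.
#' @param baseline_name,candidate_name Model labels.
#' @return A data.frame with one row per metric (r2, rmse, rpd).
#' @export
comparison_report <- function(baseline, candidate,
                              baseline_name = "baseline",
                              candidate_name = "candidate") {
  metrics <- c("r2", "rmse", "rpd")
  better <- c(r2 = "higher", rmse = "lower", rpd = "higher")
  data.frame(
    metric = metrics,
    baseline_model = baseline_name,
    baseline = vapply(metrics, function(m) baseline[[m]], numeric(1)),
    candidate_model = candidate_name,
    candidate = vapply(metrics, function(m) candidate[[m]], numeric(1)),
    relative_change_pct = vapply(metrics, function(m)
      relative_change(baseline[[m]], candidate[[m]]), numeric(1)),
    direction = unname(better[metrics])
  )
}
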