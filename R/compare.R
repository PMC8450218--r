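# Relative prediction errors between two architecture summaries, and the
# mean +/- sample-sd aggregation used for model-error tables.

#' Relative change between two values
#'
#' `100 * (to - from) / from`, optionally rounded — the convention used for
#' reporting relative growth of an architectural parameter between two ages.
#'
#' @param from,to Numeric vectors (reference first).
#' @param digits Optional number of digits to round to (`NULL` = no rounding).
#' @return Relative change in percent.
#' @export
#' @examples
#' relative_change(50.8, 87.2, digits = 0)  # 72
relative_change <- function(from, to, digits = NULL) {
  out <- 100 * (to - from) / from
  if (!is.null(digits)) out <- round(out, digits)
  out
}

# default error metrics: the derived parameters not used as model input
COMPARE_METRICS <- c("aponeurosis_length_mm", "aponeurosis_width_mm",
                     "muscle_height_mm", "muscle_mass_g")

#' Compare a predicted architecture against a measured one
#'
#' Computes, per metric, the relative error `100 * (predicted - measured) /
#' measured`. The default metrics are the derived parameters that are not
#' model inputs: mean aponeurosis length and width, muscle height, and muscle
#' mass. Metrics with a measured value of 0 are skipped with a warning.
#'
#' @param predicted,measured `muscle_architecture` objects or one-row summary
#'   tibbles (as from [glance()] or [read_summary()]).
#' @param metrics Character vector of summary field names to compare.
#' @return A tibble of class `architecture_comparison` with columns `metric`,
#'   `predicted`, `measured`, `error_pct`.
#' @export
compare_architecture <- function(predicted, measured, metrics = COMPARE_METRICS) {
  as_row <- function(x) {
    if (inherits(x, "muscle_architecture")) glance(x) else tibble::as_tibble(x)
  }
  p <- as_row(predicted); m <- as_row(measured)
  missing <- setdiff(metrics, intersect(names(p), names(m)))
  if (length(missing) > 0) {
    abort(sprintf("metric(s) not present in both summaries: %s",
                  paste(missing, collapse = ", ")))
  }
  pv <- as.numeric(p[1, metrics])
  mv <- as.numeric(m[1, metrics])
  zero <- mv == 0 & !is.na(mv)
  if (any(zero)) {
    warn(sprintf("skipping metric(s) with measured value 0: %s",
                 paste(metrics[zero], collapse = ", ")))
  }
  keep <- !zero
  out <- tibble::tibble(
    metric = metrics[keep],
    predicted = pv[keep],
    measured = mv[keep],
    error_pct = 100 * (pv[keep] - mv[keep]) / mv[keep]
  )
  class(out) <- c("architecture_comparison", class(out))
  out
}

#' Aggregate relative errors as mean and sample standard deviation
#'
#' The row-aggregation convention of model-error tables: mean +/- sample sd of
#' the percent errors, across predictions and/or metrics.
#'
#' @param errors Numeric vector of percent errors, or an
#'   `architecture_comparison` (its `error_pct` column is used).
#' @param digits Optional rounding (`NULL` = none).
#' @return One-row tibble with `mean_pct`, `sd_pct`, `n`.
#' @export
#' @examples
#' summarize_errors(c(5.3, -2.1, -4.8, -4.4, -2.5), digits = 1)  # -1.7 +/- 4.1
summarize_errors <- function(errors, digits = NULL) {
  if (is.data.frame(errors)) errors <- errors$error_pct
  errors <- errors[!is.na(errors)]
  out <- tibble::tibble(
    mean_pct = mean(errors),
    sd_pct = if (length(errors) > 1) sd(errors) else NA_real_,
    n = length(errors)
  )
  if (!is.null(digits)) {
    out$mean_pct <- round(out$mean_pct, digits)
    out$sd_pct <- round(out$sd_pct, digits)
  }
  out
}
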