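# Bias / imprecision metrics at the individual and population level, the
# importance threshold, and aggregation over Monte-Carlo replicates.

#' Individual-level bias and imprecision
#'
#' Over subjects the method actually scored (non-missing `imputed`):
#' bias is the mean of `imputed - truth`, imprecision the mean of
#' `(imputed - truth)^2`.
#'
#' @param imputed Numeric vector of method scores, `NA` where unscored.
#' @param truth Numeric vector of complete-data scores (no `NA`).
#' @return A one-row tibble with `bias`, `imprecision` and `n_scored`;
#'   metrics are `NA` (flagged, not zero) when no subject is scored.
#' @examples
#' individual_metrics(c(2, 4), c(1, 5)) # diffs +1, -1: bias 0, imprecision 1
#' @export
individual_metrics <- function(imputed, truth) {
  stopifnot(length(imputed) == length(truth))
  if (anyNA(truth)) abort("`truth` must be complete")
  ok <- !is.na(imputed)
  if (!any(ok)) {
    return(tibble(bias = NA_real_, imprecision = NA_real_, n_scored = 0L))
  }
  d <- imputed[ok] - truth[ok]
  tibble(bias = mean(d), imprecision = mean(d^2), n_scored = sum(ok))
}

#' Population-level bias and imprecision
#'
#' For one simulated dataset: bias is the mean score over scored subjects
#' minus the mean complete-data score over *all* subjects; imprecision is
#' the squared bias (averaged across replicates downstream, giving the MSE
#' of the sample mean).
#'
#' @inheritParams individual_metrics
#' @return A one-row tibble with `bias`, `imprecision` (`= bias^2`) and
#'   `n_scored`; `NA` metrics when no subject is scored.
#' @export
population_metrics <- function(imputed, truth) {
  stopifnot(length(imputed) == length(truth))
  if (anyNA(truth)) abort("`truth` must be complete")
  ok <- !is.na(imputed)
  if (!any(ok)) {
    return(tibble(bias = NA_real_, imprecision = NA_real_, n_scored = 0L))
  }
  b <- mean(imputed[ok]) - mean(truth)
  tibble(bias = b, imprecision = b^2, n_scored = sum(ok))
}

#' Correlation of method scores with quality of life
#'
#' Pearson correlation over the subjects the method scored. Undefined
#' (returns `NA` with a warning suppressed at the engine level) with fewer
#' than 3 scored subjects or zero variance.
#'
#' @param scores Numeric method scores, `NA` where unscored.
#' @param qol Numeric QoL values, same length.
#' @return A single correlation, or `NA` if degenerate.
#' @export
qol_correlation <- function(scores, qol) {
  stopifnot(length(scores) == length(qol))
  ok <- !is.na(scores) & !is.na(qol)
  if (sum(ok) < 3) return(NA_real_)
  if (sd(scores[ok]) == 0 || sd(qol[ok]) == 0) return(NA_real_)
  cor(scores[ok], qol[ok])
}

#' Flag bias exceeding the minimum important difference
#'
#' A bias is flagged important when its magnitude reaches 10 % of the
#' subscale range: 2.1 points on the 0-21 scale.
#'
#' @param bias Numeric bias value(s).
#' @param mid Minimum important difference threshold.
#' @return Logical, `TRUE` where `|bias| >= mid`.
#' @examples
#' flag_important_bias(c(2.1, -2.09, -3.2)) # TRUE FALSE TRUE
#' @export
flag_important_bias <- function(bias, mid = 2.1) {
  abs(bias) >= mid
}

#' Aggregate per-replicate metrics into one cell result
#'
#' Arithmetic means of each metric over replicates, skipping replicates
#' where a metric is undefined and reporting their count.
#'
#' @param replicates A data frame with one row per replicate and numeric
#'   columns `individual_bias`, `individual_imprecision`, `population_bias`,
#'   `population_imprecision`, `n_scored`, `qol_correlation` (any subset).
#' @return A one-row tibble with the metric means, `replicates`, and
#'   `n_undefined` (replicates with any undefined metric); all-`NA` cells
#'   yield `NA` means.
#' @export
aggregate_cell <- function(replicates) {
  stopifnot(is.data.frame(replicates), nrow(replicates) > 0)
  num <- names(replicates)[vapply(replicates, is.numeric, TRUE)]
  out <- lapply(replicates[num], function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  names(out)[names(out) == "n_scored"] <- "mean_n_scored"
  tibble(
    !!!out,
    replicates = nrow(replicates),
    n_undefined = sum(!stats::complete.cases(replicates[num]))
  )
}
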