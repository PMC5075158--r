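#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_j \mathrm{var}(x_j) / \mathrm{var}(\sum_j x_j))}
#' for a complete n x k item matrix.
#'
#' @param x A numeric matrix or data frame of item responses, subjects in
#'   rows; at least 2 columns and 2 rows, no missing entries.
#' @return A single real value (at most 1).
#' @examples
#' cronbach_alpha(cbind(a = c(0, 1, 2, 3), b = c(0, 1, 2, 3)))
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) abort("alpha needs at least 2 items")
  if (nrow(x) < 2) abort("alpha needs at least 2 subjects")
  if (anyNA(x)) abort("alpha requires complete data; handle missing items first")
  vt <- var(rowSums(x))
  if (vt == 0) abort("alpha undefined: total score has zero variance")
  k <- ncol(x)
  k / (k - 1) * (1 - sum(apply(x, 2, var)) / vt)
}

band_labels <- c("0-7", "8-10", "11-14", "15-21")

subscale_band <- function(score) {
  cut(score, breaks = c(-Inf, 7, 10, 14, Inf), labels = band_labels)
}

#' Descriptive summary of a cohort
#'
#' Item means and SDs, subscale means/SDs and Cronbach's alphas, severity
#' band proportions (normal 0-7, mild 8-10, moderate 11-14, severe 15-21 for
#' each subscale) and Pearson correlations of each score with QoL.
#'
#' @param cohort A complete cohort (no missing items), e.g. from
#'   [hads_generate()].
#' @return A list of class `hads_summary` with tibbles `items`, `scales`
#'   and `bands`.
#' @export
hads_describe <- function(cohort) {
  x <- item_matrix(cohort)
  validate_items(x, allow_missing = FALSE)
  s <- score_mat(x)
  has_qol <- "qol" %in% names(cohort)
  items <- tibble(
    item = 1:14,
    subscale = ifelse(1:14 %in% .ANX, "anxiety", "depression"),
    mean = unname(colMeans(x)),
    sd = unname(apply(x, 2, sd))
  )
  scales <- tibble(
    scale = .SCALES,
    mean = unname(colMeans(s)),
    sd = unname(apply(s, 2, sd)),
    alpha = vapply(list(x[, .ANX], x[, .DEP], x), function(b) {
      tryCatch(cronbach_alpha(b), error = function(e) NA_real_)
    }, 0),
    qol_correlation = if (has_qol) {
      c(cor(s[, 1], cohort$qol), cor(s[, 2], cohort$qol), cor(s[, 3], cohort$qol))
    } else NA_real_
  )
  bands <- tidyr::expand_grid(
    scale = c("anxiety", "depression"), band = band_labels
  )
  bands$proportion <- unlist(lapply(c("anxiety", "depression"), function(sc) {
    b <- subscale_band(s[, sc])
    as.numeric(table(b) / length(b))
  }))
  structure(list(items = items, scales = scales, bands = bands),
            class = "hads_summary")
}

#' @export
print.hads_summary <- function(x, ...) {
  cat("<hads_summary>\n-- scales --\n")
  print(x$scales, ...)
  cat("-- severity bands (proportion) --\n")
  print(tidyr::pivot_wider(x$bands, names_from = "band",
                           values_from = "proportion"), ...)
  invisible(x)
}

#' Score distributions of a cohort
#'
#' Histogram of anxiety, depression and distress scores, one facet per
#' scale.
#'
#' @param object A `hads_cohort` from [hads_generate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hads_cohort
#' @export
autoplot.hads_cohort <- function(object, ...) {
  x <- item_matrix(object)
  s <- as_tibble(score_mat(x))
  long <- tidyr::pivot_longer(s, dplyr::everything(),
                              names_to = "scale", values_to = "score")
  long$scale <- factor(long$scale, levels = .SCALES)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = -0.5,
                            fill = "grey35", colour = "white") +
    ggplot2::facet_wrap(~scale, scales = "free_x") +
    ggplot2::labs(x = "score", y = "subjects") +
    ggplot2::theme_minimal()
}
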