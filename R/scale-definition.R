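# HADS structure: 14 items scored 0-3, odd items form the anxiety subscale,
# even items the depression subscale. Raw questionnaire coding reverses some
# items; all internal work uses the scored orientation (higher = worse).

.ANX <- c(1L, 3L, 5L, 7L, 9L, 11L, 13L)
.DEP <- c(2L, 4L, 6L, 8L, 10L, 12L, 14L)
# items reverse-coded on the printed form (anxiety 1,3,5,11,13; depression 6,8,10)
.REVERSED <- c(1L, 3L, 5L, 11L, 13L, 6L, 8L, 10L)

.ITEM_COLS <- paste0("hads", 1:14)
.SCALES <- c("anxiety", "depression", "distress")
.METHODS <- c(
  "subject_mean", "subscale_mean", "subscale_half_mean",
  "item_mean", "mi", "mi_half", "complete_case"
)

#' HADS item indices
#'
#' Column indices (1-14) of the items making up each HADS scale. The anxiety
#' subscale is the odd-numbered items, depression the even-numbered items,
#' and distress (the total score) uses all 14.
#'
#' @param scale One of `"anxiety"`, `"depression"` or `"distress"`.
#' @return An integer vector of item indices.
#' @examples
#' hads_items("depression")
#' @export
hads_items <- function(scale = c("anxiety", "depression", "distress")) {
  scale <- match.arg(scale)
  switch(scale, anxiety = .ANX, depression = .DEP, distress = 1:14)
}

#' The seven missing-item handling methods
#'
#' Identifiers accepted by [hads_score()] and [hads_simulate()]: subject mean,
#' subscale mean, subscale mean under the half-rule, item mean, multiple
#' imputation by chained equations (with and without the half-rule), and
#' complete case.
#'
#' @return A character vector of method ids.
#' @export
hads_methods <- function() .METHODS

# ---- internal helpers on the item block ------------------------------------

item_matrix <- function(data) {
  miss <- setdiff(.ITEM_COLS, names(data))
  if (length(miss) > 0) {
    abort(paste0("data must contain item columns ", paste(miss, collapse = ", ")))
  }
  m <- as.matrix(data[.ITEM_COLS])
  storage.mode(m) <- "double"
  m
}

validate_items <- function(x, allow_missing = TRUE) {
  bad <- !is.na(x) & (x < 0 | x > 3 | x != round(x))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "item values must be integers in 0..3: subject %d, item %d has value %s",
      idx[1], idx[2], format(x[bad][1])
    ))
  }
  if (!allow_missing && anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1, ]
    abort(sprintf("missing item value: subject %d, item %d", idx[1], idx[2]))
  }
  invisible(x)
}

# n x 3 matrix of subscale sums (NA propagates)
score_mat <- function(x) {
  cbind(
    anxiety = rowSums(x[, .ANX, drop = FALSE]),
    depression = rowSums(x[, .DEP, drop = FALSE]),
    distress = rowSums(x)
  )
}
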