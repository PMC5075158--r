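# Scoring and the seven missing-item handling methods. All methods work on
# the item block in scored orientation; observed cells are never altered,
# imputed values are real-valued in [0, 3] and enter the sums unrounded.

#' Convert raw questionnaire coding to scored orientation
#'
#' On the printed form some items are worded positively and reverse-coded:
#' anxiety items 1, 3, 5, 11, 13 and depression items 6, 8, 10. This maps
#' those items `x -> 3 - x`, leaving the rest unchanged and preserving
#' missing values. The map is an involution: applying it twice returns the
#' input.
#'
#' @param data A data frame with `hads1`..`hads14` columns in raw coding
#'   (integers 0-3 or `NA`).
#' @return The data frame with items in scored orientation (higher = worse).
#' @export
hads_orient <- function(data) {
  x <- item_matrix(data)
  validate_items(x)
  x[, .REVERSED] <- 3 - x[, .REVERSED]
  out <- as_tibble(data)
  for (j in 1:14) out[[.ITEM_COLS[j]]] <- unname(x[, j])
  out
}

# ---- imputation on the item matrix -----------------------------------------

impute_subject_mean_mat <- function(x) {
  miss <- is.na(x)
  rm <- rowMeans(x, na.rm = TRUE) # NaN when all 14 missing
  fill <- matrix(rm, nrow(x), ncol(x))
  x[miss] <- fill[miss]
  x
}

impute_subscale_mean_mat <- function(x) {
  for (idx in list(.ANX, .DEP)) {
    block <- x[, idx, drop = FALSE]
    miss <- is.na(block)
    rm <- rowMeans(block, na.rm = TRUE) # NaN when all 7 missing
    fill <- matrix(rm, nrow(block), ncol(block))
    block[miss] <- fill[miss]
    x[, idx] <- block
  }
  x
}

impute_item_mean_mat <- function(x) {
  miss <- is.na(x)
  cm <- colMeans(x, na.rm = TRUE)
  if (any(is.nan(cm[colSums(miss) > 0]))) {
    abort("item mean undefined: an item is missing for every subject")
  }
  fill <- matrix(cm, nrow(x), ncol(x), byrow = TRUE)
  x[miss] <- fill[miss]
  x
}

# chained-equations multiple imputation: each incomplete item is regressed
# on the other 13 (linear model on currently-completed predictors), missing
# values are replaced by prediction + Gaussian noise and truncated to
# [0, 3]; sweeps iterate in item order after an item-mean initialization.
# The m completed sets are averaged cell-wise. Singular fits fall back to
# the item mean for that visit.
impute_mice_mat <- function(x, m = 10, sweeps = 10) {
  miss <- is.na(x)
  if (!any(miss)) return(x)
  incomplete <- which(colSums(miss) > 0)
  cm <- colMeans(x, na.rm = TRUE)
  if (any(is.nan(cm[incomplete]))) {
    abort("chained equations need at least one observed value per item")
  }
  acc <- matrix(0, nrow(x), ncol(x))
  for (set in seq_len(m)) {
    f <- x
    for (j in incomplete) f[miss[, j], j] <- cm[j]
    for (sw in seq_len(sweeps)) {
      for (j in incomplete) {
        obs <- !miss[, j]
        a <- cbind(1, f[, -j, drop = FALSE])
        imputed <- tryCatch({
          qr_a <- qr(a[obs, , drop = FALSE])
          beta <- qr.coef(qr_a, x[obs, j])
          beta[is.na(beta)] <- 0 # aliased columns contribute nothing
          res <- x[obs, j] - a[obs, , drop = FALSE] %*% beta
          sigma <- sqrt(sum(res^2) / max(1, sum(obs) - qr_a$rank))
          pred <- a[!obs, , drop = FALSE] %*% beta
          drawn <- pred + rnorm(sum(!obs)) * sigma
          pmin(3, pmax(0, drawn))
        }, error = function(e) rep(cm[j], sum(!obs)))
        f[!obs, j] <- imputed
      }
    }
    acc <- acc + f
  }
  out <- acc / m
  out[!miss] <- x[!miss]
  out
}

#' Impute missing HADS items
#'
#' Fills missing items with one of the imputation rules: the subject's mean
#' over all observed items (`subject_mean`), the subject's mean over the
#' observed items of the item's own subscale (`subscale_mean`), the item's
#' mean across subjects of the current sample (`item_mean`), or chained-
#' equations multiple imputation averaged over `m` completed sets (`mi`).
#' Observed cells are preserved exactly; imputed values are real numbers in
#' [0, 3].
#'
#' Degenerate subjects (all contributing items missing) keep `NaN` in the
#' affected cells under `subject_mean`/`subscale_mean`; their scores become
#' missing downstream.
#'
#' @param data A data frame with `hads1`..`hads14` columns (scored
#'   orientation, `NA` = missing).
#' @param method Imputation rule.
#' @param m Number of completed sets for `mi`.
#' @param seed Optional integer seed (only `mi` draws random numbers).
#' @return The data frame with items completed (numeric).
#' @export
hads_impute <- function(data,
                        method = c("subscale_mean", "subject_mean", "item_mean", "mi"),
                        m = 10, seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  x <- item_matrix(data)
  validate_items(x)
  x <- switch(method,
    subject_mean = impute_subject_mean_mat(x),
    subscale_mean = impute_subscale_mean_mat(x),
    item_mean = impute_item_mean_mat(x),
    mi = impute_mice_mat(x, m = m)
  )
  out <- as_tibble(data)
  for (j in 1:14) out[[.ITEM_COLS[j]]] <- unname(x[, j])
  out
}

# ---- scoring ---------------------------------------------------------------

# observed-count half-rule mask: n x 2 logical, TRUE if >= 4 of 7 observed
half_rule_pass <- function(miss) {
  cbind(
    anxiety = rowSums(!miss[, .ANX, drop = FALSE]) >= 4,
    depression = rowSums(!miss[, .DEP, drop = FALSE]) >= 4
  )
}

# scores (n x 3, NA where a method does not score) from a masked item matrix
method_scores_mat <- function(x, method, m = 10) {
  miss <- is.na(x)
  scores <- switch(method,
    complete_case = {
      s <- score_mat(x) # NA propagates: scored only when every scale item observed
      s
    },
    subject_mean = score_mat(impute_subject_mean_mat(x)),
    subscale_mean = score_mat(impute_subscale_mean_mat(x)),
    item_mean = score_mat(impute_item_mean_mat(x)),
    mi = score_mat(impute_mice_mat(x, m = m)),
    subscale_half_mean = ,
    mi_half = {
      completed <- if (method == "mi_half") impute_mice_mat(x, m = m)
                   else impute_subscale_mean_mat(x)
      s <- score_mat(completed)
      pass <- half_rule_pass(miss)
      s[!pass[, "anxiety"], "anxiety"] <- NA
      s[!pass[, "depression"], "depression"] <- NA
      s[, "distress"] <- s[, "anxiety"] + s[, "depression"]
      s
    },
    abort(paste0("unknown method: ", method))
  )
  scores[is.nan(scores)] <- NA # degenerate all-missing subjects/subscales
  scores
}

#' Score the HADS under a missing-item handling method
#'
#' Computes anxiety (items 1,3,5,7,9,11,13), depression (items
#' 2,4,6,8,10,12,14) and distress (total) scores from items in scored
#' orientation, handling missing items by the chosen method:
#'
#' * `complete`: requires complete items, errors otherwise.
#' * `complete_case`: a scale is scored only for subjects with all of that
#'   scale's items observed (per-scale exclusion).
#' * `subject_mean`, `subscale_mean`, `item_mean`, `mi`: impute (see
#'   [hads_impute()]) then sum.
#' * `subscale_half_mean`, `mi_half`: as `subscale_mean` / `mi`, but a
#'   subscale is scored only if at least half (>= 4 of 7) of its items are
#'   observed; distress requires both subscales to pass.
#'
#' @param data A data frame with `hads1`..`hads14` columns (scored
#'   orientation; use [hads_orient()] first for raw questionnaire coding).
#' @param method Handling method (see [hads_methods()]), or `"complete"`.
#' @param m Number of completed sets for the MI-based methods.
#' @param seed Optional integer seed (MI methods draw random numbers).
#' @return A tibble with columns `subject_id`, `method`, `anxiety` (0-21),
#'   `depression` (0-21), `distress` (0-42); `NA` where the method leaves a
#'   subject unscored.
#' @examples
#' complete <- tibble::as_tibble(setNames(as.list(rep(1L, 14)), paste0("hads", 1:14)))
#' hads_score(complete, "complete") # 7 / 7 / 14
#' @export
hads_score <- function(data, method = "complete", m = 10, seed = NULL) {
  method <- match.arg(method, c("complete", .METHODS))
  if (!is.null(seed)) set.seed(seed)
  x <- item_matrix(data)
  validate_items(x)
  if (method == "complete") {
    validate_items(x, allow_missing = FALSE)
    s <- score_mat(x)
  } else {
    s <- method_scores_mat(x, method, m = m)
  }
  id <- if ("subject_id" %in% names(data)) data$subject_id else seq_len(nrow(x))
  tibble(
    subject_id = id, method = method,
    anxiety = unname(s[, "anxiety"]), depression = unname(s[, "depression"]),
    distress = unname(s[, "distress"])
  )
}
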