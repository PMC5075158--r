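# Missingness induction: a two-stage procedure. Stage 1 selects deletion
# candidates (probability/fraction p_sub, by mechanism); stage 2 deletes
# each in-scope item of a candidate independently with probability p_item.

.MECHANISMS <- c("random", "demographic", "subscale")

.DEFAULT_DEMO_COEF <- c(age = 1, male = 1, on_treatment = 1, immigrant = 1)

# logistic-model linear predictor ranking subjects for the demographic
# mechanism; coefficients are log-odds weights. Only the induced ordering
# matters because candidates are taken as the top fraction.
demo_linear_predictor <- function(cohort, coefficients = .DEFAULT_DEMO_COEF) {
  age <- cohort$age
  age_z <- if (length(age) > 1 && sd(age) > 0) (age - mean(age)) / sd(age) else age * 0
  coefficients[["age"]] * age_z +
    coefficients[["male"]] * (cohort$sex == "male") +
    coefficients[["on_treatment"]] * cohort$on_treatment +
    coefficients[["immigrant"]] * cohort$immigrant
}

# top-round(p_sub * n) indices by key, ties broken by a random permutation
top_fraction <- function(key, p_sub) {
  n <- length(key)
  k <- round(p_sub * n)
  if (k == 0) return(integer())
  order(-key, sample.int(n))[seq_len(k)]
}

candidates_internal <- function(mechanism, p_sub, n, truth_score = NULL, lp = NULL) {
  switch(mechanism,
    random = which(runif(n) < p_sub),
    subscale = top_fraction(truth_score, p_sub),
    demographic = top_fraction(lp, p_sub),
    abort(paste0("unknown mechanism: ", mechanism))
  )
}

delete_internal <- function(x, candidates, scope, p_item) {
  if (length(candidates) > 0 && p_item > 0) {
    u <- matrix(runif(length(candidates) * length(scope)),
                length(candidates), length(scope))
    block <- x[candidates, scope, drop = FALSE]
    block[u < p_item] <- NA_real_
    x[candidates, scope] <- block
  }
  x
}

#' Select deletion candidates
#'
#' Stage 1 of missingness induction. Under the `random` mechanism each
#' subject is independently a candidate with probability `p_sub`; under the
#' `subscale` mechanism the `round(p_sub * n)` subjects with the highest
#' true score on `target_scale` are candidates; under the `demographic`
#' mechanism subjects are ranked by a logistic linear predictor in age
#' (standardized), male sex, treatment and immigrant status, and the top
#' fraction is taken. Ranking ties are broken by a seeded random
#' permutation.
#'
#' @param cohort A complete cohort.
#' @param mechanism One of `"random"`, `"demographic"`, `"subscale"`.
#' @param p_sub Subject-level candidate probability / fraction in (0, 1].
#' @param target_scale Scale whose true score ranks subjects under the
#'   subscale mechanism.
#' @param demo_coefficients Named log-odds weights
#'   (`age`, `male`, `on_treatment`, `immigrant`).
#' @param seed Optional integer seed.
#' @return Integer vector of candidate row indices.
#' @export
hads_candidates <- function(cohort,
                            mechanism = c("random", "demographic", "subscale"),
                            p_sub,
                            target_scale = c("depression", "anxiety", "distress"),
                            demo_coefficients = .DEFAULT_DEMO_COEF,
                            seed = NULL) {
  mechanism <- match.arg(mechanism)
  target_scale <- match.arg(target_scale)
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0, p_sub >= 0, p_sub <= 1)
  if (!is.null(seed)) set.seed(seed)
  truth <- lp <- NULL
  if (mechanism == "subscale") {
    x <- item_matrix(cohort)
    validate_items(x, allow_missing = FALSE)
    truth <- score_mat(x)[, target_scale]
  }
  if (mechanism == "demographic") lp <- demo_linear_predictor(cohort, demo_coefficients)
  sort(candidates_internal(mechanism, p_sub, nrow(cohort), truth, lp))
}

#' Induce item-level missingness
#'
#' Runs both stages of the deletion procedure on a complete cohort:
#' candidate selection (see [hads_candidates()]) followed by independent
#' deletion of each in-scope item with probability `p_item` within
#' candidates. The deletion scope is the 7 items of `target_scale`, or all
#' 14 items when `target_scale = "distress"`. Observed values are never
#' altered.
#'
#' @inheritParams hads_candidates
#' @param p_item Per-item deletion probability within candidates, in [0, 1].
#' @return The cohort tibble with deleted items set to `NA` and a logical
#'   `candidate` column appended.
#' @examples
#' \donttest{
#' cohort <- hads_generate(hads_default_spec(), 200, seed = 2)
#' masked <- hads_mask(cohort, "subscale", p_sub = 0.5, p_item = 0.5, seed = 3)
#' mean(is.na(hads_item_matrix(masked))) # about 12.5% of all 14 columns
#' }
#' @export
hads_mask <- function(cohort,
                      mechanism = c("random", "demographic", "subscale"),
                      p_sub, p_item,
                      target_scale = c("depression", "anxiety", "distress"),
                      demo_coefficients = .DEFAULT_DEMO_COEF,
                      seed = NULL) {
  mechanism <- match.arg(mechanism)
  target_scale <- match.arg(target_scale)
  stopifnot(p_item >= 0, p_item <= 1)
  if (!is.null(seed)) set.seed(seed)
  cand <- hads_candidates(cohort, mechanism, p_sub, target_scale,
                          demo_coefficients, seed = NULL)
  x <- item_matrix(cohort)
  scope <- hads_items(target_scale)
  x <- delete_internal(x, cand, scope, p_item)
  out <- as_tibble(cohort)
  for (j in 1:14) out[[.ITEM_COLS[j]]] <- unname(x[, j])
  out$candidate <- seq_len(nrow(out)) %in% cand
  out
}

#' Overall missing-item rate
#'
#' The expected fraction of in-scope item cells deleted by the two-stage
#' procedure: `100 * p_sub * p_item` percent. The default design grid
#' (`p_sub` 0.1/0.2/0.5 by `p_item` 0.2/0.5) yields rates of 2, 4, 5, 10
#' and 25 %.
#'
#' @param p_sub,p_item Stage probabilities in [0, 1] (vectorized).
#' @return Percentage(s).
#' @examples
#' overall_missing_rate(0.5, 0.5) # 25
#' @export
overall_missing_rate <- function(p_sub, p_item) {
  stopifnot(all(p_sub >= 0 & p_sub <= 1), all(p_item >= 0 & p_item <= 1))
  100 * p_sub * p_item
}

#' Extract the item block of a cohort as a matrix
#'
#' Convenience accessor: the `hads1`..`hads14` columns as a numeric matrix
#' (missing items as `NA`).
#'
#' @param data A cohort-shaped data frame.
#' @return An n x 14 numeric matrix.
#' @export
hads_item_matrix <- function(data) item_matrix(data)
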