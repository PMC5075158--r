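#' Generate a synthetic HADS cohort
#'
#' Draws `n` subjects from a calibrated graded latent-trait model: two
#' correlated standard-normal traits (anxiety, depression), one latent
#' response per item thresholded into the 0-3 categories, a quality-of-life
#' score that is a weighted sum of the traits plus Gaussian noise (mean 0,
#' SD 1 by construction), and demographic covariates drawn independently of
#' the traits (truncated-normal age, Bernoulli sex / treatment / immigrant
#' status).
#'
#' Items are returned in scored orientation (higher = worse), the
#' orientation entering the subscale sums. Use [hads_orient()] to map raw
#' questionnaire coding into this orientation.
#'
#' @param spec A `hads_spec` from [hads_calibrate()] or [hads_default_spec()].
#' @param n Number of subjects (`n = 0` gives an empty cohort).
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used. Identical `(spec, n, seed)` give identical cohorts.
#' @return A tibble of class `hads_cohort` with columns `subject_id`,
#'   `hads1`..`hads14` (integers 0-3), `age`, `sex`, `on_treatment`,
#'   `immigrant` and `qol`.
#' @examples
#' \donttest{
#' cohort <- hads_generate(hads_default_spec(), n = 500, seed = 1)
#' hads_describe(cohort)
#' }
#' @export
hads_generate <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "hads_spec"), is.numeric(n), length(n) == 1, n >= 0)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)

  if (n == 0L) {
    out <- tibble(
      subject_id = integer(),
      !!!setNames(rep(list(integer()), 14), .ITEM_COLS),
      age = numeric(), sex = character(),
      on_treatment = logical(), immigrant = logical(), qol = numeric()
    )
    return(structure(out, class = c("hads_cohort", class(out))))
  }

  rho <- spec$latent_corr
  z <- matrix(rnorm(n * 2L), n, 2L)
  trait_a <- z[, 1]
  trait_d <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]

  noise <- matrix(rnorm(n * 14L), n, 14L)
  items <- matrix(0L, n, 14L)
  for (j in 1:14) {
    p <- spec$items[j, ]
    tr <- if (p$subscale == "anxiety") trait_a else trait_d
    y <- p$loading * tr + sqrt(1 - p$loading^2) * noise[, j]
    items[, j] <- (y > p$threshold_1) + (y > p$threshold_2) + (y > p$threshold_3)
  }

  qol <- spec$qol_weights[["anxiety"]] * trait_a +
    spec$qol_weights[["depression"]] * trait_d +
    rnorm(n) * spec$qol_noise_sd

  cv <- spec$covariates
  # inverse-CDF truncated normal for age
  plo <- pnorm(cv$age_min, cv$age_mean, cv$age_sd)
  phi <- pnorm(cv$age_max, cv$age_mean, cv$age_sd)
  age <- stats::qnorm(runif(n, plo, phi), cv$age_mean, cv$age_sd)
  sex <- ifelse(runif(n) < cv$p_male, "male", "female")
  on_treatment <- runif(n) < cv$p_on_treatment
  immigrant <- runif(n) < cv$p_immigrant

  out <- tibble(subject_id = seq_len(n))
  for (j in 1:14) out[[.ITEM_COLS[j]]] <- unname(items[, j])
  out$age <- age
  out$sex <- sex
  out$on_treatment <- on_treatment
  out$immigrant <- immigrant
  out$qol <- qol
  structure(out, class = c("hads_cohort", class(out)))
}

#' Bootstrap-resample a cohort
#'
#' Draws `n` subjects uniformly with replacement, carrying all columns
#' along; this is how each simulated dataset is formed from the source
#' cohort.
#'
#' @param cohort A cohort data frame (one row per subject).
#' @param n Number of subjects to draw (positive).
#' @param seed Optional integer seed.
#' @return A tibble with `n` rows and fresh `subject_id` 1..n.
#' @export
hads_bootstrap <- function(cohort, n, seed = NULL) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0)
  if (!is.numeric(n) || length(n) != 1 || n <= 0) {
    abort("`n` must be a positive integer")
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(cohort), as.integer(n), replace = TRUE)
  out <- cohort[idx, , drop = FALSE]
  if ("subject_id" %in% names(out)) out$subject_id <- seq_len(nrow(out))
  as_tibble(out)
}

#' Read or write a cohort CSV
#'
#' The cohort dialect: one row per subject, header required, columns
#' `subject_id`, `hads1`..`hads14` (integers 0-3, scored orientation, empty
#' field = missing), `age`, `sex`, `on_treatment`, `immigrant`, `qol`.
#' Masked cohorts round-trip: missing items are written as empty fields.
#'
#' @param path File path.
#' @param cohort A cohort data frame.
#' @return `read_hads_cohort()` returns a tibble; `write_hads_cohort()`
#'   returns `path` invisibly.
#' @export
read_hads_cohort <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_items(item_matrix(out))
  out
}

#' @rdname read_hads_cohort
#' @export
write_hads_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "", progress = FALSE)
  invisible(path)
}
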