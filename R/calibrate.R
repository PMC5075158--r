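# Cohort calibration: a graded latent-trait model (discretized bivariate
# normal) whose parameters are solved so that large generated cohorts
# reproduce the reference cohort's printed descriptives.

# Latent model, per subject i and item j in subscale s:
#   y_ij = loading_s * T_is + sqrt(1 - loading_s^2) * e_ij,   T, e ~ N(0,1)
#   item_ij = #{k : y_ij > (b_k - mu_j) / scale_s},  b = (0.5, 1.5, 2.5)
# so y is marginally standard normal and the item mean is analytic:
#   E[item_j] = sum_k pnorm((mu_j - b_k) / scale_s)
.BASE_CUTS <- c(0.5, 1.5, 2.5)

# calibration residual tolerances (properties a calibrated spec must meet on
# a large fresh cohort)
.CAL_TOL <- c(item_mean = 0.05, subscale_mean = 0.15, alpha = 0.02, qol_corr = 0.03)

#' Calibration targets: descriptive statistics of the reference cohort
#'
#' The printed descriptives of the cohort the generator emulates: 1444
#' Australian cancer patients and survivors who completed the HADS and a
#' quality-of-life (QoL) questionnaire. Per-item means, subscale means and
#' standard deviations, Cronbach's alphas, and Pearson correlations of each
#' score with QoL.
#'
#' The depression alpha is taken as 0.83; severity-band proportions
#' (e.g. 76.1 % of subjects in the depression normal range 0-7) are not
#' targets but emerge from the fitted model.
#'
#' @return A named list with elements `item_means` (14 values, scored
#'   orientation), `subscale_means`, `subscale_sds`, `alphas` (anxiety,
#'   depression, distress) and `qol_correlations`.
#' @seealso [hads_calibrate()]
#' @export
hads_targets <- function() {
  item_means <- numeric(14)
  item_means[.ANX] <- c(0.87, 0.86, 1.00, 0.92, 0.56, 0.87, 0.44)
  item_means[.DEP] <- c(0.74, 0.51, 0.65, 1.36, 0.75, 0.66, 0.44)
  names(item_means) <- .ITEM_COLS
  list(
    item_means = item_means,
    subscale_means = c(anxiety = 5.66, depression = 5.07),
    subscale_sds = c(anxiety = 4.20, depression = 4.11),
    alphas = c(anxiety = 0.87, depression = 0.83, distress = 0.90),
    qol_correlations = c(anxiety = -0.687, depression = -0.767, distress = -0.796)
  )
}

# analytic item mean given location mu and subscale discretization scale s
analytic_item_mean <- function(mu, s) sum(pnorm((mu - .BASE_CUTS) / s))

solve_location <- function(target_mean, s) {
  uniroot(function(m) analytic_item_mean(m, s) - target_mean,
          lower = -12, upper = 12, tol = 1e-9)$root
}

# fast alpha on a complete matrix, no validation (hot path)
alpha_fast <- function(x) {
  k <- ncol(x)
  k / (k - 1) * (1 - sum(apply(x, 2, var)) / var(rowSums(x)))
}

# deterministic bisection: f increasing, find f = 0 in [lo, hi]
bisect <- function(f, lo, hi, iter) {
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# discretize a 7-item subscale from fixed base normals (common random numbers,
# so every tuning objective is a deterministic function of its parameter)
discretize_subscale <- function(mus, s, loading, trait, noise) {
  resid <- sqrt(1 - loading^2)
  x <- matrix(0L, length(trait), 7L)
  for (j in 1:7) {
    y <- loading * trait + resid * noise[, j]
    th <- (.BASE_CUTS - mus[j]) / s
    x[, j] <- (y > th[1]) + (y > th[2]) + (y > th[3])
  }
  x
}

run_with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Calibrate the synthetic-cohort generator
#'
#' Solves the parameters of the graded latent-trait model so that large
#' generated cohorts reproduce the target descriptives: per-item thresholds
#' from the item means (analytic bisection on the latent location), a
#' per-subscale discretization scale matched to the printed subscale SD, a
#' common per-subscale loading matched to the subscale alpha, the latent
#' anxiety-depression correlation matched to the distress alpha, and QoL
#' weights solved linearly from the target score-QoL correlations. All
#' simulation-based tuning reuses one fixed set of base normal draws, so the
#' result is deterministic given `seed`.
#'
#' Printed per-item means need not sum exactly to the printed subscale mean
#' (they are independently rounded); with `reconcile_item_means = TRUE`
#' (default) the item-mean targets are rescaled proportionally within each
#' subscale so the generated subscale mean is centred on the printed value.
#' The rescaling never moves an item target by more than the 0.05 item
#' tolerance.
#'
#' The fitted spec is validated on a fresh cohort of `validate_n` subjects;
#' if any residual exceeds its tolerance (item means 0.05, subscale means
#' 0.15, alphas 0.02, QoL correlations 0.03) calibration fails with an error
#' reporting the worst residual.
#'
#' @param targets Calibration targets, as returned by [hads_targets()].
#' @param latent_corr_init Centre of the search bracket for the latent
#'   anxiety-depression correlation.
#' @param n_calib Number of subjects in the calibration sample used for
#'   simulation-based tuning.
#' @param seed Seed for the calibration draws (a study constant, not a
#'   per-run seed; the default defines the package's reference calibration).
#' @param reconcile_item_means Rescale item-mean targets to the printed
#'   subscale means (see Details).
#' @param validate_n Size of the fresh validation cohort.
#' @param iter Bisection iteration caps, a named list
#'   (`scale`, `loading`, `corr`).
#' @return An object of class `hads_spec`: the fitted item models
#'   (locations, thresholds, loadings), latent correlation, QoL weights and
#'   noise SD, covariate distributions, and a `calibration` record holding
#'   targets, achieved values and residuals. Methods: [tidy()], [glance()],
#'   `print()`.
#' @examples
#' \donttest{
#' spec <- hads_calibrate(n_calib = 5000, validate_n = 5000)
#' glance(spec)
#' }
#' @export
hads_calibrate <- function(targets = hads_targets(),
                           latent_corr_init = 0.5,
                           n_calib = 40000,
                           seed = 1385,
                           reconcile_item_means = TRUE,
                           validate_n = 50000,
                           iter = list(scale = 12, loading = 16, corr = 16)) {
  stopifnot(
    length(targets$item_means) == 14,
    all(targets$item_means > 0, targets$item_means < 3),
    all(targets$subscale_sds > 0),
    all(targets$alphas > 0, targets$alphas < 1),
    all(targets$qol_correlations > -1, targets$qol_correlations < 0),
    n_calib >= 1000
  )

  item_targets <- targets$item_means
  if (reconcile_item_means) {
    for (s in c("anxiety", "depression")) {
      idx <- hads_items(s)
      item_targets[idx] <- item_targets[idx] *
        targets$subscale_means[[s]] / sum(item_targets[idx])
    }
    shift <- max(abs(item_targets - targets$item_means))
    if (shift > .CAL_TOL[["item_mean"]]) {
      abort(sprintf(
        "item-mean reconciliation moved a target by %.3f (> %.2f); targets inconsistent",
        shift, .CAL_TOL[["item_mean"]]
      ))
    }
  }

  # fixed base draws: 2 traits + 14 item noises
  z <- run_with_seed(seed, matrix(rnorm(n_calib * 16L), n_calib, 16L))
  traits <- list(anxiety = z[, 1], depression = z[, 2])
  noises <- list(anxiety = z[, 3:9], depression = z[, 10:16])

  # per-subscale: scale s against SD (outer), loading against alpha (inner)
  fit_subscale <- function(sub) {
    idx <- hads_items(sub)
    means <- item_targets[idx]
    a_target <- targets$alphas[[sub]]
    sd_target <- targets$subscale_sds[[sub]]
    tr <- traits[[sub]]
    no <- noises[[sub]]
    loading_for <- function(mus, s) {
      bisect(function(l) alpha_fast(discretize_subscale(mus, s, l, tr, no)) - a_target,
             0.10, 0.99, iter$loading)
    }
    sd_resid <- function(s) {
      mus <- vapply(means, solve_location, 0, s = s)
      l <- loading_for(mus, s)
      sd(rowSums(discretize_subscale(mus, s, l, tr, no))) - sd_target
    }
    s <- bisect(sd_resid, 0.4, 2.5, iter$scale)
    mus <- vapply(means, solve_location, 0, s = s)
    list(scale = s, loading = loading_for(mus, s), locations = mus)
  }
  fa <- fit_subscale("anxiety")
  fd <- fit_subscale("depression")

  # latent correlation against the distress alpha
  xa <- discretize_subscale(fa$locations, fa$scale, fa$loading,
                            traits$anxiety, noises$anxiety)
  dep_items_at <- function(rho) {
    td <- rho * traits$anxiety + sqrt(1 - rho^2) * traits$depression
    discretize_subscale(fd$locations, fd$scale, fd$loading, td, noises$depression)
  }
  lo <- max(0.01, latent_corr_init - 0.5)
  hi <- min(0.995, latent_corr_init + 0.5)
  dis_alpha <- function(rho) alpha_fast(cbind(xa, dep_items_at(rho)))
  # widen the bracket if the target alpha is not straddled
  while (dis_alpha(lo) > targets$alphas[["distress"]] && lo > 0.011) lo <- max(0.01, lo - 0.2)
  while (dis_alpha(hi) < targets$alphas[["distress"]] && hi < 0.994) hi <- min(0.995, hi + 0.2)
  rho <- bisect(function(r) dis_alpha(r) - targets$alphas[["distress"]], lo, hi, iter$corr)

  # QoL weights: solve the 2x2 linear system matching the anxiety and
  # depression score correlations; the distress correlation is implied.
  td <- rho * traits$anxiety + sqrt(1 - rho^2) * traits$depression
  xd <- dep_items_at(rho)
  sa <- rowSums(xa)
  sdep <- rowSums(xd)
  m <- rbind(
    c(cov(traits$anxiety, sa), cov(td, sa)),
    c(cov(traits$anxiety, sdep), cov(td, sdep))
  )
  rhs <- c(
    targets$qol_correlations[["anxiety"]] * sd(sa),
    targets$qol_correlations[["depression"]] * sd(sdep)
  )
  w <- tryCatch(solve(m, rhs), error = function(e) {
    abort("QoL weight system is singular; targets degenerate")
  })
  explained <- w[1]^2 + w[2]^2 + 2 * w[1] * w[2] * rho
  if (explained >= 1) {
    abort(sprintf(
      "QoL correlation targets unattainable: latent variance %.3f >= 1", explained
    ))
  }

  items <- tibble(
    item = 1:14,
    subscale = ifelse(1:14 %in% .ANX, "anxiety", "depression"),
    reverse_scored = 1:14 %in% .REVERSED,
    target_mean = unname(item_targets),
    location = 0, scale = 0, loading = 0
  )
  items$location[.ANX] <- fa$locations
  items$location[.DEP] <- fd$locations
  items$scale <- ifelse(items$subscale == "anxiety", fa$scale, fd$scale)
  items$loading <- ifelse(items$subscale == "anxiety", fa$loading, fd$loading)
  for (k in 1:3) {
    items[[paste0("threshold_", k)]] <- (.BASE_CUTS[k] - items$location) / items$scale
  }

  spec <- structure(list(
    items = items,
    latent_corr = rho,
    qol_weights = c(anxiety = w[1], depression = w[2]),
    qol_noise_sd = sqrt(1 - explained),
    covariates = list(
      age_mean = 63, age_sd = 11.8, age_min = 19, age_max = 87,
      p_male = 0.46, p_on_treatment = 0.59, p_immigrant = 0.59
    ),
    calibration = list(
      seed = seed, n_calib = n_calib, targets = targets,
      item_targets = item_targets
    )
  ), class = "hads_spec")

  # validate on a fresh cohort and record residuals
  check <- validate_calibration(spec, n = validate_n, seed = seed + 1L)
  spec$calibration$achieved <- check$achieved
  spec$calibration$residuals <- check$residuals
  worst <- check$residuals[which.max(check$residuals$residual / check$residuals$tolerance), ]
  if (worst$residual > worst$tolerance) {
    abort(sprintf(
      "calibration failed: %s residual %.4f exceeds tolerance %.3f",
      worst$quantity, worst$residual, worst$tolerance
    ))
  }
  spec
}

# achieved descriptives + residual table on a fresh generated cohort
validate_calibration <- function(spec, n, seed) {
  cohort <- hads_generate(spec, n = n, seed = seed)
  x <- item_matrix(cohort)
  s <- score_mat(x)
  targets <- spec$calibration$targets
  achieved <- list(
    item_means = colMeans(x),
    subscale_means = c(anxiety = mean(s[, 1]), depression = mean(s[, 2])),
    subscale_sds = c(anxiety = sd(s[, 1]), depression = sd(s[, 2])),
    alphas = c(
      anxiety = alpha_fast(x[, .ANX]),
      depression = alpha_fast(x[, .DEP]),
      distress = alpha_fast(x)
    ),
    qol_correlations = c(
      anxiety = cor(s[, 1], cohort$qol),
      depression = cor(s[, 2], cohort$qol),
      distress = cor(s[, 3], cohort$qol)
    )
  )
  residuals <- dplyr::bind_rows(
    tibble(
      quantity = paste0("item_mean_", 1:14),
      residual = abs(achieved$item_means - unname(targets$item_means)),
      tolerance = .CAL_TOL[["item_mean"]]
    ),
    tibble(
      quantity = paste0("subscale_mean_", names(targets$subscale_means)),
      residual = abs(achieved$subscale_means - targets$subscale_means),
      tolerance = .CAL_TOL[["subscale_mean"]]
    ),
    tibble(
      quantity = paste0("alpha_", names(targets$alphas)),
      residual = abs(achieved$alphas - targets$alphas),
      tolerance = .CAL_TOL[["alpha"]]
    ),
    tibble(
      quantity = paste0("qol_corr_", names(targets$qol_correlations)),
      residual = abs(achieved$qol_correlations - targets$qol_correlations),
      tolerance = .CAL_TOL[["qol_corr"]]
    )
  )
  list(achieved = achieved, residuals = residuals)
}

#' Reference calibrated generator spec
#'
#' The package's default `hads_spec`, calibrated once per session with
#' [hads_calibrate()] at its defaults and cached. Every quantity the
#' calibration solves is deterministic, so repeated calls (and fresh
#' sessions) yield the identical spec.
#'
#' @return A `hads_spec` object.
#' @export
hads_default_spec <- function() {
  if (is.null(.hadsim_cache$spec)) {
    .hadsim_cache$spec <- hads_calibrate()
  }
  .hadsim_cache$spec
}

#' @export
print.hads_spec <- function(x, ...) {
  cat("<hads_spec> graded latent-trait generator for 14 HADS items\n")
  cat(sprintf(
    "  loadings: anxiety %.3f, depression %.3f; latent corr %.3f\n",
    x$items$loading[.ANX[1]], x$items$loading[.DEP[1]], x$latent_corr
  ))
  cat(sprintf(
    "  QoL weights (%.3f, %.3f), noise sd %.3f\n",
    x$qol_weights[1], x$qol_weights[2], x$qol_noise_sd
  ))
  worst <- max(x$calibration$residuals$residual / x$calibration$residuals$tolerance)
  cat(sprintf(
    "  calibrated on n = %d (seed %d); worst residual %.0f%% of tolerance\n",
    x$calibration$n_calib, x$calibration$seed, 100 * worst
  ))
  invisible(x)
}

#' @describeIn hads_calibrate Per-item parameters of a fitted spec as a tibble.
#' @param x A `hads_spec`.
#' @param ... Unused.
#' @method tidy hads_spec
#' @export
tidy.hads_spec <- function(x, ...) x$items

#' @describeIn hads_calibrate One-row summary: loadings, scales, latent
#'   correlation, QoL parameters and the worst calibration residual.
#' @method glance hads_spec
#' @export
glance.hads_spec <- function(x, ...) {
  tibble(
    loading_anxiety = x$items$loading[.ANX[1]],
    loading_depression = x$items$loading[.DEP[1]],
    scale_anxiety = x$items$scale[.ANX[1]],
    scale_depression = x$items$scale[.DEP[1]],
    latent_corr = x$latent_corr,
    qol_weight_anxiety = unname(x$qol_weights["anxiety"]),
    qol_weight_depression = unname(x$qol_weights["depression"]),
    qol_noise_sd = x$qol_noise_sd,
    n_calib = x$calibration$n_calib,
    worst_residual_frac = max(
      x$calibration$residuals$residual / x$calibration$residuals$tolerance
    )
  )
}

#' Write or read a generator spec as YAML
#'
#' Serializes a `hads_spec` to a plain declarative YAML file and back.
#' Calibration provenance (targets, residuals) is carried along.
#'
#' @param spec A `hads_spec`.
#' @param path File path.
#' @return `hads_spec_write()` returns `path` invisibly; `hads_spec_read()`
#'   returns a `hads_spec`.
#' @export
hads_spec_write <- function(spec, path) {
  stopifnot(inherits(spec, "hads_spec"))
  out <- list(
    items = lapply(seq_len(nrow(spec$items)), function(i) as.list(spec$items[i, ])),
    latent_corr = spec$latent_corr,
    qol_weights = as.list(spec$qol_weights),
    qol_noise_sd = spec$qol_noise_sd,
    covariates = spec$covariates,
    calibration = list(
      seed = spec$calibration$seed,
      n_calib = spec$calibration$n_calib,
      targets = lapply(spec$calibration$targets, as.list)
    )
  )
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' @rdname hads_spec_write
#' @export
hads_spec_read <- function(path) {
  raw <- yaml::read_yaml(path)
  items <- dplyr::bind_rows(lapply(raw$items, as_tibble))
  structure(list(
    items = items,
    latent_corr = raw$latent_corr,
    qol_weights = unlist(raw$qol_weights),
    qol_noise_sd = raw$qol_noise_sd,
    covariates = raw$covariates,
    calibration = list(
      seed = raw$calibration$seed,
      n_calib = raw$calibration$n_calib,
      targets = lapply(raw$calibration$targets, unlist)
    )
  ), class = "hads_spec")
}
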