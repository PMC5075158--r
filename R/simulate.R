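# Monte-Carlo engine: the full factorial simulation over sample size,
# mechanism, p_sub, p_item and analyzed scale, with all handling methods
# evaluated on the same masked replicate.

# Lehmer-style mixing of (master seed, cell key, replicate) into a
# per-replicate seed below 2^31; products stay below 2^53 so the double
# arithmetic is exact.
.M31 <- 2147483647
mix_step <- function(h, v) ((h * 48271) %% .M31 + v %% .M31) %% .M31

string_key <- function(s) {
  h <- 7
  for (v in utf8ToInt(s)) h <- mix_step(h, v)
  h
}

replicate_seed <- function(master_seed, cell_key, rep) {
  h <- mix_step(master_seed %% .M31, cell_key)
  h <- mix_step(h, rep)
  as.integer(mix_step(h, 0))
}

# one replicate of one cell; returns a methods x metrics matrix
run_replicate <- function(items, qol, lp, n, mechanism, p_sub, p_item,
                          scale, methods, m) {
  idx <- sample.int(nrow(items), n, replace = TRUE)
  x <- items[idx, , drop = FALSE]
  truth <- score_mat(x)[, scale]
  q <- qol[idx]
  cand <- candidates_internal(
    mechanism, p_sub, n,
    truth_score = score_mat(x)[, scale], lp = lp[idx]
  )
  masked <- delete_internal(x, cand, hads_items(scale), p_item)

  mi_completed <- NULL
  if (any(c("mi", "mi_half") %in% methods)) {
    mi_completed <- impute_mice_mat(masked, m = m)
  }
  out <- matrix(NA_real_, length(methods), 6,
                dimnames = list(methods, c(
                  "individual_bias", "individual_imprecision",
                  "population_bias", "population_imprecision",
                  "n_scored", "qol_correlation"
                )))
  miss <- is.na(masked)
  for (meth in methods) {
    s <- if (meth == "mi") {
      sc <- score_mat(mi_completed)
      sc[is.nan(sc)] <- NA
      sc
    } else if (meth == "mi_half") {
      sc <- score_mat(mi_completed)
      pass <- half_rule_pass(miss)
      sc[!pass[, "anxiety"], "anxiety"] <- NA
      sc[!pass[, "depression"], "depression"] <- NA
      sc[, "distress"] <- sc[, "anxiety"] + sc[, "depression"]
      sc[is.nan(sc)] <- NA
      sc
    } else {
      method_scores_mat(masked, meth, m = m)
    }
    v <- s[, scale]
    im <- individual_metrics(v, truth)
    pm <- population_metrics(v, truth)
    out[meth, ] <- c(
      im$bias, im$imprecision, pm$bias, pm$imprecision,
      im$n_scored, qol_correlation(v, q)
    )
  }
  out
}

#' Run the missing-item simulation grid
#'
#' For every cell of the factorial design (sample size x mechanism x
#' `p_sub` x `p_item` x analyzed scale) and each replicate: bootstrap `n`
#' subjects from the cohort, compute complete-data truth scores, induce
#' missingness with the cell's mechanism (deletion scope and candidate
#' ranking follow the analyzed scale), score with every requested handling
#' method on the *same* masked data, and evaluate individual and population
#' bias/imprecision, the number of scored subjects, and the correlation
#' with QoL. Replicate metrics are averaged per cell with
#' [aggregate_cell()].
#'
#' Per-replicate seeds are derived by hashing the master seed, the cell
#' coordinates and the replicate index, so results are fully deterministic
#' and subsetting the grid never changes another cell's draws.
#'
#' @param cohort Source cohort (complete items), e.g. from
#'   [hads_generate()] or [read_hads_cohort()].
#' @param sample_sizes Bootstrap sample sizes. The defaults are the totals
#'   detecting large/medium/small standardized effects at 80 % power (see
#'   [hads_sample_size()]).
#' @param mechanisms Missingness mechanisms to cross.
#' @param p_sub,p_item Stage probabilities to cross.
#' @param methods Handling methods (see [hads_methods()]).
#' @param scales Analyzed scales; each defines its own missingness target
#'   scale and deletion scope.
#' @param replicates Simulated datasets per cell.
#' @param m Completed sets for the MI methods.
#' @param demo_coefficients Log-odds weights for the demographic mechanism.
#' @param seed Master seed.
#' @param out_dir Optional directory: writes `results.csv` and a
#'   `manifest.json` capturing the resolved configuration.
#' @return A tibble of class `hads_sim`, one row per cell x method, with
#'   the aggregated metrics, `mean_n_scored`, `qol_correlation`,
#'   `missing_rate` (percent) and the `important_bias` flag on the
#'   population bias. Methods: [glance()], [autoplot()].
#' @examples
#' \donttest{
#' cohort <- hads_generate(hads_default_spec(), 2000, seed = 9)
#' res <- hads_simulate(cohort,
#'   sample_sizes = 52, mechanisms = "subscale", p_sub = 0.5, p_item = 0.5,
#'   methods = c("subscale_mean", "complete_case"), scales = "depression",
#'   replicates = 50, seed = 1
#' )
#' res
#' }
#' @export
hads_simulate <- function(cohort,
                          sample_sizes = c(52, 128, 788),
                          mechanisms = c("random", "demographic", "subscale"),
                          p_sub = c(0.1, 0.2, 0.5),
                          p_item = c(0.2, 0.5),
                          methods = hads_methods(),
                          scales = c("anxiety", "depression", "distress"),
                          replicates = 1000,
                          m = 10,
                          demo_coefficients = .DEFAULT_DEMO_COEF,
                          seed = 1,
                          out_dir = NULL) {
  stopifnot(
    is.data.frame(cohort), nrow(cohort) > 0,
    all(methods %in% .METHODS), all(scales %in% .SCALES),
    all(mechanisms %in% .MECHANISMS),
    all(p_sub >= 0 & p_sub <= 1), all(p_item >= 0 & p_item <= 1),
    replicates >= 1
  )
  items <- item_matrix(cohort)
  validate_items(items, allow_missing = FALSE)
  has_qol <- "qol" %in% names(cohort) && !all(is.na(cohort$qol))
  qol <- if (has_qol) cohort$qol else rep(NA_real_, nrow(cohort))
  lp <- if (any(mechanisms == "demographic")) {
    demo_linear_predictor(cohort, demo_coefficients)
  } else {
    rep(0, nrow(cohort))
  }

  cells <- tidyr::expand_grid(
    n = as.integer(sample_sizes), mechanism = mechanisms,
    p_sub = p_sub, p_item = p_item, scale = scales
  )
  started <- Sys.time()
  results <- purrr::pmap(cells, function(n, mechanism, p_sub, p_item, scale) {
    cell_key <- string_key(paste(n, mechanism, p_sub, p_item, scale, sep = "|"))
    reps <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      set.seed(replicate_seed(seed, cell_key, r))
      reps[[r]] <- run_replicate(items, qol, lp, n, mechanism, p_sub,
                                 p_item, scale, methods, m)
    }
    dplyr::bind_rows(lapply(methods, function(meth) {
      per_rep <- as_tibble(t(vapply(reps, function(z) z[meth, ], numeric(6))))
      if (!has_qol) per_rep$qol_correlation <- NULL
      cell <- dplyr::mutate(aggregate_cell(per_rep), method = meth, .before = 1)
      if (!has_qol) cell$qol_correlation <- NA_real_
      cell
    }))
  })
  out <- dplyr::bind_cols(
    cells[rep(seq_len(nrow(cells)), each = length(methods)), ],
    dplyr::bind_rows(results)
  )
  out$missing_rate <- overall_missing_rate(out$p_sub, out$p_item)
  out$important_bias <- flag_important_bias(out$population_bias)
  out <- structure(
    dplyr::relocate(out, "method", .after = "scale"),
    class = c("hads_sim", class(out)),
    config = list(
      sample_sizes = sample_sizes, mechanisms = mechanisms, p_sub = p_sub,
      p_item = p_item, methods = methods, scales = scales,
      replicates = replicates, m = m, seed = seed,
      source_n = nrow(cohort)
    )
  )
  if (!is.null(out_dir)) write_sim_outputs(out, out_dir, started)
  out
}

write_sim_outputs <- function(res, out_dir, started) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(as_tibble(res), file.path(out_dir, "results.csv"),
                   progress = FALSE)
  manifest <- c(
    attr(res, "config"),
    list(
      package_version = as.character(utils::packageVersion("hadsim")),
      r_version = R.version.string,
      started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
      elapsed_secs = as.numeric(Sys.time() - started, units = "secs"),
      rows = nrow(res)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Extreme-missingness follow-up study
#'
#' The focused comparison of the subscale mean against the half-rule when
#' most of a candidate's subscale is deleted: `p_item` from 0.5 up to 0.929
#' (7 up to 13 of 14 items at the corresponding overall rates), `p_sub` 0.1
#' and 0.5, n = 52, subscale-dependent missingness on the depression scale.
#'
#' @inheritParams hads_simulate
#' @return A `hads_sim` tibble (see [hads_simulate()]).
#' @export
hads_extreme <- function(cohort,
                         p_item = c(0.5, 0.571, 0.643, 0.714, 0.786, 0.857, 0.929),
                         p_sub = c(0.1, 0.5),
                         replicates = 1000,
                         seed = 1,
                         out_dir = NULL) {
  hads_simulate(
    cohort,
    sample_sizes = 52, mechanisms = "subscale",
    p_sub = p_sub, p_item = p_item,
    methods = c("subscale_mean", "subscale_half_mean"),
    scales = "depression", replicates = replicates,
    seed = seed, out_dir = out_dir
  )
}

#' @describeIn hads_simulate One-row summary of a simulation: number of
#'   cells, replicates, the largest absolute population bias and where it
#'   occurred.
#' @param x A `hads_sim`.
#' @param ... Unused.
#' @method glance hads_sim
#' @export
glance.hads_sim <- function(x, ...) {
  worst <- x[which.max(abs(x$population_bias)), ]
  tibble(
    cells = nrow(dplyr::distinct(as_tibble(x)[c("n", "mechanism", "p_sub", "p_item", "scale")])),
    methods = length(unique(x$method)),
    replicates = attr(x, "config")$replicates,
    max_abs_population_bias = abs(worst$population_bias),
    worst_method = worst$method,
    worst_mechanism = worst$mechanism,
    n_important = sum(x$important_bias, na.rm = TRUE)
  )
}

#' Plot simulation results
#'
#' Population (or individual) bias by handling method, faceted by
#' missingness mechanism, one point per grid cell; the dashed lines mark
#' the +/- 2.1-point minimum important difference.
#'
#' @param object A `hads_sim` from [hads_simulate()].
#' @param metric Result column to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hads_sim
#' @export
autoplot.hads_sim <- function(object, metric = "population_bias", ...) {
  stopifnot(metric %in% names(object))
  d <- as_tibble(object)
  d$rate <- factor(paste0(d$missing_rate, "%"),
                   levels = paste0(sort(unique(d$missing_rate)), "%"))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$method, y = .data[[metric]],
    colour = .data$rate, shape = .data$scale
  )) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_hline(yintercept = c(-2.1, 2.1), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~mechanism) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = metric, colour = "missing rate") +
    ggplot2::theme_minimal()
}
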