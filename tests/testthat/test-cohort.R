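test_that("cronbach_alpha: perfect consistency, independence, degenerate input", {
  x <- matrix(rep(c(0, 1, 2, 3), 5), ncol = 5)
  expect_equal(cronbach_alpha(x), 1.0)

  set.seed(11)
  indep <- matrix(sample(0:3, 20000 * 7, replace = TRUE), ncol = 7)
  expect_lt(abs(cronbach_alpha(indep)), 0.05)

  expect_error(cronbach_alpha(matrix(1, 10, 3)), "zero variance")
  expect_error(cronbach_alpha(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
  expect_error(cronbach_alpha(matrix(1:10, ncol = 1)), "2 items")
})

test_that("cronbach_alpha matches the covariance-matrix formulation", {
  set.seed(12)
  x <- matrix(rnorm(500 * 6), ncol = 6) + rnorm(500)
  v <- stats::cov(x)
  oracle <- ncol(x) / (ncol(x) - 1) * (1 - sum(diag(v)) / sum(v))
  expect_equal(cronbach_alpha(x), oracle, tolerance = 1e-12)
})

test_that("generation is deterministic and respects the item range", {
  spec <- test_spec()
  a <- hads_generate(spec, 500, seed = 7)
  b <- hads_generate(spec, 500, seed = 7)
  expect_identical(a, b)
  x <- hads_item_matrix(a)
  expect_true(all(x %in% 0:3))
  expect_false(anyNA(x))
  expect_true(all(a$age >= 19 & a$age <= 87))
})

test_that("an empty cohort has the full column set and zero rows", {
  empty <- hads_generate(test_spec(), 0)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c(paste0("hads", 1:14), "age", "sex", "qol") %in% names(empty)))
})

test_that("symmetric items: means of 1.5 give thresholds symmetric about 0", {
  # with target mean 1.5 the latent location is the scale midpoint, so the
  # three category cut-points are mirror images; with a near-zero loading the
  # generated mean stays at 1.5 and items are near-independent
  spec <- test_spec()
  spec$items$location <- 1.5
  spec$items$scale <- 1
  spec$items$loading <- 1e-6
  for (k in 1:3) {
    spec$items[[paste0("threshold_", k)]] <- (c(0.5, 1.5, 2.5)[k] - 1.5) / 1
  }
  expect_equal(spec$items$threshold_1, -spec$items$threshold_3)
  expect_equal(spec$items$threshold_2, rep(0, 14))
  cohort <- hads_generate(spec, 50000, seed = 3)
  x <- hads_item_matrix(cohort)
  expect_equal(unname(colMeans(x)), rep(1.5, 14), tolerance = 0.02)
  expect_lt(abs(cronbach_alpha(x)), 0.03)
})

test_that("calibrated generator reproduces the printed descriptives at scale", {
  cohort <- cohort_100k()
  x <- hads_item_matrix(cohort)
  targets <- hads_targets()
  expect_equal(unname(colMeans(x)), unname(targets$item_means), tolerance = 0.05)

  d <- hads_describe(cohort)
  expect_equal(d$scales$mean[1:2], unname(targets$subscale_means), tolerance = 0.15)
  expect_equal(d$scales$alpha, unname(targets$alphas), tolerance = 0.02)
  expect_equal(d$scales$qol_correlation, unname(targets$qol_correlations),
               tolerance = 0.03)
  # verify alpha against a fresh, independently computed value
  v <- stats::cov(x[, hads_items("anxiety")])
  expect_equal(7 / 6 * (1 - sum(diag(v)) / sum(v)), 0.87, tolerance = 0.02)
})

test_that("calibration reports residuals and fails loudly on impossible targets", {
  spec <- test_spec()
  res <- spec$calibration$residuals
  expect_true(all(res$residual <= res$tolerance))
  bad <- hads_targets()
  bad$qol_correlations <- c(anxiety = -0.999, depression = -0.999, distress = -0.999)
  expect_error(
    hads_calibrate(bad, n_calib = 2000, validate_n = 2000),
    "unattainable|singular|residual"
  )
})

test_that("cohort summary handles degenerate and generic inputs", {
  zero <- items_tbl(matrix(0, 20, 14))
  d <- hads_describe(zero)
  expect_equal(d$items$mean, rep(0, 14))
  expect_equal(
    d$bands$proportion[d$bands$band == "0-7"], c(1, 1)
  )
  # band proportions always partition the sample
  d2 <- hads_describe(items_tbl(random_items(200, seed = 4)))
  sums <- tapply(d2$bands$proportion, d2$bands$scale, sum)
  expect_equal(as.numeric(sums), c(1, 1))
})

test_that("bootstrap resampling: determinism, degenerate source, consistency", {
  src <- source_cohort()
  a <- hads_bootstrap(src, 100, seed = 5)
  b <- hads_bootstrap(src, 100, seed = 5)
  expect_identical(a, b)

  one <- src[17, ]
  rep10 <- hads_bootstrap(one, 10, seed = 1)
  expect_identical(nrow(rep10), 10L)
  expect_true(all(vapply(
    paste0("hads", 1:14),
    function(cl) all(rep10[[cl]] == one[[cl]]), TRUE
  )))

  big <- hads_bootstrap(src, 50000, seed = 6)
  src_mean <- mean(rowSums(hads_item_matrix(src)[, hads_items("depression")]))
  boot_mean <- mean(rowSums(hads_item_matrix(big)[, hads_items("depression")]))
  expect_equal(boot_mean, src_mean, tolerance = 0.005 * src_mean)

  expect_error(hads_bootstrap(src, 0), "positive")
})

test_that("spec round-trips through YAML", {
  spec <- test_spec()
  path <- withr::local_tempfile(fileext = ".yml")
  hads_spec_write(spec, path)
  back <- hads_spec_read(path)
  expect_equal(back$items$location, spec$items$location, tolerance = 1e-8)
  expect_equal(back$items$threshold_2, spec$items$threshold_2, tolerance = 1e-8)
  expect_equal(back$latent_corr, spec$latent_corr, tolerance = 1e-8)
  expect_equal(back$qol_noise_sd, spec$qol_noise_sd, tolerance = 1e-8)
  a <- hads_generate(spec, 200, seed = 9)
  b <- hads_generate(back, 200, seed = 9)
  expect_equal(mean(hads_item_matrix(a) == hads_item_matrix(b)), 1)
})
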