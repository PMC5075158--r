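test_that("raw-to-scored orientation reverses the starred items only", {
  raw <- items_tbl(item_row(c(0, 1, 2, 3, 0, 1, 2, 3, 0, 1, 2, 3, 0, 1)))
  oriented <- hads_orient(raw)
  expect_identical(oriented$hads1, 3)   # reverse-coded
  expect_identical(oriented$hads7, 2)   # kept as-is
  expect_identical(oriented$hads6, 2)   # reverse-coded depression item
  expect_identical(hads_item_matrix(hads_orient(oriented)),
                   hads_item_matrix(raw)) # involution
  na_raw <- items_tbl(item_row(c(NA, rep(1, 13))))
  expect_true(is.na(hads_orient(na_raw)$hads1))
  expect_error(hads_orient(items_tbl(item_row(c(4, rep(1, 13))))),
               "subject 1, item 1")
})

test_that("complete scoring sums the subscales", {
  expect_equal(
    unlist(hads_score(items_tbl(item_row(rep(0, 14))))[, 3:5]),
    c(anxiety = 0, depression = 0, distress = 0)
  )
  expect_equal(
    unlist(hads_score(items_tbl(item_row(rep(3, 14))))[, 3:5]),
    c(anxiety = 21, depression = 21, distress = 42)
  )
  expect_equal(
    unlist(hads_score(items_tbl(item_row(rep(1, 14))))[, 3:5]),
    c(anxiety = 7, depression = 14 - 7, distress = 14)
  )
  with_na <- items_tbl(item_row(c(NA, rep(2, 13))))
  expect_error(hads_score(with_na, "complete"), "missing")
})

test_that("subject-mean imputation uses the mean of all observed items", {
  m <- item_row(rep(2, 14)); m[1, 4] <- NA
  done <- hads_impute(items_tbl(m), "subject_mean")
  expect_equal(done$hads4, 2)
  expect_equal(hads_score(items_tbl(m), "subject_mean")$depression, 14)

  # anxiety items all 3, depression observed all 0, one depression missing:
  # the imputed value is the mean of the 13 observed items, 21/13
  m2 <- numeric(14)
  m2[hads_items("anxiety")] <- 3
  m2[hads_items("depression")] <- 0
  m2[4] <- NA
  done2 <- hads_impute(items_tbl(item_row(m2)), "subject_mean")
  expect_equal(done2$hads4, 21 / 13)
  expect_equal(hads_score(items_tbl(item_row(m2)), "subject_mean")$depression,
               21 / 13)

  complete <- items_tbl(random_items(20, seed = 21))
  expect_identical(hads_item_matrix(hads_impute(complete, "subject_mean")),
                   hads_item_matrix(complete))
})

test_that("subscale-mean imputation stays within the item's own subscale", {
  m <- numeric(14)
  m[hads_items("anxiety")] <- 3
  m[hads_items("depression")] <- 1
  m[4] <- NA
  done <- hads_impute(items_tbl(item_row(m)), "subscale_mean")
  expect_equal(done$hads4, 1) # anxiety 3s do not leak in
  expect_equal(hads_score(items_tbl(item_row(m)), "subscale_mean")$depression, 7)

  # observed {0, 3}, five missing: each imputed 1.5, score 7 * 1.5 = 10.5
  m2 <- rep(NA_real_, 14)
  m2[hads_items("anxiety")] <- 2
  m2[2] <- 0; m2[4] <- 3
  expect_equal(hads_score(items_tbl(item_row(m2)), "subscale_mean")$depression, 10.5)
})

test_that("subscale-mean scores equal 7 x mean of observed items (oracle)", {
  for (seed in 1:6) {
    m <- random_items(30, seed = 100 + seed)
    set.seed(seed)
    m[matrix(runif(length(m)) < 0.3, nrow(m))] <- NA
    got <- hads_score(items_tbl(m), "subscale_mean")
    oracle <- brute_subscale_scores(m)
    expect_equal(got$anxiety, oracle[, 1])
    expect_equal(got$depression, oracle[, 2])
    expect_equal(got$distress, oracle[, 3])
  }
})

test_that("the half-rule scores at four observed items and not at three", {
  m4 <- rep(2, 14); m4[c(2, 4, 6)] <- NA # 4 of 7 depression observed
  s4 <- hads_score(items_tbl(item_row(m4)), "subscale_half_mean")
  expect_equal(s4$depression, 14)
  expect_equal(s4$distress, 28) # both subscales pass

  m3 <- rep(2, 14); m3[c(2, 4, 6, 8)] <- NA # 3 of 7 observed
  s3 <- hads_score(items_tbl(item_row(m3)), "subscale_half_mean")
  expect_true(is.na(s3$depression))
  expect_true(is.na(s3$distress)) # distress needs both subscales
  expect_equal(s3$anxiety, 14)

  many <- random_items(20, seed = 28)
  many[1, ] <- m3 # only subject 1 fails the rule
  s_mi <- hads_score(items_tbl(many), "mi_half", seed = 1)
  expect_true(is.na(s_mi$depression[1]))
  expect_false(anyNA(s_mi$depression[-1]))
})

test_that("item-mean imputation averages within the current sample", {
  m <- matrix(1, 3, 14)
  m[1, 4] <- 0; m[2, 4] <- 2; m[3, 4] <- NA
  done <- hads_impute(items_tbl(m), "item_mean")
  expect_equal(done$hads4[3], 1)
  all_gone <- matrix(1, 3, 14); all_gone[, 4] <- NA
  expect_error(hads_impute(items_tbl(all_gone), "item_mean"), "every subject")
})

test_that("chained-equations MI: identity, truncation, determinism", {
  complete <- items_tbl(random_items(40, seed = 22))
  expect_equal(hads_item_matrix(hads_impute(complete, "mi", seed = 1)),
               hads_item_matrix(complete))

  m <- random_items(52, seed = 23)
  set.seed(24)
  m[matrix(runif(length(m)) < 0.2, nrow(m))] <- NA
  a <- hads_impute(items_tbl(m), "mi", seed = 9)
  b <- hads_impute(items_tbl(m), "mi", seed = 9)
  expect_identical(a, b)
  xa <- hads_item_matrix(a)
  expect_true(all(xa >= 0 & xa <= 3))
  expect_equal(xa[!is.na(m)], as.numeric(m[!is.na(m)])) # observed cells untouched
})

test_that("complete-case scoring excludes per analyzed scale", {
  complete <- items_tbl(random_items(10, seed = 25))
  cc <- hads_score(complete, "complete_case")
  expect_equal(cc[3:5], hads_score(complete, "complete")[3:5])

  m <- random_items(10, seed = 26)
  m[1, 1] <- NA # anxiety item missing only
  s <- hads_score(items_tbl(m), "complete_case")
  expect_true(is.na(s$anxiety[1]))
  expect_false(is.na(s$depression[1])) # still contributes a depression score
  expect_true(is.na(s$distress[1]))
})

test_that("all methods preserve observed data and stay within score ranges", {
  for (seed in 1:3) {
    m <- random_items(52, seed = 200 + seed)
    set.seed(seed)
    m[matrix(runif(length(m)) < 0.25, nrow(m))] <- NA
    for (meth in hads_methods()) {
      s <- hads_score(items_tbl(m), meth, seed = seed)
      expect_true(all(s$anxiety >= 0 & s$anxiety <= 21, na.rm = TRUE))
      expect_true(all(s$depression >= 0 & s$depression <= 21, na.rm = TRUE))
      expect_true(all(s$distress >= 0 & s$distress <= 42, na.rm = TRUE))
      both <- !is.na(s$anxiety) & !is.na(s$depression) & !is.na(s$distress)
      expect_equal(s$distress[both], s$anxiety[both] + s$depression[both])
    }
  }
})

test_that("subjects with nothing to impute from are left unscored", {
  m <- random_items(5, seed = 27)
  m[2, ] <- NA
  s <- hads_score(items_tbl(m), "subject_mean")
  expect_true(all(is.na(unlist(s[2, 3:5]))))
  m[3, hads_items("depression")] <- NA
  s2 <- hads_score(items_tbl(m), "subscale_mean")
  expect_true(is.na(s2$depression[3]))
  expect_false(is.na(s2$anxiety[3]))
})
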