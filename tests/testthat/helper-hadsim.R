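# shared fixtures, built in code and cached for the test session

.fixtures <- new.env(parent = emptyenv())

# the reference calibrated spec (cached by the package per session)
test_spec <- function() hads_default_spec()

# large cohort for descriptive checks
cohort_100k <- function() {
  if (is.null(.fixtures$c100k)) {
    .fixtures$c100k <- hads_generate(test_spec(), 100000, seed = 42)
  }
  .fixtures$c100k
}

# moderate cohort standing in for the bootstrap source population
source_cohort <- function() {
  if (is.null(.fixtures$src)) {
    .fixtures$src <- hads_generate(test_spec(), 20000, seed = 42)
  }
  .fixtures$src
}

# build an item tibble from a 14-column matrix (values 0..3 or NA)
items_tbl <- function(m) {
  m <- matrix(m, ncol = 14)
  out <- tibble::tibble(subject_id = seq_len(nrow(m)))
  for (j in 1:14) out[[paste0("hads", j)]] <- m[, j]
  out
}

# a row of 14 item values
item_row <- function(values) matrix(values, nrow = 1)

# random complete small item matrices for property checks
random_items <- function(n, seed) {
  set.seed(seed)
  matrix(sample(0:3, n * 14, replace = TRUE), n, 14)
}

# independent oracle: subscale-mean scoring computed subject-by-subject as
# 7 x mean of the observed subscale items
brute_subscale_scores <- function(m) {
  anx <- c(1, 3, 5, 7, 9, 11, 13)
  dep <- c(2, 4, 6, 8, 10, 12, 14)
  t(apply(m, 1, function(r) {
    s <- vapply(list(anx, dep), function(idx) {
      obs <- r[idx][!is.na(r[idx])]
      if (length(obs) == 0) NA_real_ else 7 * mean(obs)
    }, 0)
    c(s, s[1] + s[2])
  }))
}
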