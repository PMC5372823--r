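test_that("median filter removes depths above factor x median", {
  ids <- paste0("s", 1:4)
  cov <- make_cov(d1 = setNames(c(10, 10, 10, 100), ids))
  b <- bin("b", ids)
  res <- median_outlier_filter(b, cov)
  expect_equal(res$medians, c(d1 = 10))
  expect_equal(res$removed, "s4")
  expect_setequal(res$kept$members, c("s1", "s2", "s3"))
  # uniform coverage: identity
  cov2 <- make_cov(d1 = setNames(rep(7, 4), ids))
  expect_length(median_outlier_filter(b, cov2)$removed, 0)
})

test_that("median filter OR/AND semantics across two datasets", {
  ids <- paste0("s", 1:6)
  # s5 exceeds only in B; s6 exceeds in both
  cov <- make_cov(A = setNames(c(10, 10, 10, 12, 11, 90), ids),
                  B = setNames(c(20, 20, 20, 22, 95, 99), ids))
  b <- bin("b", ids)
  res_or <- median_outlier_filter(b, cov)
  expect_setequal(res_or$removed, c("s5", "s6"))
  res_and <- median_outlier_filter(b, cov, all_datasets = TRUE)
  expect_equal(res_and$removed, "s6")
  # exhaustive per-scaffold oracle
  expect_setequal(res_or$removed, oracle_median_filter(ids, unclass(cov)))
})

test_that("median filter matches the brute-force oracle on random bins", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    ids <- sprintf("s%03d", seq_len(n))
    cov <- make_cov(A = setNames(rlnorm(n, 3, 0.8), ids),
                    B = setNames(rlnorm(n, 2, 1.0), ids))
    res <- median_outlier_filter(bin("b", ids), cov)
    expect_setequal(res$removed, oracle_median_filter(ids, unclass(cov)))
    expect_setequal(c(res$kept$members, res$removed), ids)
  }
})

test_that("zero-median datasets are skipped with a warning", {
  ids <- paste0("s", 1:5)
  cov <- make_cov(A = setNames(c(10, 10, 10, 10, 50), ids),
                  B = setNames(c(0, 0, 0, 2, 3), ids))
  expect_warning(res <- median_outlier_filter(bin("b", ids), cov), "zero")
  expect_equal(res$removed, "s5")  # B never drives removals
})

test_that("inverse-profile split separates two coverage-anticorrelated halves", {
  set.seed(5)
  ids <- sprintf("s%02d", 1:20)
  # 10 members high in A (r ~ +3), 10 high in B (r ~ -3)
  a <- c(rlnorm(10, log(80), 0.1), rlnorm(10, log(10), 0.1))
  bdep <- c(rlnorm(10, log(10), 0.1), rlnorm(10, log(80), 0.1))
  cov <- make_cov(A = setNames(a, ids), B = setNames(bdep, ids))
  res <- split_inverse_profiles(bin("mix", ids), cov, "A", "B")
  expect_true(res$was_split)
  expect_gte(res$split_statistic, 2)
  expect_equal(sort(lengths(lapply(res$sub_bins, `[[`, "members"))),
               c(10L, 10L))
  # union of sub-bins equals the parent
  expect_setequal(unlist(lapply(res$sub_bins, `[[`, "members")), ids)
  # the split respects provenance
  expect_setequal(res$sub_bins[[2]]$members, ids[1:10])
})

test_that("split requires an inverse (opposite-sign) profile, not just a gap", {
  set.seed(6)
  ids <- sprintf("s%02d", 1:20)
  # both halves more abundant in A: same sign, gap ~3
  a <- c(rlnorm(10, log(20), 0.05), rlnorm(10, log(160), 0.05))
  bdep <- rlnorm(20, log(10), 0.05)
  cov <- make_cov(A = setNames(a, ids), B = setNames(bdep, ids))
  res <- split_inverse_profiles(bin("b", ids), cov, "A", "B")
  expect_false(res$was_split)
  expect_length(res$sub_bins, 1)
  expect_equal(res$sub_bins[[1]]$members, ids)

  # flat profiles: no split either
  cov2 <- make_cov(A = setNames(rep(30, 20), ids),
                   B = setNames(rep(30, 20), ids))
  expect_false(split_inverse_profiles(bin("b", ids), cov2, "A", "B")$was_split)

  # too small to split
  small <- bin("b", ids[1:8])
  expect_false(split_inverse_profiles(small, cov, "A", "B")$was_split)
})

test_that("z-score purification removes a planted differential outlier", {
  ids <- c(sprintf("s%02d", 1:20), "bad")
  a <- setNames(c(rep(10, 20), 100), ids)
  bdep <- setNames(c(rep(10, 20), 10), ids)
  # hand-computed on the 21-member set: only 'bad' deviates in A
  cov <- make_cov(A = a, B = bdep)
  res <- zscore_purify(bin("b", ids), cov, "A", "B")
  expect_equal(res$removed, "bad")
  expect_length(res$kept$members, 20)

  # identical profiles: identity, nothing removed
  cov2 <- make_cov(A = setNames(rlnorm(21, 3, 0.5), ids),
                   B = setNames(numeric(21), ids))
  cov2 <- make_cov(A = unclass(cov2)[, "A"], B = unclass(cov2)[, "A"])
  res2 <- zscore_purify(bin("b", ids), cov2, "A", "B")
  expect_length(res2$removed, 0)
})

test_that("purification matches the naive recompute-after-each-removal oracle", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    ids <- sprintf("s%03d", seq_len(n))
    base <- rlnorm(n, 3, 0.4)
    a <- base * rlnorm(n, 0, 0.1)
    bdep <- base * rlnorm(n, 0, 0.1)
    # plant a few strong differential outliers
    k <- sample(0:3, 1)
    if (k > 0) {
      idx <- sample(n, k)
      a[idx] <- a[idx] * sample(c(8, 1 / 8), k, replace = TRUE)
    }
    cov <- make_cov(A = setNames(a, ids), B = setNames(bdep, ids))
    res <- zscore_purify(bin("b", ids), cov, "A", "B")
    orc <- oracle_zscore_purify(ids, unclass(cov))
    expect_identical(res$removed, orc$removed)
    expect_identical(sort(res$kept$members), orc$kept)
  }
})

test_that("purification terminates with all |z_A - z_B| <= end cutoff", {
  set.seed(88)
  n <- 60
  ids <- sprintf("s%03d", 1:n)
  a <- rlnorm(n, 3, 0.6); bdep <- rlnorm(n, 3, 0.6)
  cov <- make_cov(A = setNames(a, ids), B = setNames(bdep, ids))
  res <- zscore_purify(bin("b", ids), cov, "A", "B")
  expect_true(all(abs(res$z$z_a - res$z$z_b) <= 2))
  # partition and idempotence
  expect_setequal(c(res$kept$members, res$removed), ids)
  again <- zscore_purify(res$kept, cov, "A", "B")
  expect_length(again$removed, 0)
})

test_that("lowering the end cutoff never keeps more scaffolds", {
  set.seed(99)
  n <- 50
  ids <- sprintf("s%03d", 1:n)
  cov <- make_cov(A = setNames(rlnorm(n, 3, 0.5), ids),
                  B = setNames(rlnorm(n, 3, 0.5), ids))
  kept3 <- zscore_purify(bin("b", ids), cov, "A", "B",
                         start_cutoff = 4, end_cutoff = 3)$kept$members
  kept2 <- zscore_purify(bin("b", ids), cov, "A", "B",
                         start_cutoff = 4, end_cutoff = 2)$kept$members
  expect_lte(length(kept2), length(kept3))
  expect_true(all(kept2 %in% kept3))
})

test_that("results are independent of member ordering", {
  set.seed(33)
  n <- 30
  ids <- sprintf("s%03d", 1:n)
  cov <- make_cov(A = setNames(rlnorm(n, 3, 0.7), ids),
                  B = setNames(rlnorm(n, 3, 0.7), ids))
  r1 <- zscore_purify(bin("b", ids), cov, "A", "B")
  r2 <- zscore_purify(bin("b", rev(ids)), cov, "A", "B")
  expect_identical(r1$removed, r2$removed)
  m1 <- median_outlier_filter(bin("b", ids), cov)
  m2 <- median_outlier_filter(bin("b", rev(ids)), cov)
  expect_setequal(m1$removed, m2$removed)
})

test_that("min_members guard stops purification and is flagged", {
  ids <- paste0("s", 1:4)
  cov <- make_cov(A = setNames(c(1, 2, 100, 200), ids),
                  B = setNames(c(200, 100, 2, 1), ids))
  res <- zscore_purify(bin("b", ids), cov, "A", "B", min_members = 4)
  expect_length(res$removed, 0)
  expect_true("min_members" %in% res$flags ||
                any(res$trace$action == "flag"))
})

test_that("zero variance in a dataset drives no removals and is flagged", {
  ids <- paste0("s", 1:10)
  cov <- make_cov(A = setNames(rep(5, 10), ids),
                  B = setNames(rep(9, 10), ids))
  res <- zscore_purify(bin("b", ids), cov, "A", "B")
  expect_length(res$removed, 0)
  expect_true("zero_variance" %in% res$flags)
})

test_that("batch mode removes all offenders per round but still terminates", {
  set.seed(44)
  n <- 40
  ids <- sprintf("s%03d", 1:n)
  base <- rlnorm(n, 3, 0.3)
  a <- base; bdep <- base
  a[1:3] <- a[1:3] * 10
  cov <- make_cov(A = setNames(a, ids), B = setNames(bdep, ids))
  res <- zscore_purify(bin("b", ids), cov, "A", "B", batch = TRUE)
  expect_true(all(ids[1:3] %in% res$removed))
  expect_true(all(abs(res$z$z_a - res$z$z_b) <= 2))
})
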