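# Frequency tables, the M statistic, and the statistical tests.

test_that("frequency_table counts resolved calls per group", {
  calls <- tibble::tibble(
    specimen_id = paste0("S", 1:5), segment = "sCOIB",
    bases = NA_character_,
    haplotype = c("A", "A", "B", "C", NA),
    status = c(rep("resolved", 4), "missing"))
  meta <- tibble::tibble(specimen_id = paste0("S", 1:5),
                         collection_id = "X", state = "MS", year = 2019L)
  ft <- suppressMessages(frequency_table(calls, meta, "collection_id"))
  expect_equal(ft$n[match(c("A", "B", "C"), ft$haplotype)], c(2L, 1L, 1L))
  expect_true(all(ft$n_resolved == 4L))
  expect_equal(sum(ft$frequency), 1)
})

test_that("empirical group frequencies track generator truth", {
  set.seed(31)
  p <- 0.7
  labels <- ifelse(runif(1000) < p, "C1035/T1272", "T1035/C1272")
  calls <- tibble::tibble(specimen_id = sprintf("S%04d", 1:1000),
                          segment = "sCOIB", bases = NA_character_,
                          haplotype = labels, status = "resolved")
  meta <- tibble::tibble(specimen_id = calls$specimen_id,
                         collection_id = "X", state = "MS", year = 2019L)
  ft <- frequency_table(calls, meta, "collection_id")
  fhat <- ft$frequency[ft$haplotype == "C1035/T1272"]
  expect_lt(abs(fhat - p), 2.576 * sqrt(p * (1 - p) / 1000)) # 99% CI
})

test_that("M evaluates the haplotype-ratio formula with its symmetries", {
  expect_equal(m_statistic(71, 26), 45 / 97, tolerance = 1e-12)
  expect_equal(m_statistic(5, 5), 0)
  expect_equal(m_statistic(7, 0), 1)
  expect_error(m_statistic(0, 0), "undefined")
  set.seed(41)
  for (r in 1:50) {
    a <- sample(0:60, 1); b <- sample(0:60, 1)
    if (a + b == 0) next
    m <- m_statistic(a, b)
    expect_true(m >= -1 && m <= 1)
    expect_equal(m, -m_statistic(b, a))
    k <- sample(1:9, 1)
    expect_equal(m, m_statistic(k * a, k * b)) # scale invariance
  }
})

test_that("chi-square against uniform matches the textbook formula", {
  r0 <- chi_square_uniform(c(25, 25, 25, 25))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$df, 3)
  r1 <- chi_square_uniform(c(10, 0))
  expect_equal(r1$statistic, 10) # (10-5)^2/5 * 2
  expect_equal(r1$df, 1)
  set.seed(51)
  for (r in 1:50) {
    x <- sample(0:200, sample(2:8, 1), replace = TRUE)
    if (sum(x) == 0) next
    got <- chi_square_uniform(x)
    o <- oracle_chisq_uniform(x)
    expect_equal(got$statistic, o$stat, tolerance = 1e-10)
    expect_equal(got$df, o$df)
    expect_equal(got$p_value, o$p, tolerance = 1e-10)
  }
})

test_that("pooled and Welch t-tests match independent formulas", {
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(r$statistic, 3), -3.674)
  expect_equal(r$df, 4)

  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(61)
  for (r in 1:50) {
    a <- rnorm(sample(3:15, 1)); b <- rnorm(sample(3:15, 1), mean = 0.5)
    got_p <- two_sample_t(a, b, "pooled"); o_p <- oracle_pooled_t(a, b)
    expect_equal(got_p$statistic, o_p$t, tolerance = 1e-10)
    expect_equal(got_p$df, o_p$df)
    expect_equal(got_p$p_value, o_p$p, tolerance = 1e-10)
    got_w <- two_sample_t(a, b, "welch"); o_w <- oracle_welch_t(a, b)
    expect_equal(got_w$statistic, o_w$t, tolerance = 1e-10)
    expect_equal(got_w$df, o_w$df, tolerance = 1e-8)
    expect_equal(got_w$p_value, o_w$p, tolerance = 1e-10)
  }
})

test_that("the pooled t p-value agrees with a permutation test", {
  set.seed(71)
  a <- rnorm(8); b <- rnorm(8, mean = 1)
  p_t <- two_sample_t(a, b)$p_value
  pool <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  perm <- replicate(4000, {
    i <- sample(16, 8)
    abs(mean(pool[i]) - mean(pool[-i]))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(p_t - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 4000) + 0.02)
})

test_that("one-way ANOVA matches the sum-of-squares decomposition", {
  expect_error(one_way_anova(list(rep(1, 4), rep(1, 4))), "zero within")
  set.seed(81)
  for (r in 1:40) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(sample(3:12, 1), i / 4))
    got <- one_way_anova(groups)
    o <- oracle_anova(groups)
    expect_equal(got$statistic, o$f, tolerance = 1e-10)
    expect_equal(got$df, o$df)
    expect_equal(got$p_value, o$p, tolerance = 1e-10)
    expect_equal(got$r_squared, o$r2, tolerance = 1e-10)
  }
  # two groups: F = t^2 of the pooled t-test
  a <- rnorm(9); b <- rnorm(7, 0.3)
  expect_equal(one_way_anova(list(a, b))$statistic,
               two_sample_t(a, b)$statistic^2, tolerance = 1e-10)
})

test_that("Tukey HSD pairwise p-values match the studentized range", {
  set.seed(91)
  for (r in 1:15) {
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(sample(4:10, 1), i / 3))
    names(groups) <- paste0("G", seq_len(k))
    got <- tukey_hsd(groups)
    expect_equal(nrow(got$pairs), k * (k - 1) / 2)
    o <- sort(oracle_tukey_p(groups))
    expect_equal(sort(got$pairs$p_adj), o, tolerance = 1e-8)
  }
})

test_that("the compact letter display separates clear groups", {
  set.seed(101)
  lo <- rnorm(20, 0, 0.1); hi <- rnorm(20, 10, 0.1)
  tk <- tukey_hsd(list(low = lo, high = hi))
  expect_false(tk$letters[["low"]] == tk$letters[["high"]])

  mid <- rnorm(20, 5, 0.1)
  tk3 <- tukey_hsd(list(low = lo, mid = mid, high = hi))
  expect_equal(length(unique(tk3$letters)), 3L)

  # three overlapping groups share a letter
  tk_same <- tukey_hsd(list(a = rnorm(30), b = rnorm(30), c = rnorm(30)))
  if (all(tk_same$pairs$p_adj >= 0.05)) {
    expect_true(length(unique(unlist(strsplit(tk_same$letters, "")))) == 1L)
  }
})

test_that("identical-distribution groups share a letter ~95% of the time", {
  set.seed(111)
  hits <- vapply(1:200, function(r) {
    tk <- tukey_hsd(list(a = rnorm(40), b = rnorm(40), c = rnorm(40)))
    length(unique(tk$letters)) == 1L
  }, TRUE)
  expect_gt(mean(hits), 0.88) # ~= 1 - alpha, with Monte Carlo slack
  expect_lt(mean(hits), 1 + 1e-9)
})

test_that("regional comparison maps states and validates coverage", {
  set.seed(121)
  m_tbl <- tibble::tibble(
    state = c("FL", "GA", "SC", "TX", "LA", "MS", "PR"),
    count_a = 50L, count_b = 20L,
    m = c(rnorm(3, 0.5, 0.05), rnorm(3, -0.3, 0.05), 0))
  res <- regional_compare(m_tbl, region_scheme_east_west())
  expect_s3_class(res, "hm_htest")
  expect_equal(sum(res$groups$n), 6L) # PR excluded
  expect_lt(res$p_value, 0.01)

  bad <- dplyr::bind_rows(m_tbl,
                          tibble::tibble(state = "ZZ", count_a = 1L,
                                         count_b = 1L, m = 0))
  expect_error(regional_compare(bad, region_scheme_east_west()), "ZZ")

  pr_only <- m_tbl[m_tbl$state == "PR", ]
  expect_error(regional_compare(pr_only, region_scheme_east_west()),
               "excluded")
})

test_that("tidy and glance return one-row tibbles for test results", {
  r <- two_sample_t(rnorm(5), rnorm(5))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_true(all(c("statistic", "df", "p_value") %in% names(td)))
  expect_equal(glance(r), td)
})
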