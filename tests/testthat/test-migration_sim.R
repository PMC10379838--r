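# Founder-effect simulator: sampling stages, conservation, determinism,
# and the synthetic cohort generator.

test_that("founder sampling is a seeded multinomial draw", {
  src <- default_source()
  f1 <- sample_founders(src, 1, seed = 5)
  expect_equal(sum(f1), 1L)
  expect_equal(sum(f1 == 1L), 1L) # unit vector

  expect_identical(sample_founders(src, 200, seed = 7),
                   sample_founders(src, 200, seed = 7))

  big <- sample_founders(src, 1e6, seed = 9)
  expect_true(all(abs(big / 1e6 - src$coib_freqs) < 0.002))
})

test_that("expansion absorbs fixed founder groups and respects modes", {
  src <- default_source()
  sc <- migration_scenario(src, n_founders = 5, n_sampled = 50, seed = 1)
  fixed <- setNames(c(5L, 0L, 0L, 0L), names(src$coib_freqs))
  out <- expand_and_sample(fixed, sc)
  expect_equal(unname(out), c(50L, 0L, 0L, 0L)) # absorption
  expect_error(expand_and_sample(fixed * 0L, sc), "empty")

  # Wright-Fisher at N = 1e6 converges to exact_frequencies: the focal
  # count variance over replicates matches the single-stage multinomial
  founders <- setNames(c(68L, 27L, 4L, 1L), names(src$coib_freqs))
  sc_wf <- migration_scenario(src, n_founders = 100, n_sampled = 100,
                              expansion = list(mode = "wright_fisher",
                                               gens = 3, N = 1e6),
                              seed = 1)
  set.seed(2)
  x_wf <- replicate(2000, expand_and_sample(founders, sc_wf)[1])
  v_exact <- 100 * 0.68 * (1 - 0.68)
  expect_equal(mean(x_wf), 68, tolerance = 0.02)
  expect_lt(abs(var(x_wf) / v_exact - 1), 0.15)
})

test_that("vectorised replicate destinations match the two-stage oracle", {
  src <- default_source()
  set.seed(3)
  R <- 4000
  mat <- replicate_destinations(src, n_founders = 30, n_sampled = 60,
                                replicates = R)
  expect_equal(dim(mat), c(R, 4L))
  expect_true(all(rowSums(mat) == 60))

  # direct Monte Carlo through the scalar two-stage path
  sc <- migration_scenario(src, n_founders = 30, n_sampled = 60, seed = 1)
  set.seed(4)
  direct <- replicate(R, {
    expand_and_sample(sample_founders(src, 30), sc)[1]
  })
  f_vec <- mat[, 1] / 60
  f_dir <- direct / 60
  expect_equal(mean(f_vec), mean(f_dir), tolerance = 0.01)
  se_ratio <- sqrt(2 / R) * 2 # ~2 sd slack on a variance ratio
  expect_lt(abs(var(f_vec) / var(f_dir) - 1), 3 * se_ratio)
})

test_that("destination frequencies are conserved in expectation", {
  src <- default_source()
  set.seed(5)
  R <- 4000
  for (nf in c(10, 200)) {
    mat <- replicate_destinations(src, nf, n_sampled = 80, replicates = R)
    f <- mat[, 1] / 80
    se <- sd(f) / sqrt(R)
    expect_lt(abs(mean(f) - src$coib_freqs[[1]]), 3 * se + 1e-3)
  }
})

test_that("cohort synthesis is seed-deterministic end to end", {
  src <- source_population(singleton_rate = 0.002)
  sc <- migration_scenario(src, n_founders = 20, n_destinations = 3,
                           n_sampled = 15, seed = 77)
  r1 <- synthesize_cohort(sc, n_source_collections = 2)
  r2 <- synthesize_cohort(sc, n_source_collections = 2)
  expect_identical(r1$specimens$sequences, r2$specimens$sequences)
  expect_identical(r1$truth, r2$truth)
  expect_identical(r1$counts, r2$counts)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  synthesize_cohort(sc, out_dir = d1, n_source_collections = 2)
  synthesize_cohort(sc, out_dir = d2, n_source_collections = 2)
  for (f in c("specimens.fasta", "metadata.csv", "truth.csv",
              "true_counts.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("generator truth matches its own count table", {
  sc <- migration_scenario(default_source(), n_founders = 25,
                           n_destinations = 4, n_sampled = 30, seed = 13)
  res <- synthesize_cohort(sc, n_source_collections = 0)
  per_truth <- dplyr::count(res$truth, collection_id, coib_haplotype)
  per_counts <- res$counts[res$counts$n > 0, ]
  merged <- dplyr::left_join(
    per_counts, per_truth,
    by = c(collection_id = "collection_id", haplotype = "coib_haplotype"))
  expect_equal(merged$n.x, merged$n.y)
})

test_that("power analysis validates inputs and is reproducible", {
  src <- default_source()
  expect_error(run_power_analysis(src, 50, replicates = 10), ">= 100")
  g1 <- run_power_analysis(src, c(5, 500), replicates = 100,
                           n_collections = 5, n_sampled = 50,
                           m_sd_replicates = 500, seed = 3)
  g2 <- run_power_analysis(src, c(5, 500), replicates = 100,
                           n_collections = 5, n_sampled = 50,
                           m_sd_replicates = 500, seed = 3)
  expect_identical(g1, g2)
  expect_s3_class(g1, "hm_power_grid")
  # founder drift at size 5 inflates destination M spread
  expect_gt(g1$m_sd[g1$founder_size == 5],
            g1$m_sd[g1$founder_size == 500])
})
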