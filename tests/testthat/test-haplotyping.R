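# SNP discovery, marker selection, haplotype calling, Tpi genotyping.

test_that("discover_snps computes per-specimen minor frequencies", {
  labels <- c(rep("C1035/T1272", 67), rep("T1035/T1272", 33))
  spx <- make_mito_cohort(labels)
  sites <- discover_snps(spx, "sCOIB", REFS$sCOIB)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$position, 1035L)
  expect_equal(sites$minor_frequency, 0.33)
  expect_equal(sites$major, "C")
  expect_equal(sites$minor, "T")
  expect_false(sites$singleton)

  # monomorphic cohort: no sites
  spx0 <- make_mito_cohort(rep("C1035/T1272", 10))
  expect_equal(nrow(discover_snps(spx0, "sCOIB", REFS$sCOIB)), 0L)
})

test_that("a variant seen once is a singleton at frequency 1/n", {
  spx <- make_mito_cohort(rep("C1035/T1272", 50))
  # plant a private G at a non-marker position of specimen 7
  i <- which(spx$sequences$specimen_id == "SP007")
  alt <- setdiff(c("A", "C", "G", "T"),
                 substr(REFS$sCOIB$sequence, 10, 10))[1]
  spx$sequences$sequence[i] <- set_base_at(spx$sequences$sequence[i], 10, alt)
  sites <- discover_snps(spx, "sCOIB", REFS$sCOIB)
  expect_equal(nrow(sites), 1L)
  expect_true(sites$singleton)
  expect_equal(sites$minor_frequency, 0.02)
  # singletons are never selectable, whatever the threshold
  expect_equal(nrow(select_marker_sites(sites, threshold = 0.01)), 0L)
})

test_that("discovery is order-invariant and matches a direct tally", {
  set.seed(5)
  labels <- sample(c("C1035/T1272", "T1035/C1272", "T1035/T1272"), 80,
                   replace = TRUE, prob = c(0.6, 0.3, 0.1))
  spx <- make_mito_cohort(labels)
  sites <- discover_snps(spx, "sCOIB", REFS$sCOIB)

  # brute-force per-position tally straight off the label vector
  t1035 <- mean(substr(labels, 1, 1) == "T")
  c1272 <- mean(vapply(strsplit(labels, "/"), function(x)
    substr(x[2], 1, 1), "") == "C")
  expect_equal(sites$minor_frequency[sites$position == 1035],
               min(t1035, 1 - t1035))
  expect_equal(sites$minor_frequency[sites$position == 1272],
               min(c1272, 1 - c1272))

  # permuting specimen rows changes nothing
  spx2 <- spx
  set.seed(6)
  spx2$sequences <- spx2$sequences[sample(nrow(spx2$sequences)), ]
  expect_equal(discover_snps(spx2, "sCOIB", REFS$sCOIB), sites)

  # lowercase input gives identical calls
  spx3 <- spx
  spx3$sequences$sequence <- tolower(spx3$sequences$sequence)
  expect_equal(discover_snps(spx3, "sCOIB", REFS$sCOIB), sites)
})

test_that("marker selection is a strict >threshold filter", {
  sites <- tibble::tibble(
    segment = "sCOIB", position = c(1035L, 1272L, 1100L, 1200L, 1300L),
    major = "C", minor = "T", minor_count = c(33L, 32L, 2L, 10L, 11L),
    n_scored = 100L,
    minor_frequency = c(0.33, 0.32, 0.02, 0.100, 0.101),
    singleton = FALSE)
  sel <- select_marker_sites(sites, threshold = 0.10)
  expect_setequal(sel$position, c(1035L, 1272L, 1300L))
  expect_false(1200L %in% sel$position)  # exactly 0.10 is excluded
  expect_equal(nrow(select_marker_sites(sites[0, ], 0.10)), 0L)
  expect_error(select_marker_sites(sites, threshold = 0.6), "threshold")
})

test_that("haplotype calls label marker bases and flag ambiguity", {
  spx <- make_mito_cohort(c("C1035/T1272", "T1035/C1272"))
  sites <- tibble::tibble(segment = "sCOIB",
                          position = c(1035L, 1272L),
                          major = c("C", "T"), minor = c("T", "C"),
                          minor_count = 1L, n_scored = 2L,
                          minor_frequency = 0.5, singleton = FALSE)
  calls <- call_haplotypes(spx, "sCOIB", sites, REFS$sCOIB)
  expect_equal(calls$haplotype, c("C1035/T1272", "T1035/C1272"))
  expect_true(all(calls$status == "resolved"))

  # Y at a marker site invalidates the whole segment call
  i <- 1L
  spx$sequences$sequence[i] <- set_base_at(spx$sequences$sequence[i],
                                           1035 - REFS$sCOIB$offset + 1, "Y")
  calls2 <- call_haplotypes(spx, "sCOIB", sites, REFS$sCOIB)
  expect_equal(calls2$status[1], "unresolved_ambiguity")
  expect_true(is.na(calls2$haplotype[1]))

  # marker site outside the segment span is rejected
  bad <- sites; bad$position[2] <- 5000L
  expect_error(call_haplotypes(spx, "sCOIB", bad, REFS$sCOIB), "span")
})

test_that("i65 genotyping distinguishes del, plus and het reads", {
  al <- tpi140_alleles()
  spx <- make_specimens(tibble::tibble(
    specimen_id = c("SPdel", "SPplus", "SPhet"),
    segment = "sTpi140", allele = 1L,
    sequence = c(al$del, al$plus, al$het)),
    meta = tibble::tibble(
      specimen_id = c("SPdel", "SPplus", "SPhet"),
      collection_id = "MS-T01", state = "MS", year = 2019L,
      source_type = "field_larva", sex_ploidy = "ZZ_male"))
  g <- call_tpi(spx, REFS)
  expect_equal(setNames(g$i65_status, g$specimen_id),
               c(SPdel = "del", SPhet = "het", SPplus = "plus"))
})

test_that("phased two-allele males genotype from both alleles", {
  al <- tpi140_alleles()
  spx <- make_specimens(tibble::tibble(
    specimen_id = c("SPa", "SPa", "SPb", "SPb"),
    segment = "sTpi140", allele = c(1L, 2L, 1L, 2L),
    sequence = c(al$plus, al$del, al$del, al$del)),
    meta = tibble::tibble(
      specimen_id = c("SPa", "SPb"), collection_id = "MS-T01",
      state = "MS", year = 2019L, source_type = "field_larva",
      sex_ploidy = "ZZ_male"))
  g <- call_tpi(spx, REFS)
  expect_equal(setNames(g$i65_status, g$specimen_id),
               c(SPa = "het", SPb = "del"))
})

test_that("a heterozygous signal on a hemizygous female is rejected", {
  al <- tpi140_alleles()
  spx <- make_specimens(
    tibble::tibble(specimen_id = "SPf", segment = "sTpi140", allele = 1L,
                   sequence = al$het),
    meta = tibble::tibble(
      specimen_id = "SPf", collection_id = "MS-T01", state = "MS",
      year = 2019L, source_type = "field_larva",
      sex_ploidy = "Z_hemizygous_female"))
  expect_warning(g <- call_tpi(spx, REFS), "female")
  expect_equal(g$i65_status, "unknown")
})

test_that("per-specimen Tpi allele frequency weights hets by mode", {
  mk <- function(status) tibble::tibble(
    specimen_id = sprintf("S%d", seq_along(status)), i65_status = status)
  g1 <- mk(c(rep("del", 10), rep("plus", 90)))
  expect_equal(tpi_allele_frequency(g1, "half_weight")$frequency, 0.10)
  expect_equal(tpi_allele_frequency(g1, "carrier")$frequency, 0.10)

  g2 <- mk(c(rep("het", 4), rep("plus", 4)))
  expect_equal(tpi_allele_frequency(g2, "half_weight")$frequency, 0.25)
  expect_equal(tpi_allele_frequency(g2, "carrier")$frequency, 0.5)

  # random vectors match an independent weighted tally, unknowns excluded
  set.seed(12)
  for (r in 1:20) {
    st <- sample(c("del", "het", "plus", "unknown"), 60, replace = TRUE)
    g <- mk(st)
    known <- st[st != "unknown"]
    expect_equal(tpi_allele_frequency(g, "half_weight")$frequency,
                 (sum(known == "del") + 0.5 * sum(known == "het")) /
                   length(known))
    expect_equal(tpi_allele_frequency(g, "carrier")$frequency,
                 sum(known != "plus") / length(known))
  }
  expect_error(tpi_allele_frequency(mk(rep("unknown", 3))), "unknown")
})

test_that("with no heterozygotes, per-specimen equals per-chromosome", {
  st <- c(rep("del", 7), rep("plus", 13)) # hemizygous females only
  g <- tibble::tibble(specimen_id = sprintf("S%d", 1:20), i65_status = st)
  per_chrom <- 7 / 20
  expect_equal(tpi_allele_frequency(g, "half_weight")$frequency, per_chrom)
  expect_equal(tpi_allele_frequency(g, "carrier")$frequency, per_chrom)
})
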