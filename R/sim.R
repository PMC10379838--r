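# Founder-effect migration simulator.
#
# The explanatory model: a migrating group of n_founders individuals is a
# multinomial draw from the source haplotype frequencies; the destination
# population then expands at the founder proportions (optionally with
# Wright-Fisher drift), and n_sampled specimens are genotyped from it.
# Large migrating groups preserve the source proportions; small groups
# drift, so destination variance in haplotype frequency (and in M) grows
# as founder size shrinks: Var(f) ~ p(1-p)(1/n_founders + 1/n_sampled).

#' Define a source population
#'
#' Defaults describe the overwintering source used throughout: four COI
#' haplotypes at (0.68, 0.27, 0.04, 0.01) — consistent with the observed
#' ~67/33 and ~68/32 splits at the two marker sites and the roughly
#' three-fold excess of the third haplotype over the fourth — an i65del
#' allele frequency of 0.16, and a two-haplotype Tpi exon pool whose minor
#' variant sits at 10% (below the marker-selection threshold, as observed).
#'
#' @param name Label, e.g. `"TX"`.
#' @param coib_freqs Named frequency vector over COI haplotype labels.
#' @param i65del_freq i65del allele frequency on Z.
#' @param tpie_freqs Named frequency vector over Tpi exon haplotype labels.
#' @param singleton_rate Per-site, per-specimen probability of a private
#'   (singleton) variant at non-marker positions.
#' @return A `source_population` object.
#' @export
source_population <- function(name = "source",
                              coib_freqs = c("C1035/T1272" = 0.68,
                                             "T1035/C1272" = 0.27,
                                             "T1035/T1272" = 0.04,
                                             "C1035/C1272" = 0.01),
                              i65del_freq = 0.16,
                              tpie_freqs = c("A48/G51/C153/C177" = 0.90,
                                             "A48/A51/C153/C177" = 0.10),
                              singleton_rate = 0) {
  for (v in list(coib_freqs, tpie_freqs)) {
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      abort("frequency vectors must be non-negative and sum to 1")
    }
  }
  if (i65del_freq < 0 || i65del_freq > 1) abort("i65del_freq not in [0,1]")
  if (singleton_rate < 0 || singleton_rate > 1) {
    abort("singleton_rate not in [0,1]")
  }
  structure(list(name = name, coib_freqs = coib_freqs,
                 i65del_freq = i65del_freq, tpie_freqs = tpie_freqs,
                 singleton_rate = singleton_rate),
            class = "source_population")
}

#' Define a migration scenario
#'
#' @param source A [source_population()].
#' @param n_founders Founding group size per destination (use `Inf` for
#'   direct sampling from the source, i.e. no founder bottleneck).
#' @param n_destinations Number of destination collections.
#' @param n_sampled Specimens genotyped per destination.
#' @param expansion `"exact_frequencies"` (default: the founder event is
#'   the only drift) or `list(mode = "wright_fisher", gens, N)`.
#' @param sex_ratio Fraction of sampled specimens that are ZZ males.
#' @param seed Integer seed; fully determines all output.
#' @return A `migration_scenario` object.
#' @export
migration_scenario <- function(source, n_founders, n_destinations = 1L,
                               n_sampled = 100L,
                               expansion = "exact_frequencies",
                               sex_ratio = 0.5, seed = 1L) {
  if (!is.infinite(n_founders) && (n_founders < 1 ||
                                   n_founders != round(n_founders))) {
    abort("n_founders must be an integer >= 1 (or Inf)")
  }
  structure(list(source = source, n_founders = n_founders,
                 n_destinations = as.integer(n_destinations),
                 n_sampled = as.integer(n_sampled), expansion = expansion,
                 sex_ratio = sex_ratio, seed = as.integer(seed)),
            class = "migration_scenario")
}

#' Sample a founding group from a source population
#'
#' One multinomial draw of `n_founders` individuals from the source COI
#' haplotype frequencies.
#'
#' @param source A [source_population()].
#' @param n_founders Group size (>= 1).
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return Named integer count vector over haplotype labels.
#' @export
sample_founders <- function(source, n_founders, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_founders < 1) abort("n_founders must be >= 1")
  setNames(as.integer(rmultinom(1, n_founders, source$coib_freqs)),
           names(source$coib_freqs))
}

#' Expand a founder group and sample specimens from the destination
#'
#' In `exact_frequencies` mode the destination is sampled multinomially
#' at the founder proportions (the founder event is the only drift). In
#' `wright_fisher` mode the proportions first drift through `gens`
#' generations of binomial resampling at population size `N`.
#'
#' @param founder_counts Named count vector from [sample_founders()].
#' @param scenario A [migration_scenario()].
#' @return Named integer count vector over haplotype labels, summing to
#'   `scenario$n_sampled`.
#' @export
expand_and_sample <- function(founder_counts, scenario) {
  if (sum(founder_counts) < 1) abort("founder group is empty")
  freqs <- founder_counts / sum(founder_counts)
  ex <- scenario$expansion
  if (is.list(ex) && identical(ex$mode, "wright_fisher")) {
    for (g in seq_len(ex$gens)) {
      freqs <- as.vector(rmultinom(1, ex$N, freqs)) / ex$N
    }
  }
  setNames(as.integer(rmultinom(1, scenario$n_sampled, freqs)),
           names(founder_counts))
}

#' Replicate destination count vectors (vectorised two-stage sampling)
#'
#' Draws `replicates` independent founder-then-sample outcomes in
#' `exact_frequencies` mode. The second stage uses the sequential
#' conditional-binomial construction of the multinomial so all replicates
#' vectorise.
#'
#' @param source A [source_population()].
#' @param n_founders Founder size (`Inf` = direct source sampling).
#' @param n_sampled Specimens per destination.
#' @param replicates Number of destinations to draw.
#' @return Integer matrix `replicates x k` (columns = haplotype labels).
#' @export
replicate_destinations <- function(source, n_founders, n_sampled,
                                   replicates) {
  p <- source$coib_freqs
  k <- length(p)
  if (is.infinite(n_founders)) {
    return(t(rmultinom(replicates, n_sampled,
                       p))[, seq_len(k), drop = FALSE] |>
             `colnames<-`(names(p)))
  }
  fo <- rmultinom(replicates, n_founders, p) # k x R
  out <- matrix(0L, k, replicates)
  rem <- rep.int(n_sampled, replicates)
  frem <- colSums(fo)
  for (i in seq_len(k - 1L)) {
    pr <- ifelse(frem > 0, fo[i, ] / frem, 0)
    out[i, ] <- rbinom(replicates, rem, pr)
    rem <- rem - out[i, ]
    frem <- frem - fo[i, ]
  }
  out[k, ] <- rem
  t(out) |> `colnames<-`(names(p))
}

# per-destination M over a replicate count matrix; zero-denominator rows
# dropped
destination_m <- function(counts, focal, contrast) {
  a <- counts[, focal]; b <- counts[, contrast]
  keep <- a + b > 0
  (a[keep] - b[keep]) / (a[keep] + b[keep])
}

#' Simulate one regional study and test it
#'
#' Builds a south set of collections sampled directly from the source and
#' a north set of founder-event destinations, assigns them states of the
#' North/South scheme, and runs [regional_compare()].
#'
#' @param source A [source_population()].
#' @param n_founders Founder size for the north destinations.
#' @param n_collections Collections per region.
#' @param n_sampled Specimens per collection.
#' @param focal,contrast Haplotype labels entering M.
#' @param variant t-test variant.
#' @return The `hm_htest` from [regional_compare()].
#' @export
simulate_regional_study <- function(source, n_founders,
                                    n_collections = 10L, n_sampled = 100L,
                                    focal = "C1035/T1272",
                                    contrast = "T1035/C1272",
                                    variant = "pooled") {
  scheme <- region_scheme_north_south()
  north_states <- names(scheme$mapping)[scheme$mapping == "North"]
  south_states <- names(scheme$mapping)[scheme$mapping == "South"]
  south <- replicate_destinations(source, Inf, n_sampled, n_collections)
  north <- replicate_destinations(source, n_founders, n_sampled,
                                  n_collections)
  counts <- rbind(south, north)
  m_tbl <- tibble(
    state = c(rep_len(south_states, n_collections),
              rep_len(north_states, n_collections)),
    count_a = counts[, focal], count_b = counts[, contrast]) %>%
    filter(.data$count_a + .data$count_b > 0) %>%
    mutate(m = m_statistic(.data$count_a, .data$count_b))
  regional_compare(m_tbl, scheme, variant = variant)
}

#' Power / calibration analysis over founder sizes
#'
#' For each founder size, repeatedly simulates a paired south (direct
#' source samples) and north (founder-event destinations) study, runs
#' [regional_compare()], and records the rejection rate at `alpha`
#' together with the standard deviation of destination M.
#'
#' @param source A [source_population()].
#' @param founder_sizes Integer vector of founder sizes.
#' @param replicates Simulated studies per founder size (>= 100 for a
#'   meaningful rate; smaller values error).
#' @param alpha Significance level.
#' @param n_collections,n_sampled Study layout per region.
#' @param focal,contrast Haplotype labels entering M.
#' @param m_sd_replicates Destinations drawn for the M-sd estimate.
#' @param seed Integer seed.
#' @return Tibble of class `hm_power_grid`: `founder_size`,
#'   `rejection_rate`, `m_sd`, `replicates`, `alpha`.
#' @export
run_power_analysis <- function(source, founder_sizes,
                               replicates = 200L, alpha = 0.05,
                               n_collections = 10L, n_sampled = 100L,
                               focal = "C1035/T1272",
                               contrast = "T1035/C1272",
                               m_sd_replicates = 2000L, seed = 1L) {
  if (replicates < 100L) abort("replicates must be >= 100")
  set.seed(seed)
  rows <- lapply(founder_sizes, function(nf) {
    rej <- vapply(seq_len(replicates), function(r) {
      res <- simulate_regional_study(source, nf, n_collections, n_sampled,
                                     focal, contrast)
      res$p_value < alpha
    }, TRUE)
    msd <- sd(destination_m(
      replicate_destinations(source, nf, n_sampled, m_sd_replicates),
      focal, contrast))
    tibble(founder_size = nf, rejection_rate = mean(rej), m_sd = msd,
           replicates = replicates, alpha = alpha)
  })
  out <- bind_rows(rows)
  class(out) <- c("hm_power_grid", class(out))
  out
}
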