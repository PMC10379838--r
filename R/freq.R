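# Haplotype frequency tables and the M haplotype-ratio statistic.
#
# M contrasts the two predominant haplotypes of a group:
#   M = (n_A - n_B) / (n_A + n_B)
# with A the focal and B the contrast haplotype. M lies in [-1, 1], is
# antisymmetric under swapping the pair, and depends only on the ratio of
# the two counts — which is what makes it robust to sample-size
# differences between collections.

#' Per-group haplotype counts and frequencies
#'
#' Counts resolved haplotype calls per group. `group_by` names columns of
#' the specimen metadata (e.g. `"collection_id"`, `c("state", "year")`,
#' or `"state"`); calls whose specimens fall in groups with zero resolved
#' calls are dropped with a warning.
#'
#' @param calls Tibble from [call_haplotypes()].
#' @param meta Specimen metadata tibble (must carry `specimen_id` and the
#'   grouping columns).
#' @param group_by Character vector of metadata columns to group on.
#' @return Tibble: grouping columns, `haplotype`, `n`, `n_resolved`
#'   (group total), `frequency`.
#' @export
frequency_table <- function(calls, meta, group_by = "collection_id") {
  resolved <- calls %>% filter(.data$status == "resolved")
  if (nrow(resolved) == 0L) abort("no resolved haplotype calls")
  n_unres <- nrow(calls) - nrow(resolved)
  if (n_unres > 0L) {
    inform(sprintf("%d unresolved/missing call(s) excluded", n_unres))
  }
  joined <- resolved %>%
    left_join(meta %>% select(all_of(c("specimen_id", group_by))),
              by = "specimen_id")
  tab <- joined %>%
    count(across(all_of(group_by)), .data$haplotype, name = "n") %>%
    group_by(across(all_of(group_by))) %>%
    mutate(n_resolved = sum(.data$n),
           frequency = .data$n / .data$n_resolved) %>%
    ungroup()
  class(tab) <- c("hm_freq_table", class(tab))
  tab
}

#' The M haplotype-ratio statistic
#'
#' @param count_a Count (or frequency) of the focal haplotype.
#' @param count_b Count (or frequency) of the contrast haplotype.
#' @return `(count_a - count_b) / (count_a + count_b)`, vectorised.
#' @export
m_statistic <- function(count_a, count_b) {
  if (any(count_a < 0 | count_b < 0)) abort("counts must be non-negative")
  if (any(count_a + count_b == 0)) {
    abort("M is undefined when both haplotype counts are zero")
  }
  (count_a - count_b) / (count_a + count_b)
}

#' Per-group M statistics from a frequency table
#'
#' Groups where both the focal and contrast haplotypes are absent have an
#' undefined M and are dropped with a warning rather than imputed.
#'
#' @param freq_tab Tibble from [frequency_table()].
#' @param focal,contrast Haplotype labels entering M as A and B.
#' @return Tibble: grouping columns, `count_a`, `count_b`, `m`.
#' @export
m_table <- function(freq_tab, focal, contrast) {
  keys <- setdiff(names(freq_tab),
                  c("haplotype", "n", "n_resolved", "frequency"))
  wide <- freq_tab %>%
    filter(.data$haplotype %in% c(focal, contrast)) %>%
    select(all_of(keys), "haplotype", "n") %>%
    tidyr::pivot_wider(names_from = "haplotype", values_from = "n",
                       values_fill = 0L)
  for (h in c(focal, contrast)) if (!h %in% names(wide)) wide[[h]] <- 0L
  empty <- wide[[focal]] + wide[[contrast]] == 0L
  if (any(empty)) {
    warn(sprintf("%d group(s) dropped: both focal and contrast counts zero",
                 sum(empty)))
    wide <- wide[!empty, , drop = FALSE]
  }
  wide %>%
    mutate(count_a = .data[[focal]], count_b = .data[[contrast]],
           m = m_statistic(.data$count_a, .data$count_b)) %>%
    select(all_of(keys), "count_a", "count_b", "m")
}
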