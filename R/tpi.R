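# Z-linked Tpi genotyping: exon SNPs and the 7-bp intron deletion i65del.
#
# Tpi sits on the Z chromosome: males (ZZ) carry two copies and can be
# heterozygous, females (ZW) are hemizygous. Direct sequencing of a PCR
# product from a heterozygous male superimposes both alleles; an exon SNP
# het shows as a single IUPAC position, but a heterozygous indel shifts
# the two traces out of frame, producing a sustained run of mixed
# (ambiguous) positions downstream of the indel start. That artifact is
# itself the het-indel signal: a run of >= `het_run_length` bases starting
# inside the declared indel window in which at least `het_run_frac` of
# positions are ambiguous or mismatched marks the read heterozygous.

# classify one unambiguous allele read as del / plus / unknown
classify_i65_allele <- function(seq, ref, i65_window, del_length,
                                max_plus_mismatch = 0.05) {
  m <- tryCatch(map_to_reference(seq, ref, indel_window = i65_window),
                haplomig_unmappable = function(e) NULL)
  if (is.null(m)) return("unknown")
  if (m$indel_suspected && (m$shift - m$shift_downstream) == del_length) {
    return("del")
  }
  if (!m$indel_suspected && m$mismatch_frac <= max_plus_mismatch) {
    return("plus")
  }
  "unknown"
}

# het-indel artifact test on a direct read: returns TRUE when a sustained
# ambiguity/mismatch run begins inside the indel window
het_indel_run <- function(seq_ch, ref, map, i65_window,
                          het_run_length = 20L, het_run_frac = 0.5) {
  positions <- ref$offset + seq_len(ref$length) - 1L
  read_idx <- positions - ref$offset + 1L + map$shift
  in_read <- read_idx >= 1L & read_idx <= length(seq_ch)
  amb <- rep(FALSE, length(positions))
  mis <- rep(FALSE, length(positions))
  ref_ch <- strsplit(ref$sequence, "")[[1]]
  amb[in_read] <- is_ambiguous(seq_ch[read_idx[in_read]])
  mis[in_read] <- !iupac_compatible(seq_ch[read_idx[in_read]],
                                    ref_ch[in_read])
  bad <- amb | mis
  starts <- which(amb & positions >= i65_window[1] &
                    positions <= i65_window[2])
  for (s in starts) {
    span <- s:min(s + het_run_length - 1L, length(positions))
    if (length(span) >= het_run_length && mean(bad[span]) >= het_run_frac) {
      return(TRUE)
    }
  }
  FALSE
}

# i65 status for one specimen's intron reads (1 direct or 2 phased)
i65_status_one <- function(seqs, ref, i65_window, del_length,
                           het_run_length, het_run_frac) {
  if (length(seqs) == 2L) {
    calls <- vapply(seqs, classify_i65_allele, "", ref = ref,
                    i65_window = i65_window, del_length = del_length)
    if (any(calls == "unknown")) return("unknown")
    if (all(calls == "del")) return("del")
    if (all(calls == "plus")) return("plus")
    return("het")
  }
  seq <- toupper(seqs[1])
  m <- tryCatch(map_to_reference(seq, ref, indel_window = i65_window),
                haplomig_unmappable = function(e) NULL)
  if (!is.null(m) && !m$indel_suspected) {
    seq_ch <- strsplit(seq, "")[[1]]
    if (het_indel_run(seq_ch, ref, m, i65_window,
                      het_run_length, het_run_frac)) {
      return("het")
    }
  }
  classify_i65_allele(seq, ref, i65_window, del_length)
}

#' Genotype specimens at the Tpi exon sites and the i65del intron indel
#'
#' Exon sites are read per specimen: phased ZZ-male pairs give an
#' unordered base pair, direct reads give a base or (via a two-base IUPAC
#' code) a het pair. The i65 indel status is `del` when the read carries a
#' clean frame offset of `del_length` starting in `i65_window`, `plus`
#' when it matches the full reference co-linearly, `het` when the
#' direct-read het-indel artifact is detected (or a phased pair mixes del
#' and plus), else `unknown`. Heterozygous calls on a hemizygous female
#' are biologically impossible and are downgraded to unknown with a
#' warning.
#'
#' @param specimens Specimen set from [read_specimens()].
#' @param refs Named list of [ref_segment()]s containing
#'   `intron_segment` (and `exon_segment` if exon sites are requested).
#' @param exon_sites Marker sites tibble for the exon segment, or `NULL`
#'   to skip exon genotyping.
#' @param i65_window Gene-frame interval of the deletion (default
#'   `c(65, 71)` in the intron frame).
#' @param del_length Deletion length in bp (default 7).
#' @param exon_segment,intron_segment Segment names.
#' @param het_run_length,het_run_frac Het-indel artifact detection: the
#'   run length (bases) and minimum ambiguous/mismatch fraction.
#' @return Tibble: `specimen_id`, `sex_ploidy`, `i65_status`, and one
#'   column per exon site (named `<segment>_<position>`, values like
#'   `"A"` or `"A/G"`).
#' @export
call_tpi <- function(specimens, refs, exon_sites = NULL,
                     i65_window = c(65L, 71L), del_length = 7L,
                     exon_segment = "sTpiE", intron_segment = "sTpi140",
                     het_run_length = 20L, het_run_frac = 0.5) {
  ref_i <- refs[[intron_segment]]
  if (is.null(ref_i)) abort(sprintf("no reference for %s", intron_segment))
  sex <- setNames(specimens$meta$sex_ploidy, specimens$meta$specimen_id)

  intron <- specimens$sequences %>% filter(.data$segment == intron_segment)
  ids <- sort(unique(intron$specimen_id))
  status <- vapply(ids, function(id) {
    s <- intron$sequence[intron$specimen_id == id]
    if (length(s) > 2L) abort(sprintf("more than 2 intron reads for %s", id))
    i65_status_one(s, ref_i, i65_window, del_length,
                   het_run_length, het_run_frac)
  }, "")
  female <- sex[ids] == "Z_hemizygous_female"
  if (any(status == "het" & female, na.rm = TRUE)) {
    n_bad <- sum(status == "het" & female, na.rm = TRUE)
    warn(sprintf(
      "%d hemizygous female(s) with heterozygous i65 signal set to unknown",
      n_bad))
    status[status == "het" & female] <- "unknown"
  }
  out <- tibble(specimen_id = ids,
                sex_ploidy = unname(sex[ids]),
                i65_status = unname(status))

  if (!is.null(exon_sites) && nrow(exon_sites) > 0L) {
    ref_e <- refs[[exon_segment]]
    if (is.null(ref_e)) abort(sprintf("no reference for %s", exon_segment))
    am <- allele_set_matrices(specimens, exon_segment, ref_e)
    col_idx <- match(exon_sites$position, am$positions)
    for (k in seq_along(col_idx)) {
      j <- col_idx[k]
      b1 <- am$b1[, j]; b2 <- am$b2[, j]
      call <- ifelse(is.na(b1), NA_character_,
                     ifelse(is.na(b2), b1, paste(b1, b2, sep = "/")))
      fem <- sex[rownames(am$b1)] == "Z_hemizygous_female"
      het <- !is.na(b2)
      if (any(het & fem, na.rm = TRUE)) {
        warn("heterozygous exon call(s) on hemizygous female set to unknown")
        call[het & fem] <- NA_character_
      }
      colname <- paste0(exon_segment, "_", exon_sites$position[k])
      out <- out %>%
        left_join(tibble(specimen_id = rownames(am$b1),
                         !!colname := call),
                  by = "specimen_id")
    }
  }
  out
}

#' Per-specimen Tpi allele frequency
#'
#' Frequencies are per specimen, not per chromosome: with `half_weight`
#' a het male contributes 0.5, with `carrier` a het contributes 1 (any
#' carrier counts). Specimens with unknown status are excluded from the
#' denominator and reported.
#'
#' @param genotypes Tibble from [call_tpi()] (needs `i65_status`).
#' @param mode `"half_weight"` (default) or `"carrier"`.
#' @return One-row tibble: `frequency`, `n_del`, `n_het`, `n_plus`,
#'   `n_unknown`, `n_scored`, `mode`.
#' @export
tpi_allele_frequency <- function(genotypes, mode = c("half_weight",
                                                     "carrier")) {
  mode <- match.arg(mode)
  st <- genotypes$i65_status
  n_del <- sum(st == "del"); n_het <- sum(st == "het")
  n_plus <- sum(st == "plus"); n_unknown <- sum(st == "unknown")
  n_scored <- n_del + n_het + n_plus
  if (n_scored == 0L) abort("all specimens have unknown i65 status")
  w <- if (mode == "half_weight") 0.5 else 1
  tibble(frequency = (n_del + w * n_het) / n_scored,
         n_del = n_del, n_het = n_het, n_plus = n_plus,
         n_unknown = n_unknown, n_scored = n_scored, mode = mode)
}
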