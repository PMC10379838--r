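# SNP discovery and marker-site selection.
#
# A site becomes a candidate SNP when at least two distinct unambiguous
# bases occur among scored specimens. Frequencies are per specimen, pooled
# across all collections: a heterozygous ZZ male carries both alleles and
# contributes one specimen to the minor tally. Marker sites are the
# candidates whose minor-variant frequency strictly exceeds the selection
# threshold (default 10%); singletons (minor allele seen in exactly one
# specimen) are treated as noise and are never selectable.

# per-specimen allele-set matrices over the reference span.
# Returns list(b1, b2): character matrices [specimen x position]; b2 is NA
# where the specimen carries a single base; both NA where unscored.
allele_set_matrices <- function(specimens, segment, ref,
                                indel_window = NULL, max_shift = 30L) {
  seqs <- specimens$sequences %>% filter(.data$segment == !!segment)
  if (nrow(seqs) == 0L) abort(sprintf("no sequences for segment %s", segment))
  ids <- sort(unique(seqs$specimen_id))
  L <- ref$length
  positions <- ref$offset + seq_len(L) - 1L
  b1 <- matrix(NA_character_, length(ids), L, dimnames = list(ids, NULL))
  b2 <- b1
  mito <- is_mito_segment(segment)
  skipped <- character(0)

  for (id in ids) {
    rows <- seqs[seqs$specimen_id == id, , drop = FALSE]
    per_allele <- vector("list", nrow(rows))
    ok <- TRUE
    for (k in seq_len(nrow(rows))) {
      m <- tryCatch(
        map_to_reference(rows$sequence[k], ref, indel_window = indel_window,
                         max_shift = max_shift),
        haplomig_unmappable = function(e) NULL)
      if (is.null(m)) { ok <- FALSE; break }
      seq_ch <- strsplit(toupper(rows$sequence[k]), "")[[1]]
      per_allele[[k]] <- mapped_bases(seq_ch, ref, m, positions)
    }
    if (!ok) { skipped <- c(skipped, id); next }
    if (length(per_allele) == 2L) {
      # phased pair: union of the two allele bases; ambiguity in either
      # read voids the position
      a <- per_allele[[1]]; b <- per_allele[[2]]
      plain <- !is.na(a) & !is.na(b) & !is_ambiguous(a) & !is_ambiguous(b)
      b1[id, plain] <- pmin(a[plain], b[plain])
      b2[id, plain] <- ifelse(a[plain] == b[plain], NA_character_,
                              pmax(a[plain], b[plain]))
    } else {
      a <- per_allele[[1]]
      plain <- !is.na(a) & !is_ambiguous(a)
      b1[id, plain] <- a[plain]
      if (!mito) {
        # direct read: two-base IUPAC codes are heterozygous calls
        het <- !is.na(a) & a %in% c("R", "Y", "S", "W", "K", "M")
        if (any(het)) {
          pairs <- vapply(a[het], function(code) IUPAC_SETS[[code]],
                          character(2))
          b1[id, het] <- pairs[1, ]
          b2[id, het] <- pairs[2, ]
        }
      }
    }
  }
  list(b1 = b1, b2 = b2, positions = positions, skipped = skipped)
}

#' Discover polymorphic sites in a marker segment
#'
#' Tallies per-specimen alleles at every reference position and reports
#' each site where two or more distinct unambiguous bases are observed.
#' Frequencies are per specimen scored (not per chromosome): a ZZ male
#' heterozygous at a site counts once in the minor-allele tally.
#'
#' @param specimens Specimen set from [read_specimens()] (or the
#'   synthesizer).
#' @param segment Segment name.
#' @param ref The segment's [ref_segment()].
#' @param indel_window Optional gene-frame indel interval passed to the
#'   mapper.
#' @return Tibble with one row per polymorphic site: `segment`, `position`
#'   (gene frame), `major`, `minor`, `minor_count`, `n_scored`,
#'   `minor_frequency`, `singleton`.
#' @export
discover_snps <- function(specimens, segment, ref, indel_window = NULL) {
  am <- allele_set_matrices(specimens, segment, ref,
                            indel_window = indel_window)
  n_mapped <- nrow(am$b1) - length(am$skipped)
  if (n_mapped == 0L) abort("no specimen maps to the reference")
  if (n_mapped < 2L) abort("fewer than two mappable specimens")

  bases <- c("A", "C", "G", "T")
  carriers <- vapply(bases, function(b) {
    colSums(am$b1 == b, na.rm = TRUE) + colSums(am$b2 == b, na.rm = TRUE)
  }, numeric(ncol(am$b1)))
  scored <- colSums(!is.na(am$b1))
  n_alleles <- rowSums(carriers > 0)

  poly <- which(n_alleles >= 2 & scored >= 2)
  if (length(poly) == 0L) {
    return(tibble(segment = character(), position = integer(),
                  major = character(), minor = character(),
                  minor_count = integer(), n_scored = integer(),
                  minor_frequency = double(), singleton = logical()))
  }
  rows <- lapply(poly, function(j) {
    cnt <- sort(carriers[j, ], decreasing = TRUE)
    tibble(segment = segment, position = am$positions[j],
           major = names(cnt)[1], minor = names(cnt)[2],
           minor_count = as.integer(cnt[2]), n_scored = as.integer(scored[j]),
           minor_frequency = unname(cnt[2]) / scored[j],
           singleton = cnt[2] == 1L)
  })
  bind_rows(rows) %>% arrange(.data$position)
}

#' Select marker sites by polymorphism frequency
#'
#' Retains sites whose minor-variant frequency strictly exceeds
#' `threshold`. Singletons are never selected regardless of frequency.
#'
#' @param sites Tibble from [discover_snps()].
#' @param threshold Selection threshold in (0, 0.5]; default 0.10.
#' @return Filtered tibble, position order preserved.
#' @export
select_marker_sites <- function(sites, threshold = 0.10) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 0.5) {
    abort("threshold must lie in (0, 0.5]")
  }
  sites %>% filter(.data$minor_frequency > threshold, !.data$singleton)
}
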