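# Per-specimen haplotype calls at selected marker sites.
#
# The mitochondrial COI is maternally inherited, so each specimen carries
# one haplotype: the combination of bases at the selected marker sites,
# labelled "<base><position>/<base><position>" in position order (e.g.
# "C1035/T1272"). Any IUPAC ambiguity at a marker site invalidates the
# whole segment call — mito heteroplasmy is not modelled, so a mixed base
# is read failure, not signal.

haplotype_label <- function(bases, positions) {
  ord <- order(positions)
  paste0(bases[ord], positions[ord], collapse = "/")
}

#' Call per-specimen haplotypes at marker sites
#'
#' @param specimens Specimen set from [read_specimens()].
#' @param segment Segment name (one sequence per specimen expected).
#' @param sites Marker sites from [select_marker_sites()]; non-empty.
#' @param ref The segment's [ref_segment()].
#' @return Tibble: `specimen_id`, `segment`, `bases` (character,
#'   `NA` unless resolved), `haplotype` (label, `NA` unless resolved),
#'   `status` in `resolved`/`unresolved_ambiguity`/`missing`.
#' @export
call_haplotypes <- function(specimens, segment, sites, ref) {
  if (nrow(sites) == 0L) abort("no marker sites supplied")
  span <- sites$position - ref$offset + 1L
  if (any(span < 1L | span > ref$length)) {
    abort("marker site outside the reference segment span")
  }
  seqs <- specimens$sequences %>% filter(.data$segment == !!segment)
  ids <- sort(unique(seqs$specimen_id))
  out <- lapply(ids, function(id) {
    rows <- seqs[seqs$specimen_id == id, , drop = FALSE]
    if (nrow(rows) != 1L) {
      return(tibble(specimen_id = id, segment = segment,
                    bases = NA_character_, haplotype = NA_character_,
                    status = "missing"))
    }
    m <- tryCatch(map_to_reference(rows$sequence[1], ref),
                  haplomig_unmappable = function(e) NULL)
    if (is.null(m)) {
      return(tibble(specimen_id = id, segment = segment,
                    bases = NA_character_, haplotype = NA_character_,
                    status = "missing"))
    }
    seq_ch <- strsplit(toupper(rows$sequence[1]), "")[[1]]
    b <- mapped_bases(seq_ch, ref, m, sites$position)
    if (any(is.na(b))) {
      status <- "missing"; hap <- NA_character_; bs <- NA_character_
    } else if (any(is_ambiguous(b))) {
      status <- "unresolved_ambiguity"; hap <- NA_character_
      bs <- paste(b, collapse = "")
    } else {
      status <- "resolved"
      hap <- haplotype_label(b, sites$position)
      bs <- paste(b, collapse = "")
    }
    tibble(specimen_id = id, segment = segment, bases = bs,
           haplotype = hap, status = status)
  })
  bind_rows(out)
}
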