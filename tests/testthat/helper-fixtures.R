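# In-code fixture builders.

REFS <- read_reference_set()

# build a specimen set directly (bypassing disk) from a sequences tibble;
# metadata defaults to one field collection in MS
make_specimens <- function(sequences, meta = NULL) {
  ids <- unique(sequences$specimen_id)
  if (is.null(meta)) {
    meta <- tibble::tibble(
      specimen_id = ids, collection_id = "MS-T01", state = "MS",
      year = 2019L, source_type = "field_larva", sex_ploidy = "ZZ_male")
  }
  collections <- dplyr::summarise(
    dplyr::group_by(meta, collection_id, state, year, source_type),
    n_specimens = dplyr::n(), .groups = "drop")
  list(sequences = sequences, meta = meta, collections = collections)
}

# n specimens carrying given haplotype labels on one mito segment
make_mito_cohort <- function(labels, segment = "sCOIB", ref = REFS$sCOIB) {
  seqs <- tibble::tibble(
    specimen_id = sprintf("SP%03d", seq_along(labels)),
    segment = segment, allele = 1L,
    sequence = vapply(labels, function(l) {
      ch <- strsplit(ref$sequence, "")[[1]]
      for (tok in strsplit(l, "/", fixed = TRUE)[[1]]) {
        pos <- as.integer(substring(tok, 2))
        ch[pos - ref$offset + 1] <- substr(tok, 1, 1)
      }
      paste(ch, collapse = "")
    }, "", USE.NAMES = FALSE))
  make_specimens(seqs)
}

set_base_at <- function(seq, idx, base) {
  substr(seq, idx, idx) <- base
  seq
}

# plus / del / het-direct-read intron sequences from the bundled sTpi140
tpi140_alleles <- function(ref = REFS$sTpi140, w1 = 65L, len = 7L) {
  plus <- ref$sequence
  del <- paste0(substr(plus, 1, w1 - 1), substr(plus, w1 + len, nchar(plus)))
  pc <- strsplit(plus, "")[[1]]; dc <- strsplit(del, "")[[1]]
  het <- vapply(seq_along(dc), function(i) {
    if (i < w1 || pc[i] == dc[i]) return(dc[i])
    haplomig:::iupac_merge(pc[i], dc[i])
  }, "")
  list(plus = plus, del = del, het = paste(het, collapse = ""))
}

write_fasta <- function(headers, seqs, path) {
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}

default_source <- function(...) source_population(...)
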