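# Specimen sequence + metadata ingestion.
#
# One strict FASTA header dialect: "specimen_id|segment|allele", allele 1
# or 2. Two alleles are only legal on Tpi segments of ZZ males (the
# phased representation of a heterozygote); mitochondrial segments are
# haploid. Metadata is a comma-delimited table with one row per specimen.

SPECIMEN_META_COLS <- c("specimen_id", "collection_id", "state", "year",
                        "source_type", "sex_ploidy")
SOURCE_TYPES <- c("field_larva", "colony_F1_F2", "pheromone_trap")
SEX_PLOIDY <- c("mito_haploid", "Z_hemizygous_female", "ZZ_male", "unknown")
MITO_SEGMENTS <- c("sCOIA", "sCOIB")

is_mito_segment <- function(segment) segment %in% MITO_SEGMENTS

#' Read specimen sequences and metadata
#'
#' Loads a specimen FASTA (headers `id|segment|allele`) and the per-specimen
#' metadata CSV, cross-validates them, and returns tidy tibbles.
#'
#' Validation enforces the biology of the markers: at most two alleles per
#' (specimen, segment); two alleles only on non-mitochondrial segments of
#' `ZZ_male` (or unknown-ploidy) specimens; mitochondrial reads with IUPAC
#' ambiguity at more than `max_mito_ambiguity` of positions are rejected as
#' unreadable (a single maternally inherited haplotype is expected, so a
#' heavily mixed trace indicates a failed read). Sequences are upcased and
#' `U` mapped to `T` on ingestion.
#'
#' @param seq_path FASTA of per-specimen amplicon sequences.
#' @param meta_path CSV with columns `specimen_id, collection_id, state,
#'   year, source_type, sex_ploidy` (and optionally `collector`).
#' @param delim Header field delimiter (default `"|"`).
#' @param max_mito_ambiguity Maximum tolerated fraction of ambiguous
#'   positions in a mitochondrial read.
#' @return List with `sequences` (tibble: specimen_id, segment, allele,
#'   sequence), `meta` (specimen metadata tibble) and `collections`
#'   (one row per collection: collection_id, state, year, source_type,
#'   n_specimens).
#' @export
read_specimens <- function(seq_path, meta_path, delim = "|",
                           max_mito_ambiguity = 0.20) {
  ss <- Biostrings::readDNAStringSet(seq_path)
  if (length(ss) == 0) abort(sprintf("no sequences in '%s'", seq_path))
  parts <- strsplit(names(ss), delim, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L)) {
    abort(sprintf("malformed FASTA header '%s' (expected id%ssegment%sallele)",
                  names(ss)[which(nf != 3L)[1]], delim, delim))
  }
  seqs <- tibble(
    specimen_id = vapply(parts, `[`, "", 1L),
    segment     = vapply(parts, `[`, "", 2L),
    allele      = as.integer(vapply(parts, `[`, "", 3L)),
    sequence    = gsub("U", "T", toupper(as.character(ss)), fixed = TRUE)
  )
  if (any(is.na(seqs$allele)) || any(!seqs$allele %in% c(1L, 2L))) {
    abort("allele field in FASTA headers must be 1 or 2")
  }
  dup <- seqs %>% count(.data$specimen_id, .data$segment, .data$allele) %>%
    filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("duplicate FASTA record for %s%s%s%s%d",
                  dup$specimen_id[1], delim, dup$segment[1], delim,
                  dup$allele[1]))
  }

  meta <- readr::read_csv(meta_path, show_col_types = FALSE)
  missing_cols <- setdiff(SPECIMEN_META_COLS, names(meta))
  if (length(missing_cols) > 0L) {
    abort(paste("metadata is missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(meta$specimen_id)) {
    abort("duplicate specimen_id in metadata")
  }
  bad_type <- setdiff(unique(meta$source_type), SOURCE_TYPES)
  if (length(bad_type) > 0L) {
    abort(paste("unknown source_type:", paste(bad_type, collapse = ", ")))
  }
  bad_sex <- setdiff(unique(meta$sex_ploidy), SEX_PLOIDY)
  if (length(bad_sex) > 0L) {
    abort(paste("unknown sex_ploidy:", paste(bad_sex, collapse = ", ")))
  }

  orphans <- setdiff(unique(seqs$specimen_id), meta$specimen_id)
  if (length(orphans) > 0L) {
    abort(sprintf("specimen(s) in FASTA absent from metadata: %s",
                  paste(head(orphans, 5L), collapse = ", ")))
  }

  # two alleles: Tpi segments of ZZ males (or unknown) only
  two <- seqs %>% count(.data$specimen_id, .data$segment) %>%
    filter(.data$n == 2L)
  if (nrow(two) > 0L) {
    mito2 <- two %>% filter(is_mito_segment(.data$segment))
    if (nrow(mito2) > 0L) {
      abort(sprintf("two alleles on mitochondrial segment %s of %s",
                    mito2$segment[1], mito2$specimen_id[1]))
    }
    sex <- setNames(meta$sex_ploidy, meta$specimen_id)
    bad <- two$specimen_id[!sex[two$specimen_id] %in% c("ZZ_male", "unknown")]
    if (length(bad) > 0L) {
      abort(sprintf("two alleles for non-ZZ_male specimen %s", bad[1]))
    }
  }

  # mito reads that are mostly ambiguity are failed traces, not data
  mito <- seqs %>% filter(is_mito_segment(.data$segment))
  if (nrow(mito) > 0L) {
    amb <- vapply(mito$sequence, function(s) {
      ch <- strsplit(s, "")[[1]]
      mean(is_ambiguous(ch))
    }, 0)
    if (any(amb > max_mito_ambiguity)) {
      i <- which(amb > max_mito_ambiguity)[1]
      abort(sprintf(
        "mitochondrial read %s/%s unreadable: %.0f%% ambiguous positions",
        mito$specimen_id[i], mito$segment[i], 100 * amb[i]))
    }
  }

  collections <- meta %>%
    group_by(.data$collection_id, .data$state, .data$year,
             .data$source_type) %>%
    summarise(n_specimens = dplyr::n(), .groups = "drop")
  if (anyDuplicated(collections$collection_id)) {
    abort("collection_id maps to inconsistent state/year/source_type rows")
  }

  list(sequences = seqs, meta = as_tibble(meta), collections = collections)
}

#' Write a specimen set back to FASTA + CSV
#'
#' Inverse of [read_specimens()]; rows are written in a canonical order
#' (specimen, segment, allele) so a read/write/read cycle is byte-identical.
#'
#' @param specimens List as returned by [read_specimens()].
#' @param seq_path,meta_path Output paths.
#' @param delim Header delimiter.
#' @return Invisibly, the two paths.
#' @export
write_specimens <- function(specimens, seq_path, meta_path, delim = "|") {
  seqs <- specimens$sequences %>%
    arrange(.data$specimen_id, .data$segment, .data$allele)
  headers <- paste(seqs$specimen_id, seqs$segment, seqs$allele, sep = delim)
  lines <- as.vector(rbind(paste0(">", headers), seqs$sequence))
  writeLines(lines, seq_path)
  meta <- specimens$meta %>% arrange(.data$specimen_id)
  readr::write_csv(meta, meta_path)
  invisible(c(seq_path, meta_path))
}
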