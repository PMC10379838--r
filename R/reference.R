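# Reference segments and gene-frame coordinates.
#
# Marker positions are named in a gene frame (e.g. sCOIB_1035 is position
# 1035 of the COI gene), not segment-relative. A reference segment is the
# amplicon sequence plus the 1-based gene-frame coordinate of its first
# base, so position p reads string index p - offset + 1.

#' Construct a reference segment
#'
#' @param name Segment identifier (conventionally one of `sCOIA`, `sCOIB`,
#'   `sTpiE`, `sTpi140`).
#' @param sequence Nucleotide string; upcased, `U` mapped to `T`; must then
#'   be pure A/C/G/T.
#' @param offset 1-based gene-frame coordinate of the first base.
#' @param frame Coordinate-frame label, e.g. `"COI"` or `"Tpi"`.
#' @return An object of class `ref_segment`.
#' @export
ref_segment <- function(name, sequence, offset, frame = name) {
  stopifnot(is.character(name), length(name) == 1L)
  sequence <- toupper(sequence)
  sequence <- gsub("U", "T", sequence, fixed = TRUE)
  if (nchar(sequence) == 0L) abort("reference sequence is empty")
  bad <- regexpr("[^ACGT]", sequence)
  if (bad > 0L) {
    abort(sprintf("reference '%s' has non-ACGT character '%s' at position %d",
                  name, substr(sequence, bad, bad), bad))
  }
  if (!is.numeric(offset) || length(offset) != 1L || offset < 1 ||
      offset != round(offset)) {
    abort("offset must be a single integer >= 1")
  }
  structure(
    list(name = name, sequence = sequence, offset = as.integer(offset),
         frame = frame, length = nchar(sequence)),
    class = "ref_segment"
  )
}

#' @export
print.ref_segment <- function(x, ...) {
  cat(sprintf("<ref_segment> %s [%s frame], %d bp, gene-frame %d..%d\n",
              x$name, x$frame, x$length, x$offset, x$offset + x$length - 1L))
  invisible(x)
}

#' Read a reference segment from a single-record FASTA file
#'
#' @param path Path to a FASTA file with exactly one record.
#' @param offset 1-based gene-frame coordinate of the first base.
#' @param frame Coordinate-frame label; defaults to the record name.
#' @param name Segment name; defaults to the FASTA record id.
#' @return A [ref_segment()].
#' @export
read_reference <- function(path, offset, frame = NULL, name = NULL) {
  # BStringSet so that tolerated input (lowercase, U) reaches the
  # ref_segment validator intact
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) != 1L) {
    abort(sprintf("expected a single FASTA record in '%s', found %d",
                  path, length(ss)))
  }
  id <- strsplit(names(ss)[1], "\\s+")[[1]][1]
  if (is.null(name)) name <- id
  if (is.null(frame)) frame <- name
  ref_segment(name, as.character(ss[[1]]), offset, frame)
}

#' Read the bundled set of synthetic reference segments
#'
#' The package ships one synthetic reference per marker segment together
#' with its gene-frame offset (a stand-in for the study organism's real
#' amplicons; only coordinates and marker positions matter to the method).
#'
#' @param path FASTA of reference segments; record headers are
#'   `name offset=<int> frame=<label>`.
#' @return Named list of [ref_segment()] objects.
#' @export
read_reference_set <- function(path = system.file("extdata",
                                                  "synthetic_refs.fasta",
                                                  package = "haplomig")) {
  ss <- Biostrings::readDNAStringSet(path)
  refs <- lapply(seq_along(ss), function(i) {
    hdr <- names(ss)[i]
    toks <- strsplit(hdr, "\\s+")[[1]]
    kv <- toks[-1]
    get <- function(key, default = NULL) {
      hit <- grep(paste0("^", key, "="), kv, value = TRUE)
      if (length(hit) == 0) default else sub(paste0("^", key, "="), "", hit[1])
    }
    off <- get("offset")
    if (is.null(off)) abort(sprintf("record '%s' lacks offset=", toks[1]))
    ref_segment(toks[1], as.character(ss[[i]]), as.integer(off),
                frame = get("frame", toks[1]))
  })
  setNames(refs, vapply(refs, `[[`, "", "name"))
}

#' Read the base of a reference at gene-frame positions
#'
#' @param ref A [ref_segment()].
#' @param positions Integer gene-frame positions.
#' @return Character vector of bases; `NA` outside the segment span.
#' @export
ref_base <- function(ref, positions) {
  idx <- positions - ref$offset + 1L
  ok <- idx >= 1L & idx <= ref$length
  out <- rep(NA_character_, length(positions))
  if (any(ok)) out[ok] <- substring(ref$sequence, idx[ok], idx[ok])
  out
}
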