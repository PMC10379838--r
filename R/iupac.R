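# IUPAC nucleotide ambiguity handling.
#
# Direct Sanger reads of a heterozygous Z-linked locus superimpose two
# alleles; mixed positions are encoded with the standard one-letter
# ambiguity codes (Y = C/T etc.). These tables drive both the caller
# (expanding a read base into the set of bases it may represent) and the
# synthetic-read generator (merging two alleles into one direct read).

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# reverse lookup: sorted base set -> code
IUPAC_CODES <- local({
  keys <- vapply(IUPAC_SETS, function(b) paste(sort(b), collapse = ""), "")
  setNames(names(IUPAC_SETS), keys)
})

#' Expand an IUPAC base into the set of bases it can represent
#'
#' @param base Single uppercase character.
#' @return Character vector of A/C/G/T bases, or `NA` for characters that
#'   are not IUPAC nucleotide codes (e.g. gap symbols).
#' @keywords internal
iupac_expand <- function(base) {
  s <- IUPAC_SETS[[base]]
  if (is.null(s)) NA_character_ else s
}

#' Merge two bases into the IUPAC code covering both
#'
#' Used by the read synthesizer to build the direct-sequencing trace of a
#' heterozygous male: each output position carries the union of the two
#' allele bases.
#'
#' @param a,b Uppercase bases (may themselves be ambiguity codes).
#' @return Single IUPAC character.
#' @keywords internal
iupac_merge <- function(a, b) {
  u <- sort(unique(c(iupac_expand(a), iupac_expand(b))))
  u <- u[!is.na(u)]
  if (length(u) == 0) return("N")
  IUPAC_CODES[[paste(u, collapse = "")]]
}

#' Vectorised IUPAC compatibility between a read and a reference
#'
#' A read base is compatible with a reference base when the reference base
#' is contained in the read base's ambiguity set (so Y matches C or T).
#'
#' @param read,ref Equal-length character vectors of single bases.
#' @return Logical vector (FALSE for non-IUPAC read characters).
#' @keywords internal
iupac_compatible <- function(read, ref) {
  out <- IUPAC_COMPAT[cbind(
    match(read, rownames(IUPAC_COMPAT)),
    match(ref, colnames(IUPAC_COMPAT))
  )]
  out[is.na(out)] <- FALSE
  out
}

# precomputed 15 x 4 compatibility lookup, indexed [read code, ref base]
IUPAC_COMPAT <- local({
  m <- matrix(FALSE, length(IUPAC_SETS), 4,
              dimnames = list(names(IUPAC_SETS), c("A", "C", "G", "T")))
  for (code in names(IUPAC_SETS)) m[code, IUPAC_SETS[[code]]] <- TRUE
  m
})

is_ambiguous <- function(bases) !(bases %in% c("A", "C", "G", "T"))
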