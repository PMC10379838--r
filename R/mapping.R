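# Co-linear placement of an amplicon read on its reference segment.
#
# Sanger amplicons from fixed primers are co-linear with the reference
# except across an indel, so a full gapped alignment is unnecessary: an
# exhaustive scan over a bounded range of shifts, picking the minimum
# mismatch fraction (IUPAC-compatible bases count as matches), is exact
# and auditable. A declared indel window gets a second, split scan: a
# deletion in the read makes the downstream portion fit best at
# (upstream shift - deletion length).
#
# Convention: gene-frame position p reads specimen index p - offset + 1 + shift.

# scan shifts for the read slice [i_lo, i_hi]; returns best (shift,
# mismatches, frac, overlap). Ties prefer smaller |shift| then smaller shift.
scan_shifts <- function(seq_ch, ref_ch, i_lo, i_hi, shifts, min_overlap = 15L) {
  n_ref <- length(ref_ch)
  best <- list(shift = NA_integer_, mismatches = NA_integer_,
               frac = Inf, overlap = 0L)
  ord <- shifts[order(abs(shifts), shifts)]
  for (s in ord) {
    lo <- max(i_lo, 1L + s)
    hi <- min(i_hi, n_ref + s)
    if (hi - lo + 1L < min_overlap) next
    idx <- lo:hi
    ok <- iupac_compatible(seq_ch[idx], ref_ch[idx - s])
    mm <- sum(!ok)
    frac <- mm / length(idx)
    if (frac < best$frac - 1e-12) {
      best <- list(shift = s, mismatches = mm, frac = frac,
                   overlap = length(idx))
    }
  }
  best
}

#' Map a specimen sequence onto a reference segment
#'
#' Exhaustively scans shifts in `[-max_shift, max_shift]` and selects the
#' one minimising the mismatch fraction, counting IUPAC-compatible bases
#' as matches. When `indel_window` (a gene-frame interval) is supplied,
#' the read is additionally scanned in two pieces split at the window
#' start; a downstream piece that fits markedly better at a different,
#' nearby shift flags a suspected indel, with the deletion length
#' recoverable as `shift - shift_downstream`.
#'
#' @param seq Nucleotide string (IUPAC codes allowed), length >= 40.
#' @param ref A [ref_segment()].
#' @param indel_window Optional gene-frame interval `c(start, end)` where
#'   an indel may occur.
#' @param max_shift Scan half-range (default 30).
#' @param max_mismatch_frac Mapping acceptance ceiling (default 0.30);
#'   reads that fit nowhere below it are rejected as unmappable.
#' @return A `position_map` list: `segment`, `shift`, `mismatches`,
#'   `mismatch_frac`, `overlap`, `indel_suspected`, `shift_downstream`,
#'   `split_at` (seq index where the downstream piece starts, or `NA`).
#' @export
map_to_reference <- function(seq, ref, indel_window = NULL, max_shift = 30L,
                             max_mismatch_frac = 0.30) {
  seq <- toupper(seq)
  if (nchar(seq) < 40L) abort("sequence shorter than 40 bases")
  seq_ch <- strsplit(seq, "")[[1]]
  ref_ch <- strsplit(ref$sequence, "")[[1]]
  shifts <- seq.int(-max_shift, max_shift)

  colinear <- scan_shifts(seq_ch, ref_ch, 1L, length(seq_ch), shifts)

  out <- list(segment = ref$name, shift = colinear$shift,
              mismatches = colinear$mismatches,
              mismatch_frac = colinear$frac, overlap = colinear$overlap,
              indel_suspected = FALSE, shift_downstream = NA_integer_,
              split_at = NA_integer_)

  if (!is.null(indel_window)) {
    s_up <- colinear$shift
    # upstream piece ends where the window starts in read coordinates
    split_i <- indel_window[1] - ref$offset + 1L + ifelse(is.na(s_up), 0L, s_up)
    up <- scan_shifts(seq_ch, ref_ch, 1L, split_i - 1L, shifts)
    if (!is.na(up$shift)) {
      split_i <- indel_window[1] - ref$offset + 1L + up$shift
      down <- scan_shifts(seq_ch, ref_ch, split_i, length(seq_ch),
                          shifts, min_overlap = 20L)
      if (!is.na(down$shift) && down$shift != up$shift &&
          abs(down$shift - up$shift) <= 10L) {
        # require the alternative downstream frame to be a real improvement
        at_up <- scan_shifts(seq_ch, ref_ch, split_i, length(seq_ch),
                             up$shift, min_overlap = 20L)
        if (is.infinite(at_up$frac) || down$frac + 0.20 < at_up$frac) {
          out$indel_suspected <- TRUE
          out$shift <- up$shift
          out$mismatches <- up$mismatches + down$mismatches
          out$mismatch_frac <- (up$mismatches + down$mismatches) /
            (up$overlap + down$overlap)
          out$shift_downstream <- down$shift
          out$split_at <- split_i
        }
      }
    }
  }

  if (!out$indel_suspected &&
      (is.infinite(out$mismatch_frac) ||
       out$mismatch_frac > max_mismatch_frac)) {
    abort(sprintf("unmappable: no shift places '%s' read below %.0f%% mismatch",
                  ref$name, 100 * max_mismatch_frac),
          class = "haplomig_unmappable")
  }
  structure(out, class = "position_map")
}

#' @export
print.position_map <- function(x, ...) {
  cat(sprintf("<position_map> %s shift=%d mismatches=%d (%.1f%%)%s\n",
              x$segment, x$shift, x$mismatches, 100 * x$mismatch_frac,
              if (x$indel_suspected)
                sprintf(" indel suspected (downstream shift %d)",
                        x$shift_downstream) else ""))
  invisible(x)
}

# char vector over gene-frame positions [pos_lo, pos_hi] given a co-linear
# map; NA outside the read
mapped_bases <- function(seq_ch, ref, map, positions) {
  idx <- positions - ref$offset + 1L + map$shift
  ok <- idx >= 1L & idx <= length(seq_ch)
  out <- rep(NA_character_, length(positions))
  out[ok] <- seq_ch[idx[ok]]
  out
}
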