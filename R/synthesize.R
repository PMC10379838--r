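# Synthetic cohort generator: turns a migration scenario into full
# per-specimen FASTA + metadata with ground truth, emulating the data a
# field study produces — COI haplotypes implanted at the scenario's
# destination proportions, Z-linked exon haplotypes and i65del alleles
# drawn per chromosome (two for ZZ males, one for ZW females) at the
# source allele frequency, heterozygous males rendered as direct-
# sequencing reads (IUPAC codes at exon hets; the frame-shifted ambiguity
# run downstream of a het indel), and optional private singleton variants
# at non-marker positions.

parse_haplotype_label <- function(label) {
  toks <- strsplit(label, "/", fixed = TRUE)[[1]]
  tibble(base = substr(toks, 1, 1),
         position = as.integer(substring(toks, 2)))
}

# build the sequence of one haplotype on a reference
haplotype_sequence <- function(ref, label) {
  ch <- strsplit(ref$sequence, "")[[1]]
  sp <- parse_haplotype_label(label)
  idx <- sp$position - ref$offset + 1L
  if (any(idx < 1L | idx > ref$length)) {
    abort(sprintf("haplotype '%s' has positions outside %s", label,
                  ref$name))
  }
  ch[idx] <- sp$base
  paste(ch, collapse = "")
}

# superimpose two equal-length allele strings into one direct read
merge_direct_read <- function(a, b) {
  if (a == b) return(a)
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  diffidx <- which(ac != bc)
  for (i in diffidx) ac[i] <- iupac_merge(ac[i], bc[i])
  paste(ac, collapse = "")
}

# direct read of a het indel: traces stay in register up to the deletion
# start, then the plus and (7-bp advanced) del traces superimpose
merge_het_indel_read <- function(plus_seq, del_seq, del_start_idx) {
  pc <- strsplit(plus_seq, "")[[1]]
  dc <- strsplit(del_seq, "")[[1]]
  n <- length(dc)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (i < del_start_idx) pc[i] else iupac_merge(pc[i], dc[i])
  }
  paste(out, collapse = "")
}

#' Synthesize a full study cohort from a migration scenario
#'
#' Generates `n_source_collections` southern collections sampled directly
#' from the source plus `scenario$n_destinations` northern collections
#' produced by founder events, writes (optionally) specimen FASTA,
#' metadata CSV and a ground-truth CSV, and returns everything in memory.
#'
#' @param scenario A [migration_scenario()].
#' @param refs Named list of [ref_segment()]s (default: the bundled
#'   synthetic references).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param n_source_collections Southern (direct-source) collections.
#' @param segments Segments to synthesize.
#' @param i65_window,del_length Intron deletion location and length.
#' @param south_states,north_states State labels cycled over the two
#'   collection sets.
#' @param year Collection year recorded in metadata.
#' @return List: `specimens` (as from [read_specimens()]), `truth`
#'   (per-specimen ground-truth tibble), `counts` (per-collection true
#'   haplotype counts), `paths` (written files or `NULL`).
#' @export
synthesize_cohort <- function(scenario, refs = read_reference_set(),
                              out_dir = NULL, n_source_collections = 0L,
                              segments = c("sCOIB", "sTpiE", "sTpi140"),
                              i65_window = c(65L, 71L), del_length = 7L,
                              south_states = c("TX", "LA", "MS", "GA",
                                               "FL", "AL"),
                              north_states = c("KS", "TN", "VA", "NC",
                                               "SC"),
                              year = 2019L) {
  src <- scenario$source
  set.seed(scenario$seed)

  hap_labels <- names(src$coib_freqs)
  ref_coib <- refs[["sCOIB"]]
  coib_seqs <- vapply(hap_labels, haplotype_sequence, "", ref = ref_coib)

  tpie_labels <- names(src$tpie_freqs)
  ref_tpie <- refs[["sTpiE"]]
  tpie_seqs <- vapply(tpie_labels, haplotype_sequence, "", ref = ref_tpie)

  ref_int <- refs[["sTpi140"]]
  plus_seq <- ref_int$sequence
  w1 <- i65_window[1] - ref_int$offset + 1L
  del_seq <- paste0(substr(plus_seq, 1L, w1 - 1L),
                    substr(plus_seq, w1 + del_length,
                           nchar(plus_seq)))

  coll <- tibble(
    collection_id = c(
      sprintf("%s-S%02d", rep_len(south_states,
                                  n_source_collections),
              seq_len(max(n_source_collections, 0L))),
      sprintf("%s-N%02d", rep_len(north_states,
                                  scenario$n_destinations),
              seq_len(scenario$n_destinations))),
    state = c(rep_len(south_states, n_source_collections),
              rep_len(north_states, scenario$n_destinations)),
    kind = c(rep("source", n_source_collections),
             rep("destination", scenario$n_destinations)))

  seq_rows <- list(); meta_rows <- list(); truth_rows <- list()
  count_rows <- list()
  spec_counter <- 0L

  for (ci in seq_len(nrow(coll))) {
    if (coll$kind[ci] == "source" || is.infinite(scenario$n_founders)) {
      counts <- setNames(as.integer(
        rmultinom(1, scenario$n_sampled, src$coib_freqs)), hap_labels)
    } else {
      founders <- sample_founders(src, scenario$n_founders)
      counts <- expand_and_sample(founders, scenario)
    }
    count_rows[[ci]] <- tibble(collection_id = coll$collection_id[ci],
                               state = coll$state[ci],
                               haplotype = hap_labels,
                               n = as.integer(counts))
    haps <- rep(hap_labels, counts)
    n <- length(haps)
    ids <- sprintf("SP%05d", spec_counter + seq_len(n))
    spec_counter <- spec_counter + n
    male <- stats::runif(n) < scenario$sex_ratio

    for (si in seq_len(n)) {
      id <- ids[si]
      out_seqs <- list()
      if ("sCOIB" %in% segments) {
        out_seqs[["sCOIB"]] <- coib_seqs[[haps[si]]]
      }
      te_lab <- NA_character_
      if ("sTpiE" %in% segments) {
        if (male[si]) {
          two <- sample(tpie_labels, 2L, replace = TRUE,
                        prob = src$tpie_freqs)
          out_seqs[["sTpiE"]] <- merge_direct_read(tpie_seqs[[two[1]]],
                                                   tpie_seqs[[two[2]]])
          te_lab <- paste(sort(two), collapse = "+")
        } else {
          one <- sample(tpie_labels, 1L, prob = src$tpie_freqs)
          out_seqs[["sTpiE"]] <- tpie_seqs[[one]]
          te_lab <- one
        }
      }
      i65 <- NA_character_
      if ("sTpi140" %in% segments) {
        n_al <- if (male[si]) 2L else 1L
        dels <- stats::runif(n_al) < src$i65del_freq
        i65 <- if (all(dels)) "del" else if (!any(dels)) "plus" else "het"
        out_seqs[["sTpi140"]] <- switch(
          i65,
          del = del_seq, plus = plus_seq,
          het = merge_het_indel_read(plus_seq, del_seq, w1))
      }
      seq_rows[[length(seq_rows) + 1L]] <- tibble(
        specimen_id = id, segment = names(out_seqs), allele = 1L,
        sequence = unlist(out_seqs, use.names = FALSE))
      meta_rows[[length(meta_rows) + 1L]] <- tibble(
        specimen_id = id, collection_id = coll$collection_id[ci],
        state = coll$state[ci], year = year,
        source_type = "field_larva",
        sex_ploidy = if (male[si]) "ZZ_male" else "Z_hemizygous_female")
      truth_rows[[length(truth_rows) + 1L]] <- tibble(
        specimen_id = id, collection_id = coll$collection_id[ci],
        state = coll$state[ci], coib_haplotype = haps[si],
        tpie_haplotype = te_lab, i65_status = i65,
        male = male[si])
    }
  }

  seqs <- bind_rows(seq_rows)
  meta <- bind_rows(meta_rows)
  truth <- bind_rows(truth_rows)
  counts_tbl <- bind_rows(count_rows)

  # private singleton variants: distinct non-marker positions, each in
  # exactly one specimen, so every injected variant is a true singleton
  if (src$singleton_rate > 0 && "sCOIB" %in% segments) {
    marker_pos <- unique(unlist(lapply(hap_labels, function(l)
      parse_haplotype_label(l)$position)))
    cand <- setdiff(seq_len(ref_coib$length),
                    marker_pos - ref_coib$offset + 1L)
    coib_rows <- which(seqs$segment == "sCOIB")
    n_events <- rbinom(1, length(coib_rows) * length(cand),
                       src$singleton_rate)
    n_events <- min(n_events, length(cand))
    if (n_events > 0L) {
      ev_pos <- sample(cand, n_events)
      ev_row <- sample(coib_rows, n_events, replace = TRUE)
      sing <- list()
      for (e in seq_len(n_events)) {
        s <- seqs$sequence[ev_row[e]]
        old <- substr(s, ev_pos[e], ev_pos[e])
        new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        substr(s, ev_pos[e], ev_pos[e]) <- new
        seqs$sequence[ev_row[e]] <- s
        sing[[e]] <- tibble(specimen_id = seqs$specimen_id[ev_row[e]],
                            segment = "sCOIB",
                            position = ev_pos[e] + ref_coib$offset - 1L,
                            ref = old, alt = new)
      }
      truth_singletons <- bind_rows(sing)
    } else {
      truth_singletons <- tibble(specimen_id = character(),
                                 segment = character(),
                                 position = integer(), ref = character(),
                                 alt = character())
    }
  } else {
    truth_singletons <- tibble(specimen_id = character(),
                               segment = character(), position = integer(),
                               ref = character(), alt = character())
  }

  collections <- meta %>%
    group_by(.data$collection_id, .data$state, .data$year,
             .data$source_type) %>%
    summarise(n_specimens = dplyr::n(), .groups = "drop")
  specimens <- list(sequences = seqs, meta = meta,
                    collections = collections)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(fasta = file.path(out_dir, "specimens.fasta"),
                  meta = file.path(out_dir, "metadata.csv"),
                  truth = file.path(out_dir, "truth.csv"),
                  counts = file.path(out_dir, "true_counts.csv"))
    write_specimens(specimens, paths$fasta, paths$meta)
    readr::write_csv(truth, paths$truth)
    readr::write_csv(counts_tbl, paths$counts)
  }

  list(specimens = specimens, truth = truth, counts = counts_tbl,
       singletons = truth_singletons, paths = paths)
}
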