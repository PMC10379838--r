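# Config-driven pipeline: simulate -> call -> analyze -> power.
#
# One YAML config drives every stage; every artifact CSV starts with a
# provenance comment (tool version, config hash, seed) and rerunning a
# stage with the same config and seed reproduces identical bytes.

default_config <- function() {
  list(
    seed = 1L,
    outdir = "haplomig_out",
    refs = NULL, # NULL = bundled synthetic references
    specimens = list(fasta = NULL, meta = NULL),
    segments = list(mito = "sCOIB", exon = "sTpiE", intron = "sTpi140"),
    thresholds = list(snp_threshold = 0.10, het_run_length = 20L,
                      max_mismatch_frac = 0.30),
    tpi_mode = "half_weight",
    test_variant = "pooled",
    focal = "C1035/T1272",
    contrast = "T1035/C1272",
    i65_window = c(65L, 71L),
    del_length = 7L,
    scenario = list(n_founders = 50L, n_destinations = 10L,
                    n_source_collections = 10L, n_sampled = 50L,
                    sex_ratio = 0.5,
                    source = list(singleton_rate = 0)),
    power = list(founder_sizes = c(5L, 50L, 500L), replicates = 200L,
                 alpha = 0.05)
  )
}

#' Read a pipeline run configuration
#'
#' Reads a YAML file and merges it over the package defaults. Referenced
#' input paths are checked at validation time.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides Named list merged over the file values (e.g. from
#'   command-line flags).
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file '%s' not found", path))
    cfg <- modifyList(cfg, yaml::read_yaml(path))
  }
  if (length(overrides) > 0L) cfg <- modifyList(cfg, overrides)
  cfg$seed <- as.integer(cfg$seed)
  if (!cfg$tpi_mode %in% c("half_weight", "carrier")) {
    abort("tpi_mode must be half_weight or carrier")
  }
  if (!cfg$test_variant %in% c("pooled", "welch")) {
    abort("test_variant must be pooled or welch")
  }
  for (field in c("fasta", "meta")) {
    p <- cfg$specimens[[field]]
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("specimens$%s path '%s' does not exist", field, p))
    }
  }
  if (!is.null(cfg$refs) && !file.exists(cfg$refs)) {
    abort(sprintf("refs path '%s' does not exist", cfg$refs))
  }
  structure(cfg, class = "run_config")
}

# hash of the scientific configuration: the output location does not
# change what is computed, so it is excluded
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL
  digest::digest(cfg, algo = "sha1")
}

provenance_header <- function(config) {
  sprintf("# haplomig %s config=%s seed=%d",
          as.character(utils::packageVersion("haplomig")),
          config_hash(config), config$seed)
}

write_artifact <- function(df, path, config) {
  writeLines(provenance_header(config), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read back a pipeline artifact CSV (skipping the provenance header)
#' @param path CSV written by a pipeline stage.
#' @return Tibble.
#' @export
read_artifact <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

load_refs <- function(config) {
  if (is.null(config$refs)) read_reference_set()
  else read_reference_set(config$refs)
}

source_from_config <- function(config) {
  sc <- config$scenario$source
  args <- list()
  if (!is.null(sc$name)) args$name <- sc$name
  if (!is.null(sc$coib_freqs)) args$coib_freqs <- unlist(sc$coib_freqs)
  if (!is.null(sc$i65del_freq)) args$i65del_freq <- sc$i65del_freq
  if (!is.null(sc$tpie_freqs)) args$tpie_freqs <- unlist(sc$tpie_freqs)
  if (!is.null(sc$singleton_rate)) {
    args$singleton_rate <- sc$singleton_rate
  }
  do.call(source_population, args)
}

scenario_from_config <- function(config) {
  sc <- config$scenario
  migration_scenario(source_from_config(config),
                     n_founders = sc$n_founders,
                     n_destinations = sc$n_destinations,
                     n_sampled = sc$n_sampled,
                     sex_ratio = sc$sex_ratio,
                     seed = config$seed)
}

#' Pipeline stage: synthesize a cohort
#'
#' Writes `simulate/` under the configured outdir: specimen FASTA,
#' metadata, ground truth, true counts and a manifest with the config
#' hash. Refuses to overwrite an existing non-empty stage directory
#' unless `force = TRUE`.
#'
#' @param config A [read_run_config()] result.
#' @param force Overwrite an existing stage directory.
#' @return Invisibly, the [synthesize_cohort()] result.
#' @export
pipeline_simulate <- function(config, force = FALSE) {
  stage <- file.path(config$outdir, "simulate")
  if (dir.exists(stage) && length(list.files(stage)) > 0L && !force) {
    abort(sprintf("output directory '%s' exists; use force = TRUE", stage))
  }
  dir.create(stage, recursive = TRUE, showWarnings = FALSE)
  res <- synthesize_cohort(
    scenario_from_config(config), refs = load_refs(config),
    out_dir = stage,
    n_source_collections = config$scenario$n_source_collections,
    i65_window = as.integer(config$i65_window),
    del_length = config$del_length)
  manifest <- list(stage = "simulate", config_hash = config_hash(config),
                   seed = config$seed,
                   files = sort(basename(unlist(res$paths))))
  yaml::write_yaml(manifest, file.path(stage, "manifest.yaml"))
  invisible(res)
}

#' Pipeline stage: discover SNPs and call haplotypes/genotypes
#'
#' Reads the configured specimen FASTA + metadata (defaulting to the
#' `simulate/` stage output), discovers SNPs on the mitochondrial
#' segment, selects marker sites at the configured threshold, calls
#' per-specimen haplotypes and Tpi genotypes, and writes `calls/`:
#' `snp_summary.csv` (site, n, polymorphism, frequency), `haplotype_calls.csv`,
#' `tpi_calls.csv`.
#'
#' @param config A [read_run_config()] result.
#' @return Invisibly, a list: `sites`, `selected`, `calls`, `tpi`.
#' @export
pipeline_call <- function(config) {
  fasta <- config$specimens$fasta %||%
    file.path(config$outdir, "simulate", "specimens.fasta")
  meta <- config$specimens$meta %||%
    file.path(config$outdir, "simulate", "metadata.csv")
  if (!file.exists(fasta) || !file.exists(meta)) {
    abort("no specimen inputs: configure specimens$fasta/meta or run pipeline_simulate first")
  }
  refs <- load_refs(config)
  specimens <- read_specimens(fasta, meta)
  mito <- config$segments$mito
  sites <- discover_snps(specimens, mito, refs[[mito]])
  selected <- select_marker_sites(sites, config$thresholds$snp_threshold)
  if (nrow(selected) == 0L) {
    abort("no marker sites exceed the selection threshold",
          class = "haplomig_data_quality")
  }
  calls <- call_haplotypes(specimens, mito, selected, refs[[mito]])
  if (!any(calls$status == "resolved")) {
    abort("zero resolvable specimens", class = "haplomig_data_quality")
  }
  tpi <- call_tpi(specimens, refs,
                  i65_window = as.integer(config$i65_window),
                  del_length = config$del_length,
                  exon_segment = config$segments$exon,
                  intron_segment = config$segments$intron,
                  het_run_length = config$thresholds$het_run_length)

  stage <- file.path(config$outdir, "calls")
  dir.create(stage, recursive = TRUE, showWarnings = FALSE)
  snp_summary <- sites %>%
    mutate(snp = sprintf("%s_%d", .data$segment, .data$position),
           polymorphism = paste(.data$major, .data$minor, sep = "/"),
           selected = .data$position %in% selected$position) %>%
    select("snp", n = "n_scored", "polymorphism",
           frequency = "minor_frequency", "singleton", "selected")
  write_artifact(snp_summary, file.path(stage, "snp_summary.csv"), config)
  write_artifact(calls, file.path(stage, "haplotype_calls.csv"), config)
  write_artifact(tpi, file.path(stage, "tpi_calls.csv"), config)
  invisible(list(sites = sites, selected = selected, calls = calls,
                 tpi = tpi, specimens = specimens))
}

#' Pipeline stage: frequency tables, M and regional comparisons
#'
#' Consumes the `calls/` stage outputs and writes `analysis/`: haplotype
#' frequencies by state and year, per-collection M, the regional
#' comparison report (both schemes), and the per-specimen i65del allele
#' frequency.
#'
#' @param config A [read_run_config()] result.
#' @return Invisibly, a list: `freq`, `m_tbl`, `report`, `tpi_freq`.
#' @export
pipeline_analyze <- function(config) {
  stage_in <- file.path(config$outdir, "calls")
  calls_p <- file.path(stage_in, "haplotype_calls.csv")
  tpi_p <- file.path(stage_in, "tpi_calls.csv")
  meta_p <- config$specimens$meta %||%
    file.path(config$outdir, "simulate", "metadata.csv")
  if (!file.exists(calls_p)) abort("run pipeline_call first")
  calls <- read_artifact(calls_p)
  tpi <- read_artifact(tpi_p)
  meta <- readr::read_csv(meta_p, show_col_types = FALSE)

  freq <- frequency_table(calls, meta, group_by = c("state", "year"))
  m_tbl <- frequency_table(calls, meta,
                           group_by = c("collection_id", "state")) %>%
    m_table(config$focal, config$contrast)

  schemes <- list(region_scheme_east_west(), region_scheme_north_south())
  report_rows <- lapply(schemes, function(sch) {
    res <- tryCatch(
      regional_compare(m_tbl, sch, variant = config$test_variant),
      error = function(e) {
        warn(sprintf("regional test skipped for %s: %s", sch$name,
                     conditionMessage(e)))
        NULL
      })
    if (is.null(res)) return(NULL)
    tibble(scheme = sch$name,
           group1 = res$groups$group[1], n1 = res$groups$n[1],
           mean1 = res$groups$mean[1], sd1 = res$groups$sd[1],
           group2 = res$groups$group[2], n2 = res$groups$n[2],
           mean2 = res$groups$mean[2], sd2 = res$groups$sd[2],
           t = res$statistic, df = res$df,
           p = round(res$p_value, 4))
  })
  report <- bind_rows(report_rows)
  tpi_freq <- tpi_allele_frequency(tpi, mode = config$tpi_mode)

  stage <- file.path(config$outdir, "analysis")
  dir.create(stage, recursive = TRUE, showWarnings = FALSE)
  write_artifact(freq, file.path(stage, "haplotype_frequencies.csv"),
                 config)
  write_artifact(m_tbl, file.path(stage, "m_by_collection.csv"), config)
  if (nrow(report) > 0L) {
    write_artifact(report, file.path(stage, "regional_report.csv"), config)
  }
  write_artifact(tpi_freq, file.path(stage, "tpi_frequency.csv"), config)
  invisible(list(freq = freq, m_tbl = m_tbl, report = report,
                 tpi_freq = tpi_freq))
}

#' Pipeline stage: founder-size power analysis
#'
#' @param config A [read_run_config()] result.
#' @return Invisibly, the [run_power_analysis()] grid.
#' @export
pipeline_power <- function(config) {
  pw <- config$power
  grid <- run_power_analysis(
    source_from_config(config),
    founder_sizes = pw$founder_sizes, replicates = pw$replicates,
    alpha = pw$alpha,
    n_collections = config$scenario$n_destinations,
    n_sampled = config$scenario$n_sampled,
    focal = config$focal, contrast = config$contrast,
    seed = config$seed)
  stage <- file.path(config$outdir, "power")
  dir.create(stage, recursive = TRUE, showWarnings = FALSE)
  write_artifact(grid, file.path(stage, "power_table.csv"), config)
  invisible(grid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
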