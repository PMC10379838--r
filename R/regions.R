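# Regional grouping schemes and the regional M comparison.
#
# Two schemes mirror the study design for the continental US:
#  * East/West — Atlantic-coast states (east of the Appalachians) vs
#    states to the west, probing whether the two overwintering sources
#    (FL vs TX) leave distinct haplotype signatures along their
#    respective migratory corridors.
#  * North/South — Gulf-bordering states (the overwintering zone) vs the
#    northern migratory destinations, probing whether migration preserves
#    the source haplotype proportions.
# Puerto Rico is excluded from both by default (island population,
# outside the continental migration system).

#' Construct a regional grouping scheme
#'
#' @param name Scheme label.
#' @param mapping Named character vector: state -> group.
#' @param excluded States deliberately outside the scheme.
#' @return A `region_scheme` object.
#' @export
region_scheme <- function(name, mapping, excluded = "PR") {
  structure(list(name = name, mapping = mapping, excluded = excluded),
            class = "region_scheme")
}

#' @rdname region_scheme
#' @export
region_scheme_east_west <- function() {
  region_scheme("East/West", c(
    FL = "East", GA = "East", SC = "East", NC = "East", VA = "East",
    TX = "West", LA = "West", MS = "West", KS = "West", TN = "West",
    AL = "West"))
}

#' @rdname region_scheme
#' @export
region_scheme_north_south <- function() {
  region_scheme("North/South", c(
    KS = "North", TN = "North", VA = "North", NC = "North", SC = "North",
    TX = "South", LA = "South", MS = "South", GA = "South", FL = "South",
    AL = "South"))
}

#' @export
print.region_scheme <- function(x, ...) {
  cat(sprintf("<region_scheme> %s\n", x$name))
  for (g in unique(x$mapping)) {
    cat(sprintf("  %s: %s\n", g,
                paste(names(x$mapping)[x$mapping == g], collapse = ", ")))
  }
  if (length(x$excluded)) {
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare per-collection M between two regions
#'
#' Maps each group-level M value to its region under `scheme` and runs an
#' unpaired two-tailed t-test between the two region samples. A state that
#' is neither mapped nor explicitly excluded is an error (the scheme must
#' account for all data); excluded states are dropped silently.
#'
#' @param m_tbl Tibble from [m_table()] with a `state` column (one row
#'   per collection-level group).
#' @param scheme A [region_scheme()].
#' @param variant t-test variant, `"pooled"` (default) or `"welch"`.
#' @return An `hm_htest` with per-region summaries and an added
#'   `region_data` tibble (state, m, region).
#' @export
regional_compare <- function(m_tbl, scheme,
                             variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (!"state" %in% names(m_tbl)) abort("m_tbl must carry a 'state' column")
  unmapped <- setdiff(unique(m_tbl$state),
                      c(names(scheme$mapping), scheme$excluded))
  if (length(unmapped) > 0L) {
    abort(sprintf("state(s) not covered by scheme '%s': %s", scheme$name,
                  paste(unmapped, collapse = ", ")))
  }
  dat <- m_tbl %>%
    filter(!.data$state %in% scheme$excluded) %>%
    mutate(region = unname(scheme$mapping[.data$state]))
  if (nrow(dat) == 0L) {
    abort(sprintf("all groups excluded under scheme '%s'", scheme$name))
  }
  sides <- split(dat$m, dat$region)
  if (length(sides) < 2L || any(lengths(sides) < 2L)) {
    abort(sprintf(
      "scheme '%s' needs at least two groups per region (got %s)",
      scheme$name,
      paste(names(sides), lengths(sides), sep = "=", collapse = ", ")))
  }
  res <- two_sample_t(sides[[1]], sides[[2]], variant = variant)
  res$method <- sprintf("%s M comparison (%s t, two-tailed)",
                        scheme$name, variant)
  res$groups$group <- names(sides)
  res$region_data <- dat
  res
}
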