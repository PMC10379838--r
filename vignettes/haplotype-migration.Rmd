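---
title: "Inferring moth migratory structure from haplotype proportions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring moth migratory structure from haplotype proportions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplomig)
library(dplyr)
```

## The problem

Long-distance migratory moths such as the soybean looper overwinter only
where winters are mild (southern Texas, Florida, the Caribbean) and
recolonise the continent every growing season. Because migrants mix
extensively, populations rarely carry private alleles; what persists are
*differences in the proportions* of haplotypes that every population
shares. `haplomig` implements a complete proportion-based workflow for
Sanger-style amplicon data:

1. **Marker discovery and calling** — SNP discovery on a mitochondrial
   COI segment, per-specimen haplotype calls at selected marker sites,
   and genotyping of a Z-linked *Tpi* exon and a 7-bp intron deletion
   (`i65del`), including the heterozygous-indel artifact of direct
   sequencing.
2. **Population statistics** — per-group haplotype frequency tables, the
   M haplotype-ratio statistic, and the regional comparisons (chi-square
   against uniform, unpaired two-tailed t-tests, one-way ANOVA with
   Tukey's HSD).
3. **A founder-effect migration simulator** that doubles as the
   package's synthetic-data generator, so the whole pipeline is testable
   end-to-end with known ground truth.

## The M statistic and its model

For the two predominant haplotypes of a group with counts $n_A$ and
$n_B$,

$$M = \frac{n_A - n_B}{n_A + n_B} \in [-1, 1].$$

M depends only on the ratio of the two dominant haplotypes, which makes
it comparable across collections of very different size; it is
antisymmetric under swapping the pair and invariant under scaling both
counts. The biological reading: if migration moves groups large enough
to be representative, destination M resembles source M; if migration
proceeds through small founder groups, destination M scatters around the
source value.

That intuition is made quantitative by a two-stage sampling model. A
founder group of $n_f$ individuals is one multinomial draw from the
source haplotype frequencies; the destination then expands at exactly
the founder proportions, and $n_s$ specimens are genotyped from it. For
any single haplotype frequency $p$ this yields

$$\mathrm{Var}(\hat p) = p(1-p)\left(\frac{1}{n_f} + \frac{1}{n_s}
  - \frac{1}{n_f n_s}\right) \approx
  p(1-p)\left(\frac{1}{n_f} + \frac{1}{n_s}\right),$$

the founder term dominating once $n_f \ll n_s$ fails to hold. The
simulator implements exactly this model (`sample_founders()`,
`expand_and_sample()`), with optional Wright–Fisher resampling between
the founder event and the census for users who want explicit
generations; the default is the pure two-stage form because it has the
closed-form variance above, which the test-suite verifies to within
Monte-Carlo error.

## Calling rules and their rationale

**Marker selection.** A site becomes a candidate SNP when at least two
distinct unambiguous bases are observed; it becomes a *marker* site when
its minor-variant frequency, pooled across all collections and computed
per specimen, strictly exceeds the selection threshold (default
`0.10`). The inequality is strict — a site at exactly 10% is excluded —
and variants observed in exactly one specimen (singletons) are never
selectable regardless of frequency, since a frequency estimated from one
observation carries no population signal and such variants behave as
noise.

**Per-specimen frequencies.** Mitochondrial segments are haploid, so per
specimen and per chromosome coincide. For the Z-linked *Tpi*, males (ZZ)
carry two copies: a heterozygous male counts as carrying both alleles
but contributes *one* specimen to the tally. For the i65del allele
frequency two conventions are offered: `half_weight` (het = 0.5, the
default, equivalent to per-chromosome counting under the two-draw model)
and `carrier` (het = 1, "any carrier counts"). Both are exposed because
"per specimen" is genuinely ambiguous for heterozygotes; the default is
the one that keeps the estimator unbiased for the underlying allele
frequency.

**Ambiguity.** An IUPAC code at a mitochondrial marker site invalidates
the whole segment call (`unresolved_ambiguity`) rather than producing a
partial haplotype: a single maternally inherited haplotype is expected,
so a mixed base is read failure, not heteroplasmy (which is not
modelled). On *Tpi*, two-base codes in a direct read are legitimate
heterozygous calls — for males. A heterozygous signal on a hemizygous
female is biologically impossible and is downgraded to `unknown` with a
warning.

**Mapping.** Amplicons from fixed primers are treated as co-linear with
the reference: an exhaustive scan over shifts in ±30 selects the
minimum-mismatch placement (IUPAC-compatible bases count as matches),
with ties resolved toward the smallest absolute shift. Reads that fit
nowhere below a 30% mismatch ceiling are rejected as unmappable. A full
gapped aligner is deliberately avoided — the only indel the assay cares
about lives in a declared window, where a split scan recovers it: a
downstream region fitting best at `upstream shift − 7` is a clean 7-bp
deletion.

**Heterozygous indels.** Direct sequencing of a del/plus male
superimposes two traces that fall out of frame at the deletion start,
producing a sustained run of mixed positions. The detector requires an
ambiguity beginning inside the indel window followed by a run of at
least 20 bases in which ≥ 50% of positions are ambiguous or mismatched.
The run length and fraction are tunable (`het_run_length`,
`het_run_frac`); the defaults are conservative enough that point
ambiguities never trigger the het call, while a true frame offset
(expected ≈ 75% mixed positions for diverged frames) always does.

## Regional comparisons

The unit of analysis is the collection-level M (one value per
collection, grouped by collection and state); region membership is a
`region_scheme` mapping states to two sides, with Puerto Rico excluded
by default from both bundled schemes (East/West across the Appalachians;
North/South at the Gulf-adjacent line). A state present in the data but
neither mapped nor excluded is an error, not a silent drop. The t-test
defaults to the classic pooled-variance form with $df = n_1 + n_2 - 2$
(Welch is a flag away); groups where both focal and contrast counts are
zero have undefined M and are dropped with a warning rather than
imputed. p-values are reported to four decimals in the pipeline report
and no multiple-testing correction is applied beyond Tukey's HSD where
that test is used.

The compact letter display over Tukey's pairwise p-values uses the
insert-and-absorb algorithm: groups sharing a letter are not
significantly different at the family-wise level.

## What the generator emulates — and what it does not

`synthesize_cohort()` turns a `migration_scenario` into specimen FASTA +
metadata + ground truth. Its defaults define the study conditions used
throughout the tests:

* **COI haplotype pool**: four haplotypes at frequencies
  (0.68, 0.27, 0.04, 0.01) for `C1035/T1272`, `T1035/C1272`,
  `T1035/T1272`, `C1035/C1272` — a dominant pair at roughly 2.5:1 with
  the third haplotype about three-fold the fourth, matching the observed
  ~67/33 and ~68/32 site-level splits of the marker SNPs.
* **i65del allele frequency** 0.16, the overall mean observed for this
  marker; males draw two alleles and females one at the same frequency
  (no sex-specific frequencies — the simplest model consistent with
  Z-linkage).
* **Tpi exon pool**: a 90/10 two-haplotype mixture, placing the exon's
  most variable site exactly at the selection threshold so exon SNPs
  are discovered but *not* selected — the behaviour expected of this
  marker class.
* **Singleton noise**: private variants at a configurable per-site,
  per-specimen rate (0 by default), placed at distinct non-marker
  positions so that every injected variant is a true singleton. This
  keeps marker recovery exact while exercising the singleton-flagging
  logic.
* **Direct-read artifacts**: heterozygous males are rendered as a
  single merged trace — IUPAC codes at exon hets, and the frame-shifted
  ambiguity run downstream of a het indel.

The generator does **not** emulate chromatogram quality decay, primer
sequence, PCR drop-out, contamination, heteroplasmy, or recombination;
passing tests therefore demonstrate correctness of the calling logic
and the statistics under clean-to-moderately-noisy reads, not
robustness to every failure mode of real Sanger data.

## Numerical and design choices

* Coordinates are 1-based in a named gene frame carried by each
  reference segment's `offset`; marker names like `sCOIB_1035` read
  directly off this frame.
* Haplotype labels are canonicalised as
  `<base><position>/<base><position>` sorted by position.
* Degenerate inputs fail loudly: zero mappable specimens, all-unknown
  i65 status, both-zero M counts, zero within-group variance in ANOVA
  are all errors (or logged drops), never silent NAs.
* Tie-breaks in mapping prefer shift 0, then the smaller absolute
  shift, then the smaller signed shift — deterministic by construction.
* Every pipeline artifact begins with a provenance comment (package
  version, configuration hash, seed); the hash excludes the output
  directory, so the same scientific configuration writes byte-identical
  artifacts wherever it is run. All randomness flows from the single
  scenario seed.

## Problem sizes used in validation

The bundled checks run at sizes chosen to give tight Monte-Carlo error
while remaining quick on a laptop: caller-recovery cohorts of 500
specimens across 10 collections; 2,000 replicate studies for the type-I
calibration of the regional test (10 collections per region, 100
specimens each, founder size $10^5$); 50,000 replicate destinations for
the variance-law check at founder sizes 50 and 500; and 100 seeded
batches of 2,000 replicates each for the monotone decrease of
destination-M spread across founder sizes 5–5,000.

## A worked example

```{r example}
src <- source_population()
sc <- migration_scenario(src, n_founders = 40, n_destinations = 5,
                         n_sampled = 50, seed = 424242)
cohort <- synthesize_cohort(sc, n_source_collections = 5)
refs <- read_reference_set()

sites <- discover_snps(cohort$specimens, "sCOIB", refs$sCOIB)
sel <- select_marker_sites(sites, 0.10)
sel

calls <- call_haplotypes(cohort$specimens, "sCOIB", sel, refs$sCOIB)
ft <- frequency_table(calls, cohort$specimens$meta,
                      group_by = c("collection_id", "state"))
m_tbl <- m_table(ft, "C1035/T1272", "T1035/C1272")
regional_compare(m_tbl, region_scheme_north_south())
```

With a founder size of 40 the northern M values visibly scatter; rerun
with `n_founders = 5` to watch the founder effect dominate, or with
`n_founders = 1e5` to make the two regions statistically
indistinguishable.

## Known limitations

* The mapper's ±30 scan range presumes primer-anchored amplicons; it is
  not a general aligner and will reject reads with large structural
  differences.
* Collection-level M treats collections as exchangeable replicates
  within a region; unbalanced specimen counts per collection are not
  weighted.
* The founder model collapses a full demographic history into one
  bottleneck plus optional Wright–Fisher steps; it deliberately
  estimates no founder size from data — founder size is a scenario
  parameter, not an inferred quantity.
* Exact confidence intervals for M and Bayesian alternatives are out of
  scope.
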