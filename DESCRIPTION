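Package: haplomig
Title: Haplotype-Proportion Analysis of Moth Migration from Amplicon Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers migratory population structure in noctuid moths from
    Sanger-style amplicon markers: SNP discovery and haplotype calling on
    mitochondrial COI segments, genotyping of Z-linked Tpi exon SNPs and a
    7-bp intron deletion (including heterozygous-indel artifacts in
    direct-sequencing reads), the M haplotype-ratio statistic with regional
    chi-square, t-test, ANOVA and Tukey comparisons, and a founder-effect
    migration simulator that also generates full synthetic FASTA cohorts
    with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    digest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
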