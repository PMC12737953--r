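Package: homeoscan
Title: Detection of Spontaneous Large-Scale Chromosomal Instability in
    Allotetraploid Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect spontaneous large-scale chromosomal
    instability - homeologous-exchange compositions (ABBB, AAAB, AAAA,
    BBBB) and terminal deletions - in selfed allotetraploid lineages such
    as cultivated peanut (AABB). Converts SNP-array signals to tetraploid
    allele-dosage scores (0-4), applies a control-anchored marker-filter
    cascade, calls composition events from consecutive-marker dosage runs,
    separates cohort-wide background compositions from novel events,
    traces event inheritance through a single-seed-descent pedigree, and
    computes instability rates. A companion whole-genome-sequencing module
    normalizes allele depths at subgenome-diagnostic sites against a
    synthetic-tetraploid 1:1 baseline, classifies genomic windows into
    compositions, and reconciles them with array calls (e.g. resolving
    deletions miscalled as AAAB). A synthetic-data generator reproduces
    the full experimental design (pedigree, controls, array noise, read
    sampling) with a known truth ledger so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    vcfR,
    optparse
Config/testthat/edition: 3
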