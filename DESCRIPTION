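Package: haplorigin
Title: Genome Origin Profiling and Haploid Induction Statistics for
    Doubled Haploid Breeding
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Verifies maternal haploids and detects paternal chromosome or
    segment loss from low-coverage resequencing of inducer crosses. Derives
    parent-informative SNP markers from parental variant calls (VCF), computes
    a per-bin genome origin index (GOI) in nonoverlapping 100-kb windows,
    and classifies offspring as maternal haploid, biparental diploid, or
    diploid with paternal chromosome/segment loss. Also implements
    haploid-induction-rate (HIR) screening arithmetic with exact binomial
    intervals and spontaneous chromosome-doubling categories, and ships a
    synthetic cross-and-sequencing simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
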