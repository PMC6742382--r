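Package: fnscope
Title: False-Negative and False-Positive Error Estimation for Mutation Callsets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes per-sample mutation callsets from multiple sequencing
    platforms (MAF-dialect tables), builds a high-allele-frequency truth set
    from deep targeted sequencing, and estimates possible true-positive,
    false-positive, adjusted false-positive and false-negative rates of
    database callsets against that truth set. Includes replicate consistency
    binned by mutant allele frequency, three-way callset comparison, per-gene
    false-negative profiling, CpG-island and read-count stratified statistics,
    and a synthetic multi-platform callset generator for parameter-recovery
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
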