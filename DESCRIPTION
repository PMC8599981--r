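Package: cnvburden
Title: Whole-Genome CNV Harmonization, Rare-Variant Filtering and Burden Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for post-processing copy-number-variant (CNV) callsets
    from whole-genome sequencing cohorts. Provides alignment-coverage quality
    control based on k-mer-unique (repetitive-free) reference regions,
    harmonization of per-sample callsets from multiple callers into
    non-overlapping same-type segments with conflicting-type regions removed,
    rare-CNV identification by cohort frequency exclusion and genome
    accessibility masking, case/control burden analysis with permutation
    p-values over a grid of burden features and event classes, and asymmetric
    cross-callset concordance. A synthetic-data generator produces every input
    the pipeline consumes (reference sequences, cohort CNV genotypes with
    caller observation noise, depth tracks with aneuploidy, accessibility
    masks, phenotypes with injectable burden effects) so the whole workflow is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
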