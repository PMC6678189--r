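Package: snpsseq
Title: Allele-Specific Protein-DNA Binding Analysis from SNP Oligo Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for SNPs-seq style assays, in which pools of
    short allele-pair oligo duplexes are incubated with nuclear extract and
    the protein-bound fraction is sequenced to detect allele-dependent
    protein-DNA binding. Provides candidate SNP selection from eQTL/LD
    tables, design of 21-bp allele-specific oligo template libraries with a
    GC-content exclusion, exact-match read counting with mapping and
    replicate QC, biased-allelic-binding (BAB) log2 ratio-of-ratios scoring
    with significance and treatment-overlap classification, MATCH-style
    position weight matrix core/matrix similarity scanning for
    allele-dependent motif gain or loss, a local-table annotation
    prioritization funnel, EMSA band-ratio quantification, and a seeded
    synthetic-data generator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
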