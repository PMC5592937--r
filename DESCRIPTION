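Package: hemimapper
Title: Mapping-by-Sequencing of X-Linked Recessive Mutations from Pooled
    Hemizygous Mutants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to localize X-linked recessive mutations by bulked
    segregant analysis of pooled hemizygous (XY male) mutant offspring.
    Provides a forward simulator of the mapping cross (Haldane
    recombination, pooled short-read depths, minimal VCF output), the
    variant filters applied before scanning, a dual-statistic 50-variant
    sliding-window scan (target-allele proportion and mixed-variant
    proportion), triage of candidate coding variants (frameshift,
    BLOSUM62 scoring, homopolymer context), indel calling from
    Sanger-sequenced clones of CRISPR/Cas9-edited amplicons, and the
    exact segregation statistics (binomial, Fisher, Mann-Whitney)
    used to support the mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    broom,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
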