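Package: ectamapper
Title: Mapping-by-Sequencing Analysis for C. elegans Forward Genetic Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying causal mutations from pooled-sequencing
    mapping crosses in C. elegans forward genetic screens. Simulates EMS
    mutagenesis, crosses to a polymorphic (Hawaiian-type) mapping strain and
    phenotype-based F2 selection at the allele-count level; computes
    mapping-strain SNV allele frequencies from pooled read depths; localizes
    the causal locus by per-chromosome tricube-weighted local (Loess)
    regression; builds exclusive variant lists by set subtraction and detects
    sibling strains by variant-set overlap; classifies candidate variants by
    predicted protein effect at codon level; and quantifies screen phenotypes
    (penetrance with Wilson intervals, DAPI-intensity ploidy estimation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
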