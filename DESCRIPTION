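Package: seedmir
Title: Genome-Independent Small RNA Catalogues and Cross-Kingdom miRNA Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reference-based pipeline for cataloguing microRNAs from plant
    small RNA sequencing libraries when no genome assembly is available.
    Implements adapter clipping, quality and length filtering, read collapsing,
    exact-identity subtraction of structural non-coding RNAs, conserved-miRNA
    identification by full-length identity against a mature miRNA library,
    family profiling and length distributions, a cross-species conservation
    rate, an ungapped plant-animal miRNA overlay score with seed-region
    stringency for cross-kingdom homology screening, and relative expression
    from qRT-PCR cycle thresholds by the 2^-ddCt method. Includes a
    ground-truth small RNA library simulator so every stage is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
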