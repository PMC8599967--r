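Package: plaqomics
Title: Multi-Omics Analysis of Carotid Plaque Stability on Synthetic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a multi-omics workflow for comparing
    stable and unstable carotid atherosclerotic plaques: anchor-based
    back-splice junction (circRNA) detection, lncRNA class-code assignment and
    filtering, negative-binomial differential expression of count layers and
    Welch tests on label-free proteomic intensities, cis-target and origin-gene
    interval mapping, transcriptome-proteome consistency analysis,
    hypergeometric gene-set over-representation, seed-match ceRNA network
    construction, and MCODE-style clustering of protein-protein interaction
    graphs. A synthetic-data module generates every input with planted ground
    truth so that each stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
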