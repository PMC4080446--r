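Package: epimodnet
Title: Epigenetic Network Construction and Interplay Module Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds weighted DNA-methylation and chromatin-modification
    networks over a protein-interaction background, extracts disease seed
    subnetworks, assesses them against global and degree-preserving
    permutation null models, mines dense network modules, and detects
    statistically significant interplay modules shared between the two
    epigenetic layers via the cumulative hypergeometric test. Includes a
    SAM-style moderated statistic with permutation FDR for differential
    methylation calling, ChIP-seq peak-to-promoter intensity mapping,
    methylation-expression regression with prediction intervals, and a
    synthetic-data generator that emulates all required inputs so the full
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
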