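Package: codaexplore
Title: Compositional Exploration of Sequencing Count Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Headless exploration of high-throughput sequencing count tables
    as compositions: sample/feature filtering with removal reports, zero
    handling (count-zero-multiplicative replacement or pseudocounts),
    centered log-ratio transformation, Dirichlet Monte-Carlo differential
    abundance with standardized effect sizes and expected Benjamini-Hochberg
    values, CLR-PCA biplots, Aitchison-distance hierarchical clustering,
    relative-abundance and GO-slim summaries, a synthetic count-table
    generator with known spiked fold changes, and export of commented
    scripts that reproduce every plot's underlying data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    withr,
    ape,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
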