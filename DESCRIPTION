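Package: regBeacons
Title: Regulator-Guided Discovery and Prioritization of Biosynthetic Gene
    Clusters
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies bacterial transcriptional regulators by protein
    domain architecture, quantifies the association of regulator
    subclasses with biosynthetic gene cluster (BGC) regions, and uses
    highly BGC-associated subclasses as beacons to nominate candidate
    cluster regions missed by rule-based predictors. Includes a domain
    co-occurrence network builder with a native Markov Clustering (MCL)
    implementation, a declarative subclass rule engine, in/out-BGC
    association statistics with MIBiG-style similarity filtering, a
    direct-repeat binding-site scanner, and a synthetic-genome simulator
    that generates all inputs with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
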