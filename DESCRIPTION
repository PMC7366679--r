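Package: mutlayers
Title: Multi-Layer Quantitative Proteomics of Kinase Point Mutations
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Differential analysis pipeline for studying how point mutations
    in a kinase remodel its protein interaction network (AP-MS and BioID),
    its structural topology (quantitative cross-linking mass spectrometry
    with PRM transition quantification and distance-restraint validation
    against a crystal structure), and the cellular phospho- and total
    proteome (DIA/SWATH), together with integration of the regulated
    cancer-driver proteins into an evidence-filtered reference interaction
    network. A seeded synthetic-data module generates every input table
    with planted effects so each stage can be tested by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Network, DifferentialExpression
RoxygenNote: 7.3.3
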