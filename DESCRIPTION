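Package: famflux
Title: Birth-Death-Innovation Models of Gene Family Copy-Number Evolution on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits truncated birth-death-innovation continuous-time Markov
    chain models of gene family copy-number evolution along time-calibrated
    phylogenies. Tip observations may be uncertain: qPCR copy-number
    estimates are converted to interval-threshold likelihood profiles,
    unique-sequence counts to minimum-copy profiles, and missing data to
    uninformative profiles. Supports lineage-specific rate classes,
    exhaustive scoring of a gene-category partition by model-form space with
    BIC weights, marginal ancestral copy-number reconstruction, analytic
    expected event counts on branches with model averaging, and a Gillespie
    simulator that generates study-shaped synthetic datasets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
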