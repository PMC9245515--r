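Package: colptm
Title: Motif-Constrained Identification and Quantitation of Collagen
    Post-Translational Modifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping and quantifying site-specific collagen
    post-translational modifications (3-/4-hydroxyproline, hydroxylysine and
    its O-glycosylated forms) from bottom-up proteomics data. Provides
    collagen chain annotation (Gly-Xaa-Yaa / G-X-K motif context, propeptide
    cleavage-site transfer by ortholog alignment), in-silico tryptic
    digestion with motif-constrained variable-modification enumeration, a
    transparent HCD b/y-ion spectrum matcher with target-decoy false
    discovery rate control, site-level PTM cataloging with the positional
    3-hydroxyproline assignment rule, MS1-area occupancy and lysine
    microheterogeneity statistics across experimental conditions, and a
    seeded synthetic-data generator so the whole pipeline is testable
    without raw instrument files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
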