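Package: paleofv
Title: Paleovirology of Endogenous Foamy Viruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dating endogenous retrovirus (ERV) integrations and
    testing virus-host codivergence, built around endogenous foamy viruses.
    Provides an in-frame stop-codon census for decayed proviral reading
    frames, Monte-Carlo dating of integration ages from stop-codon
    accumulation under neutral substitution, exact event-based cophylogeny
    reconciliation that maximises cospeciation events with a random
    tip-mapping permutation test, codivergence regression with iterative
    Cook's-distance outlier pruning and calibration-based node dating, and
    seeded generators of synthetic sequences, tree pairs and regression data
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phytools,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
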