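Package: ckifrags
Title: Extended Warheads and Adjacent Fragments of Covalent Kinase Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Curates kinase bioactivity tables into a covalent kinase
    inhibitor (CKI) data set, matches a prioritised library of 30
    electrophilic warhead SMARTS patterns, extracts the "adjacent
    fragments" that bridge warheads and scaffolds by traversing RECAP
    fragmentation hierarchies, and profiles the resulting fragment
    library by frequency, kinase and warhead coverage, physicochemical
    descriptors, and average-linkage clustering of Morgan fingerprint
    cosine similarities. A synthetic CKI generator with known ground
    truth makes every pipeline stage testable offline. Chemistry
    primitives are computed through a bundled RDKit batch worker.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.8) with the RDKit package on PATH as
    'python' or 'python3'
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
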