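Package: rbpprio
Title: Multi-Evidence Prioritization of Cancer-Associated RNA-Binding Proteins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative in-silico pipeline for prioritizing
    RNA-binding proteins (RBPs) with tumorigenic profiles in breast
    cancer. Combines genomic alteration-burden profiling of patient
    cohorts, ordinal immunohistochemical shift classification between
    normal and tumor tissue, confidence-filtered protein-protein
    interaction networks, loss-of-function dependency-screen
    essentiality calling, a four-criteria evidence intersection, and
    molecular-complex detection (MCODE) with protein-complex catalog
    annotation. Ships a synthetic-cohort generator with planted ground
    truth (known progressor genes and a known dense complex) so the
    whole pipeline can be exercised and validated end-to-end without
    external database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    fgsea,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
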