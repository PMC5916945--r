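Package: kinomenrich
Title: Composition-Adjusted Enrichment of Cancer Mutations and PTM Sites in Kinase Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinome-wide prioritization of protein functional domains that carry
    more cancer missense mutations and curated post-translational modification
    (PTM) sites than expected from amino-acid composition. Implements variant
    enrichment analysis (VEA) and modification enrichment analysis (MEA) as
    Poisson upper-tail tests with composition-adjusted expected counts and
    Benjamini-Hochberg false discovery rate control, an annotation-completeness
    score (omega) over a multi-resource count matrix with cross-classification
    against literature-based under-studied kinase criteria, mutation-PTM
    overlapping-site detection, per-position domain profiles, and a synthetic
    kinome generator with planted enrichment signal for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
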