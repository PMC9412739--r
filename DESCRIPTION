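Package: ginsannot
Title: Ginsenoside MS/MS Annotation, Transformation Pathways, and
    Chemometric Marker Discovery for Fermented Ginseng Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for profiling triterpene saponins (ginsenosides) in
    fermented ginseng beverages from negative-mode high-resolution
    LC-MS/MS data. Implements elemental-formula and adduct mass
    arithmetic, a curated ginsenoside knowledgebase, rule-based
    annotation of tandem spectra by glycosyl neutral-loss ladders ending
    at diagnostic aglycone ions, construction of deglycosylation
    transformation-pathway graphs, OPLS-DA with VIP scores and
    permutation validation for differential-marker selection, and
    Cytohubba-style hub ranking with hypergeometric enrichment for
    interaction networks. Includes seeded simulators for spectra,
    two-group feature tables, and interaction graphs with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
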