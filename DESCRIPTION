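Package: gotaxcon
Title: Taxon-Based Gene Ontology Constraints from Annotation Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives taxon-based Gene Ontology (GO) constraints
    ("never_in" term lists per taxonomic node) from a GO annotation
    corpus, merges them with consortium-provided taxon-constraint axioms
    and user-curated manual constraints under a strict priority scheme,
    audits annotation databases for constraint violations, and evaluates
    the effect of constraint filtering on automated function predictions
    with species-centric CAFA metrics (Fmax, weighted Fmax, Smin).
    Includes deterministic generators for synthetic ontologies,
    taxonomies and annotation files so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
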