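Package: collann
Title: Versioned Archiving and Structured Annotation of Biodiversity
    Collection Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A repository model for curating specimen and occurrence
    records from biological collections. Archives schema-based XML record
    documents (ABCD-like or simple Darwin Core dialects) under persistent
    versioned identifiers, detects revisions through an order-insensitive
    document similarity rule, and supports structured annotations of
    record elements with expectations, proposed values and comments.
    Curatorial annotations record per-element decisions on published
    annotations, and batch annotations link identical annotations across
    records. Annotations serialize to the W3C Open Annotation RDF model
    (Turtle and RDF/XML) and parse back losslessly. Includes filter-based
    querying, subscription-driven notification fan-out with an
    inspectable outbox, curator-role access control synchronized at
    import time, and a deterministic synthetic record generator for
    testing similarity and versioning behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    tibble,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
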