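Package: ppitools
Title: Tools for the Plant-Pollinator Interactions Data Standard
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read, write, validate and convert standardized plant-pollinator
    interaction data built on the Darwin Core Event/Occurrence model. Provides
    the plant-pollinator interactions (PPI) controlled vocabulary as a queryable
    term registry, an in-memory interaction dataset model with a minimal-record
    validity contract, lossless serialization as Darwin Core Archives
    (sampling-event star schema with the ExtendedMeasurementOrFact and
    ResourceRelationship extensions), as namespaced XML and as RDF
    (Turtle/N-Triples following Darwin-SW), bidirectional conversion between
    record-level interaction datasets and species-level bipartite adjacency
    networks, a deterministic synthetic fixture generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
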