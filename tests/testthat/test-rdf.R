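BASE <- "http://example.org/ppi/"

test_that("the minimal interaction maps to the expected structural triples", {
  d <- minimal_dataset()
  tr <- to_triples(d, base = BASE)
  # oracle: brute-force triple construction straight from the record tables
  at <- observed_iri_triples(tr, function(p) p == "http://purl.org/dsw/atEvent")
  expect_equal(at, expected_atevent_triples(d, BASE))
  expect_length(at, 2)
  ro <- observed_iri_triples(tr, function(p) {
    startsWith(p, "http://purl.obolibrary.org/obo/RO_")
  })
  expect_equal(ro, expected_interaction_triples(d, BASE))
  expect_length(ro, 1)
  expect_equal(sum(tr$predicate == "http://purl.org/dc/terms/relation"), 0)
})

test_that("an empty dataset maps to an empty graph", {
  expect_equal(nrow(to_triples(ppi_dataset())), 0)
})

test_that("measurements hang off their owner with vocabulary-IRI types", {
  d <- with_measurement(minimal_dataset(), "ev1-pl", "flowerColor", "violet")
  tr <- to_triples(d, base = BASE)
  rel <- tr[tr$predicate == "http://purl.org/dc/terms/relation", ]
  expect_equal(nrow(rel), 1)
  expect_equal(rel$subject, paste0(BASE, "occurrence/ev1-pl"))
  mtype <- tr[tr$predicate == "http://rs.tdwg.org/dwc/iri/measurementType", ]
  expect_equal(mtype$object, paste0(PPI_NS, "flowerColor"))
  expect_equal(mtype$object_type, "iri")
  # value is a typed literal
  mval <- tr[tr$predicate == "http://rs.tdwg.org/dwc/terms/measurementValue", ]
  expect_equal(mval$object, "violet")
  expect_equal(mval$datatype, "http://www.w3.org/2001/XMLSchema#string")
})

test_that("free-text measurement types fall back to the literal term", {
  d <- with_measurement(minimal_dataset(), "", "wind speed", "3.5",
                        type_iri = "")
  tr <- to_triples(d, base = BASE)
  expect_equal(sum(tr$predicate ==
                     "http://rs.tdwg.org/dwc/iri/measurementType"), 0)
  lit <- tr[tr$predicate == "http://rs.tdwg.org/dwc/terms/measurementType", ]
  expect_equal(lit$object, "wind speed")
  expect_equal(lit$object_type, "literal")
})

test_that("controlled-vocabulary value IRIs serialize as xsd:anyURI literals", {
  d <- with_measurement(minimal_dataset(), "ev1-pl", "flowerOpeningType",
                        "chasmogamous")
  d$measurements$measurementValueID <-
    paste0(PPI_NS, "flowerOpeningType/chasmogamous")
  tr <- to_triples(d, base = BASE)
  mval <- tr[tr$predicate == "http://rs.tdwg.org/dwc/terms/measurementValue", ]
  expect_equal(mval$object_type, "literal")
  expect_equal(mval$datatype, "http://www.w3.org/2001/XMLSchema#anyURI")
  expect_equal(mval$object, paste0(PPI_NS, "flowerOpeningType/chasmogamous"))
})

test_that("serialization round-trips triple sets across both formats", {
  d <- generate_dataset(profile_for_seed(8))
  tr <- to_triples(d, base = BASE)
  ttl <- serialize_graph(tr, "turtle")
  nt <- serialize_graph(tr, "ntriples")
  expect_true(triples_equal(parse_graph(ttl, "turtle"), tr))
  expect_true(triples_equal(parse_graph(nt, "ntriples"), tr))
  expect_true(triples_equal(parse_graph(ttl, "turtle"),
                            parse_graph(nt, "ntriples")))
  # one statement per line in N-Triples
  lines <- strsplit(nt, "\n")[[1]]
  expect_equal(sum(nzchar(lines)), nrow(ppitools:::canonical_triples(tr)))
})

test_that("literal escaping survives serialization in both formats", {
  tr <- ppitools:::empty_triples()
  nasty <- "line1\nline2\t\"quoted\" back\\slash eé"
  tr <- ppitools:::add_triple(tr, "http://x/s", "http://x/p", nasty,
                              "literal")
  for (fmt in c("turtle", "ntriples")) {
    back <- parse_graph(serialize_graph(tr, fmt), fmt)
    expect_equal(back$object, nasty, info = fmt)
  }
})

test_that("graph reconstruction inverts the mapping up to documented lossiness", {
  for (seed in c(6, 17, 28)) {
    d <- generate_dataset(profile_for_seed(seed))
    tr <- to_triples(d, base = BASE)
    back <- from_triples(tr)
    expect_true(ppi_equal(d, back, ignore = "relationshipAccordingTo"),
                info = paste("seed", seed))
    # and the graph of the reconstruction is the original graph
    back$relationships$relationshipAccordingTo <- "restored"
    expect_true(triples_equal(to_triples(back, base = BASE), tr))
  }
})

test_that("structural defects in graphs are rejected; stray triples are ignored", {
  d <- minimal_dataset()
  tr <- to_triples(d, base = BASE)

  no_atevent <- ppitools:::as_triples(
    tr[tr$predicate != "http://purl.org/dsw/atEvent", ])
  expect_error(from_triples(no_atevent), "no dsw:atEvent")

  rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  no_event_type <- ppitools:::as_triples(
    tr[!(tr$predicate == rdf_type &
           tr$object == "http://rs.tdwg.org/dwc/terms/Event"), ])
  expect_error(from_triples(no_event_type), "Event type statement")

  extra <- ppitools:::add_triple(tr, "http://elsewhere/x",
                                 "http://elsewhere/p", "y", "literal")
  expect_message(back <- from_triples(extra), "play no role")
  expect_true(ppi_equal(d, back, ignore = "relationshipAccordingTo"))
})

test_that("relationships without an IRI type cannot become predicates", {
  d <- minimal_dataset()
  d$relationships$relationshipOfResourceID <- ""
  expect_error(to_triples(d), "rel-ev1")
  expect_message(tr <- to_triples(d, strict = FALSE), "dropping 1")
  expect_length(observed_iri_triples(tr, function(p) {
    startsWith(p, "http://purl.obolibrary.org/obo/RO_")
  }), 0)
})

test_that("structural triple counts equal record counts on random datasets", {
  for (seed in 101:110) {
    d <- generate_dataset(profile_for_seed(seed))
    tr <- to_triples(d, base = BASE)
    expect_equal(sum(tr$predicate == "http://purl.org/dsw/atEvent"),
                 nrow(d$occurrences))
    expect_equal(sum(startsWith(tr$predicate,
                                "http://purl.obolibrary.org/obo/RO_")),
                 nrow(d$relationships))
    expect_equal(sum(tr$predicate == "http://purl.org/dc/terms/relation"),
                 nrow(d$measurements))
  }
})
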