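test_that("a one-row tabular registry loads with IRI and controlled vocabulary", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "term_name,label,iri,category,definition,controlled_vocabulary",
    paste0("flowerOpeningType,Flower Opening Type,", PPI_NS,
           "flowerOpeningType,Flower,\"Whether the corolla opens\",",
           "cleistogamous; chasmogamous ;both")
  ), f)
  reg <- load_registry(f)
  t <- get_term(reg, "flowerOpeningType")
  expect_equal(t$iri, paste0(PPI_NS, "flowerOpeningType"))
  expect_equal(t$controlled_vocabulary,
               c("cleistogamous", "chasmogamous", "both"))
  expect_equal(t$category, "Flower")
  expect_equal(t$term_type, "Property")
})

test_that("registry loading rejects schema, uniqueness and category defects", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("term_name,iri,definition", "a,http://x/a,def"), f)
  expect_error(load_registry(f), "missing required column.*category")

  writeLines(c("term_name,iri,category,definition",
               "a,http://x/a,Flower,def",
               "b,http://x/a,Animal,def"), f)
  expect_error(load_registry(f), "duplicate IRI.*http://x/a")

  writeLines(c("term_name,iri,category,definition",
               "a,http://x/a,Fungus,def"), f)
  expect_error(load_registry(f), "unknown category token.*Fungus")
})

test_that("term lookup resolves by name, then IRI, and is symmetric", {
  reg <- ppi_default_registry()
  t <- get_term(reg, "flowerOpeningType")
  expect_equal(t$category, "Flower")
  expect_identical(get_term(reg, t$iri), t)
  expect_error(get_term(reg, "noSuchTerm"), "not found.*noSuchTerm")
})

test_that("controlled-value checks follow the recommendation semantics", {
  reg <- ppi_default_registry()
  fot <- get_term(reg, "flowerOpeningType")
  expect_true(validate_controlled_value(fot, "cleistogamous")$accepted)
  expect_true(validate_controlled_value(fot, "  chasmogamous ")$accepted)
  expect_false(validate_controlled_value(fot, "open")$accepted)
  expect_false(validate_controlled_value(fot, "Cleistogamous")$accepted)
  expect_true(validate_controlled_value(fot, "Cleistogamous",
                                        case_sensitive = FALSE)$accepted)
  free <- get_term(reg, "flowerColor")
  expect_true(validate_controlled_value(free, "any text")$accepted)
  expect_false(validate_controlled_value(free, "")$accepted)
})

test_that("acceptance of a value is equivalent to CV membership across the registry", {
  reg <- ppi_default_registry()
  for (t in reg$terms) {
    cv <- t$controlled_vocabulary
    if (length(cv)) {
      for (v in cv) expect_true(validate_controlled_value(t, v)$accepted)
      expect_false(validate_controlled_value(t, "not-a-cv-token")$accepted)
    } else {
      expect_true(validate_controlled_value(t, "anything")$accepted)
    }
  }
})

test_that("registry indices are bijections onto the term collection", {
  reg <- ppi_default_registry()
  expect_equal(length(reg$terms), length(reg$by_iri))
  expect_false(anyDuplicated(names(reg$terms)) > 0)
  expect_false(anyDuplicated(names(reg$by_iri)) > 0)
  expect_setequal(unname(reg$by_iri), names(reg$terms))
  for (nm in names(reg$terms)) {
    expect_identical(reg$by_iri[[reg$terms[[nm]]$iri]], nm)
  }
})

test_that("tabular export round-trips field-wise through load_registry", {
  reg <- ppi_default_registry()
  f <- withr::local_tempfile(fileext = ".csv")
  export_term_list(reg, "csv", file = f)
  reg2 <- load_registry(f, version = reg$version)
  expect_equal(reg2$terms, reg$terms)
})

test_that("structured-config (YAML) registries load like tabular ones", {
  reg <- ppi_default_registry()
  f <- withr::local_tempfile(fileext = ".yaml")
  terms <- lapply(unname(reg$terms), function(t) {
    t <- unclass(t)
    t[lengths(t) > 0 & vapply(t, function(v) any(nzchar(v)), TRUE)]
  })
  yaml::write_yaml(list(version = reg$version, terms = terms), f)
  reg2 <- load_registry(f, format = "yaml")
  expect_equal(names(reg2$terms), names(reg$terms))
  expect_equal(reg2$terms[["flowerOpeningType"]],
               reg$terms[["flowerOpeningType"]])
})

test_that("RDF export declares one rdf:Property per term, counted via an independent parse", {
  reg <- ppi_default_registry()
  doc <- export_term_list(reg, "rdf")
  tr <- parse_graph(doc, "turtle")
  types <- tr[tr$predicate == "http://www.w3.org/1999/02/22-rdf-syntax-ns#type" &
                tr$object == "http://www.w3.org/1999/02/22-rdf-syntax-ns#Property", ]
  expect_equal(nrow(types), length(reg$terms))
  # second, parser-independent route: raw pattern count on the document
  expect_equal(lengths(regmatches(doc, gregexpr(" a rdf:Property .", doc,
                                                fixed = TRUE))),
               length(reg$terms))
  expect_setequal(types$subject,
                  vapply(reg$terms, `[[`, "", "iri"))
})

test_that("an empty registry exports a valid document with zero entries", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("term_name,label,iri,category,definition", f)
  empty <- load_registry(f)
  expect_length(empty$terms, 0)
  out <- export_term_list(empty, "csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(out, f2, sep = "")
  expect_length(load_registry(f2)$terms, 0)
  expect_equal(nrow(parse_graph(export_term_list(empty, "rdf"), "turtle")), 0)
  expect_error(export_term_list(empty, "json"), "unsupported export format")
})
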