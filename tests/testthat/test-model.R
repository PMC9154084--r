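test_that("a complete minimal interaction record is valid", {
  rep <- validate_dataset(minimal_dataset())
  expect_true(rep$is_valid)
  expect_equal(nrow(rep$findings), 0)
})

test_that("each blanked minimal field produces exactly one matching error", {
  for (fault in minimal_faults()) {
    d <- fault$inject(minimal_dataset())
    rep <- validate_dataset(d)
    errors <- rep$findings[rep$findings$severity == "error", ]
    expect_equal(nrow(errors), 1, info = fault$name)
    expect_equal(errors$code, fault$code, info = fault$name)
    expect_false(rep$is_valid)
  }
})

test_that("referential and identity defects are reported with their codes", {
  d <- minimal_dataset()
  d$relationships$relatedResourceID <- "ghost"
  rep <- validate_dataset(d)
  expect_equal(rep$findings$code[rep$findings$severity == "error"],
               "DANGLING_REFERENCE")

  d <- minimal_dataset()
  d$relationships$relatedResourceID <- d$relationships$resourceID
  codes <- validate_dataset(d)$findings$code
  expect_true("SELF_RELATIONSHIP" %in% codes)

  d <- minimal_dataset()
  d$occurrences$occurrenceID <- c("dup", "dup")
  d$relationships$resourceID <- "dup"
  d$relationships$relatedResourceID <- "other"
  codes <- validate_dataset(d)$findings$code
  expect_true("DUPLICATE_ID" %in% codes)

  # occurrence bound to a different event than its relationship
  d <- minimal_dataset()
  d$events <- rbind_fill(d$events, data.frame(eventID = "ev2",
                                              stringsAsFactors = FALSE))
  d$occurrences$eventID[2] <- "ev2"
  codes <- validate_dataset(d)$findings$code
  expect_true("DANGLING_REFERENCE" %in% codes)
})

test_that("recommendation breaches are warnings, not errors", {
  d <- with_measurement(minimal_dataset(), "ev1-pl", "flowerOpeningType",
                        "open")
  rep <- validate_dataset(d)
  expect_true(rep$is_valid)
  expect_equal(rep$findings$code[rep$findings$severity == "warning"],
               "CV_VIOLATION")

  d <- with_measurement(minimal_dataset(), "", "customAssay", "7",
                        type_iri = "http://example.org/terms/customAssay")
  rep <- validate_dataset(d)
  expect_true(rep$is_valid)
  expect_true("UNKNOWN_MEASUREMENT_TYPE" %in% rep$findings$code)

  d <- minimal_dataset()
  d$events <- rbind_fill(d$events, data.frame(eventID = "ev2",
                                              stringsAsFactors = FALSE))
  rep <- validate_dataset(d)
  expect_true(rep$is_valid)
  expect_equal(rep$findings$code, "EVENT_WITHOUT_RELATIONSHIP")
  expect_equal(rep$findings$record, "ev2")
})

test_that("findings are deterministically ordered by kind, record, code", {
  d <- minimal_dataset()
  d$occurrences$scientificName <- c("", "")
  d$relationships$relationshipAccordingTo <- ""
  d$relationships$relationshipOfResource <- ""
  d$relationships$relationshipOfResourceID <- ""
  rep1 <- validate_dataset(d)
  # permute record order; the report must not change
  d2 <- d
  d2$occurrences <- d2$occurrences[2:1, ]
  rep2 <- validate_dataset(d2)
  expect_identical(rep1$findings, rep2$findings)
  expect_equal(rep1$findings$code,
               c("MISSING_SCIENTIFIC_NAME", "MISSING_SCIENTIFIC_NAME",
                 "MISSING_ACCORDING_TO", "MISSING_RELATIONSHIP_TYPE"))
})

test_that("canonicalization is idempotent, order-invariant and trims padding", {
  d <- generate_dataset(fixture_profile(seed = 11))
  c1 <- canonicalize(d)
  expect_identical(canonicalize(c1), c1)

  d2 <- d
  d2$events <- d2$events[rev(seq_len(nrow(d2$events))), ]
  d2$occurrences <- d2$occurrences[sample(nrow(d2$occurrences)), ]
  expect_identical(canonicalize(d2), c1)

  d3 <- minimal_dataset()
  d4 <- minimal_dataset()
  d4$occurrences$scientificName <-
    paste0("  ", d4$occurrences$scientificName, " ")
  expect_identical(canonicalize(d3), canonicalize(d4))
  expect_true(ppi_equal(d3, d4))

  expect_error(canonicalize(minimal_faults()[[1]]$inject(minimal_dataset())),
               "invalid dataset")
})

test_that("associatedTaxa strings parse by the entry/qualifier grammar", {
  p <- parse_associated_taxa('"pollinator of":"Fuchsia magellanica"')
  expect_equal(p$relationship, "pollinator of")
  expect_equal(p$taxon, "Fuchsia magellanica")

  expect_equal(nrow(parse_associated_taxa("")), 0)
  expect_equal(nrow(parse_associated_taxa(NA)), 0)

  p <- parse_associated_taxa(
    'visits flowers of: Salvia guaranitica | preys on: Apis mellifera')
  expect_equal(p$relationship, c("visits flowers of", "preys on"))
  expect_equal(p$taxon, c("Salvia guaranitica", "Apis mellifera"))

  # no qualifier: whole entry is the taxon
  p <- parse_associated_taxa("Apis mellifera | Bombus terrestris")
  expect_equal(p$relationship, c("", ""))
  expect_equal(p$taxon, c("Apis mellifera", "Bombus terrestris"))
})

test_that("format/parse of associatedTaxa round-trips delimiter-free pairs", {
  set.seed(402)
  rels <- c("pollinator of", "visits flowers of", "preys on", "parasite of")
  taxa <- c("Fuchsia magellanica", "Salvia guaranitica", "Apis mellifera",
            "Bombus cf. morio", "Xylocopa (Neoxylocopa) frontalis")
  for (i in 1:25) {
    n <- sample.int(4, 1)
    pairs <- data.frame(
      relationship = sample(c(rels, ""), n, replace = TRUE),
      taxon = sample(taxa, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    # entries without a qualifier lose nothing but the empty string
    back <- parse_associated_taxa(format_associated_taxa(pairs))
    expect_equal(back, pairs)
  }
  expect_equal(format_associated_taxa(
    data.frame(relationship = character(0), taxon = character(0))), "")
})
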