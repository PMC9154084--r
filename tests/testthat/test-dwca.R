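read_entry <- function(zip, name) {
  dir <- tempfile("entry")
  dir.create(dir)
  utils::unzip(zip, files = name, exdir = dir)
  file.path(dir, name)
}

test_that("written archives carry an Event core and the four declared tables", {
  d <- minimal_dataset()
  f <- withr::local_tempfile(fileext = ".zip")
  write_dwca(d, f)
  listing <- utils::unzip(f, list = TRUE)
  expect_setequal(listing$Name,
                  c("meta.xml", "eml.xml", "event.csv", "occurrence.csv",
                    "extendedmeasurementorfact.csv",
                    "resourcerelationship.csv"))
  meta <- xml2::read_xml(read_entry(f, "meta.xml"))
  xml2::xml_ns_strip(meta)
  expect_equal(xml2::xml_attr(xml2::xml_find_first(meta, "core"), "rowType"),
               "http://rs.tdwg.org/dwc/terms/Event")
  expect_setequal(
    xml2::xml_attr(xml2::xml_find_all(meta, "extension"), "rowType"),
    c("http://rs.tdwg.org/dwc/terms/Occurrence",
      "http://rs.iobis.org/obis/terms/ExtendedMeasurementOrFact",
      "http://rs.tdwg.org/dwc/terms/ResourceRelationship"))
})

test_that("a minimal interaction yields an empty eMoF table and one relationship row", {
  f <- withr::local_tempfile(fileext = ".zip")
  write_dwca(minimal_dataset(), f)
  emof <- utils::read.csv(read_entry(f, "extendedmeasurementorfact.csv"),
                          colClasses = "character")
  expect_equal(nrow(emof), 0)
  rel <- utils::read.csv(read_entry(f, "resourcerelationship.csv"),
                         colClasses = "character")
  expect_equal(nrow(rel), 1)
  expect_equal(rel$relationshipAccordingTo, "Field observer A")
})

test_that("occurrence-level measurements carry occurrenceID in eMoF; event-level rows leave it empty", {
  d <- with_measurement(minimal_dataset(), "ev1-pl", "flowerColor", "violet",
                        id = "m-occ")
  d <- with_measurement(d, "", "resourceCollected", "nectar", id = "m-ev")
  f <- withr::local_tempfile(fileext = ".zip")
  write_dwca(d, f)
  emof <- utils::read.csv(read_entry(f, "extendedmeasurementorfact.csv"),
                          colClasses = "character", na.strings = NULL)
  occ_row <- emof[emof$measurementID == "m-occ", ]
  ev_row <- emof[emof$measurementID == "m-ev", ]
  expect_equal(occ_row$occurrenceID, "ev1-pl")
  expect_equal(ev_row$occurrenceID, "")
  expect_equal(occ_row$eventID, "ev1")
  expect_equal(ev_row$eventID, "ev1")
})

test_that("the eMoF schema adds exactly the three OBIS ID terms to classic MoF", {
  schema <- emof_schema()
  expect_setequal(attr(schema, "new_terms"),
                  c("measurementTypeID", "measurementValueID",
                    "measurementUnitID"))
  expect_length(attr(schema, "new_terms"), 3)
})

test_that("write/read archives round-trip seeded fixtures", {
  for (seed in c(2, 9, 23)) {
    d <- generate_dataset(profile_for_seed(seed))
    f <- withr::local_tempfile(fileext = ".zip")
    write_dwca(d, f)
    expect_true(ppi_equal(d, read_dwca(f)), info = paste("seed", seed))
  }
})

test_that("every extension row's core id appears in the core table", {
  f <- withr::local_tempfile(fileext = ".zip")
  write_dwca(generate_dataset(profile_for_seed(5)), f)
  core_ids <- utils::read.csv(read_entry(f, "event.csv"),
                              colClasses = "character")$eventID
  for (tab in c("occurrence.csv", "extendedmeasurementorfact.csv",
                "resourcerelationship.csv")) {
    ids <- utils::read.csv(read_entry(f, tab),
                           colClasses = "character")$eventID
    expect_true(all(ids %in% core_ids), info = tab)
  }
})

test_that("readers follow meta.xml term IRIs, not column position", {
  d <- generate_dataset(profile_for_seed(4))
  f <- withr::local_tempfile(fileext = ".zip")
  write_dwca(d, f)
  dir <- withr::local_tempdir()
  utils::unzip(f, exdir = dir)

  # shuffle the occurrence table's columns and rewrite the declared indices
  occ <- utils::read.csv(file.path(dir, "occurrence.csv"),
                         colClasses = "character", check.names = FALSE)
  perm <- rev(seq_along(occ))
  occ <- occ[, perm, drop = FALSE]
  meta <- xml2::read_xml(file.path(dir, "meta.xml"))
  xml2::xml_ns_strip(meta)
  ext <- xml2::xml_find_first(
    meta, "extension[@rowType='http://rs.tdwg.org/dwc/terms/Occurrence']")
  for (field in xml2::xml_find_all(ext, "field")) {
    iri <- xml2::xml_attr(field, "term")
    nm <- sub(".*[/#:]", "", iri)
    xml2::xml_set_attr(field, "index",
                       as.character(match(nm, names(occ)) - 1L))
  }
  xml2::xml_set_attr(xml2::xml_find_first(ext, "coreid"), "index",
                     as.character(match("eventID", names(occ)) - 1L))
  writeLines(as.character(meta), file.path(dir, "meta.xml"))
  writeLines(ppitools:::format_csv(occ), file.path(dir, "occurrence.csv"),
             sep = "")

  f2 <- withr::local_tempfile(fileext = ".zip")
  entries <- lapply(list.files(dir), function(n) {
    readChar(file.path(dir, n), file.size(file.path(dir, n)),
             useBytes = TRUE)
  })
  names(entries) <- list.files(dir)
  ppitools:::zip_write(f2, entries)
  expect_true(ppi_equal(d, read_dwca(f2)))
})

test_that("archives with a non-Event core or no manifest are rejected", {
  f <- withr::local_tempfile(fileext = ".zip")
  write_dwca(minimal_dataset(), f)
  dir <- withr::local_tempdir()
  utils::unzip(f, exdir = dir)
  meta <- readChar(file.path(dir, "meta.xml"),
                   file.size(file.path(dir, "meta.xml")))
  meta_occ <- sub("http://rs.tdwg.org/dwc/terms/Event",
                  "http://rs.tdwg.org/dwc/terms/Occurrence", meta,
                  fixed = TRUE)
  f2 <- withr::local_tempfile(fileext = ".zip")
  ppitools:::zip_write(f2, list("meta.xml" = meta_occ))
  expect_error(read_dwca(f2), "core row type.*Occurrence")

  f3 <- withr::local_tempfile(fileext = ".zip")
  ppitools:::zip_write(f3, list("readme.txt" = "not an archive"))
  expect_error(read_dwca(f3), "no meta.xml")
  expect_error(read_dwca(file.path(dir, "nope.zip")), "no such file")
})

test_that("measurement type IRIs are filled from the registry on write", {
  d <- with_measurement(minimal_dataset(), "ev1-pl", "flowerOpeningType",
                        "chasmogamous", type_iri = "")
  f <- withr::local_tempfile(fileext = ".zip")
  write_dwca(d, f)
  back <- read_dwca(f)
  expect_equal(back$measurements$measurementTypeID,
               paste0(PPI_NS, "flowerOpeningType"))
})

test_that("refusing to serialize invalid datasets is a contract error", {
  d <- minimal_dataset()
  d$occurrences$scientificName[1] <- ""
  f <- withr::local_tempfile(fileext = ".zip")
  expect_error(write_dwca(d, f), "invalid dataset")
})
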