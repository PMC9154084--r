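# Shared builders: a hand-written minimal interaction record and an
# independent brute-force triple builder used as the oracle for the RDF
# mapping (simple paste() loops, no shared code with to_triples()).

RO_POLLINATES <- "http://purl.obolibrary.org/obo/RO_0002455"
PPI_NS <- "http://rs.rebipp.org.br/ppi/terms/"

minimal_dataset <- function() {
  ppi_dataset(
    events = data.frame(eventID = "ev1", eventDate = "2021-10-05",
                        stringsAsFactors = FALSE),
    occurrences = data.frame(
      occurrenceID = c("ev1-pl", "ev1-an"),
      eventID = "ev1",
      scientificName = c("Fuchsia magellanica", "Sephanoides sephaniodes"),
      organismRole = c("plant", "animal"),
      stringsAsFactors = FALSE
    ),
    relationships = data.frame(
      resourceRelationshipID = "rel-ev1", eventID = "ev1",
      resourceID = "ev1-an", relatedResourceID = "ev1-pl",
      relationshipOfResource = "pollinates",
      relationshipOfResourceID = RO_POLLINATES,
      relationshipAccordingTo = "Field observer A",
      stringsAsFactors = FALSE
    )
  )
}

with_measurement <- function(dataset, occurrence_id, type, value,
                             type_iri = paste0(PPI_NS, type),
                             id = "m1") {
  dataset$measurements <- ppitools:::normalize_table(
    rbind_fill(dataset$measurements, data.frame(
      measurementID = id,
      eventID = if (nzchar(occurrence_id)) {
        dataset$occurrences$eventID[
          match(occurrence_id, dataset$occurrences$occurrenceID)]
      } else {
        dataset$events$eventID[1]
      },
      occurrenceID = occurrence_id,
      measurementType = type, measurementTypeID = type_iri,
      measurementValue = value, stringsAsFactors = FALSE
    )),
    ppitools:::MEASUREMENT_COLS
  )
  dataset
}

rbind_fill <- function(a, b) {
  if (is.null(a) || !nrow(a)) return(b)
  for (col in setdiff(names(a), names(b))) b[[col]] <- ""
  for (col in setdiff(names(b), names(a))) a[[col]] <- ""
  rbind(a, b[, names(a), drop = FALSE])
}

# independent brute-force builders for the structural RDF triples
mint <- function(base, kind, id) {
  paste0(base, kind, "/", utils::URLencode(id, reserved = TRUE))
}

expected_atevent_triples <- function(d, base) {
  if (!nrow(d$occurrences)) return(character(0))
  sort(paste0(
    "<", mint(base, "occurrence", d$occurrences$occurrenceID),
    "> <http://purl.org/dsw/atEvent> <",
    mint(base, "event", d$occurrences$eventID), ">"
  ))
}

expected_interaction_triples <- function(d, base) {
  if (!nrow(d$relationships)) return(character(0))
  sort(paste0(
    "<", mint(base, "occurrence", d$relationships$resourceID),
    "> <", d$relationships$relationshipOfResourceID, "> <",
    mint(base, "occurrence", d$relationships$relatedResourceID), ">"
  ))
}

expected_relation_triples <- function(d, base) {
  if (!nrow(d$measurements)) return(character(0))
  owner <- ifelse(
    nzchar(d$measurements$occurrenceID),
    mint(base, "occurrence", d$measurements$occurrenceID),
    mint(base, "event", d$measurements$eventID)
  )
  sort(paste0(
    "<", owner, "> <http://purl.org/dc/terms/relation> <",
    mint(base, "mof", d$measurements$measurementID), ">"
  ))
}

observed_iri_triples <- function(triples, predicate_filter) {
  df <- as.data.frame(triples)
  df <- df[df$object_type == "iri" & predicate_filter(df$predicate), ,
           drop = FALSE]
  if (!nrow(df)) return(character(0))
  sort(paste0("<", df$subject, "> <", df$predicate, "> <", df$object, ">"))
}

# the six minimal-record faults: each blanks one field (everywhere the value
# occurs, as it would disappear from a flat file) and names the single error
# code the contract must report
minimal_faults <- function() {
  list(
    list(name = "scientificName", code = "MISSING_SCIENTIFIC_NAME",
         inject = function(d) {
           d$occurrences$scientificName[1] <- ""
           d
         }),
    list(name = "eventID", code = "MISSING_EVENT_ID",
         inject = function(d) {
           d$events$eventID <- ""
           d$occurrences$eventID <- ""
           d$measurements$eventID <- rep("", nrow(d$measurements))
           d$relationships$eventID <- ""
           d
         }),
    list(name = "resourceID", code = "DANGLING_REFERENCE",
         inject = function(d) {
           d$relationships$resourceID <- ""
           d
         }),
    list(name = "relatedResourceID", code = "DANGLING_REFERENCE",
         inject = function(d) {
           d$relationships$relatedResourceID <- ""
           d
         }),
    list(name = "relationship type", code = "MISSING_RELATIONSHIP_TYPE",
         inject = function(d) {
           d$relationships$relationshipOfResource <- ""
           d$relationships$relationshipOfResourceID <- ""
           d
         }),
    list(name = "relationshipAccordingTo", code = "MISSING_ACCORDING_TO",
         inject = function(d) {
           d$relationships$relationshipAccordingTo <- ""
           d
         })
  )
}

# profile grid used by the round-trip property suites: parameters vary with
# the seed so the suite covers sizes, connectance and measurement rates
profile_for_seed <- function(seed) {
  fixture_profile(
    n_plants = 2 + seed %% 4,
    n_animals = 2 + (seed %/% 2) %% 4,
    connectance = c(0.2, 0.5, 0.8, 1)[1 + seed %% 4],
    records_per_edge = 1 + seed %% 2,
    measurement_rate = c(0, 0.3, 0.7, 1)[1 + (seed %/% 3) %% 4],
    seed = seed
  )
}
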