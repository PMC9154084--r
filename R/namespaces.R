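#' @keywords internal
"_PACKAGE"

# Namespace IRIs used across the serializers. The PPI term namespace follows
# the term-template identifier form ("/ppi/terms/"), which is the one actual
# term IRIs are minted under.
NS <- list(
  dwc     = "http://rs.tdwg.org/dwc/terms/",
  dwciri  = "http://rs.tdwg.org/dwc/iri/",
  dsw     = "http://purl.org/dsw/",
  dcterms = "http://purl.org/dc/terms/",
  rdf     = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs    = "http://www.w3.org/2000/01/rdf-schema#",
  xsd     = "http://www.w3.org/2001/XMLSchema#",
  ppi     = "http://rs.rebipp.org.br/ppi/terms/",
  ro      = "http://purl.obolibrary.org/obo/RO_",
  obo     = "http://purl.obolibrary.org/obo/",
  obis    = "http://rs.iobis.org/obis/terms/",
  # local namespace for columns that are not Darwin Core / OBIS / PPI terms
  # (e.g. organismRole); an artifact of this implementation, kept stable so
  # archives round-trip.
  local   = "http://rs.rebipp.org.br/ppi/local/"
)

# Row type IRIs for the Darwin Core Archive star schema.
ROW_TYPES <- list(
  event        = "http://rs.tdwg.org/dwc/terms/Event",
  occurrence   = "http://rs.tdwg.org/dwc/terms/Occurrence",
  emof         = "http://rs.iobis.org/obis/terms/ExtendedMeasurementOrFact",
  relationship = "http://rs.tdwg.org/dwc/terms/ResourceRelationship"
)

# Darwin Core terms used as canonical columns, plus a few common extras, so
# meta.xml can carry proper term IRIs. The three *ID measurement terms are the
# OBIS additions that turn MeasurementOrFact into ExtendedMeasurementOrFact.
DWC_TERMS <- c(
  "eventID", "parentEventID", "eventDate", "eventTime", "samplingProtocol",
  "sampleSizeValue", "sampleSizeUnit", "samplingEffort", "eventRemarks",
  "locationID", "locality", "country", "countryCode", "stateProvince",
  "decimalLatitude", "decimalLongitude", "geodeticDatum",
  "coordinateUncertaintyInMeters", "habitat", "fieldNumber",
  "occurrenceID", "basisOfRecord", "scientificName", "taxonRank", "kingdom",
  "phylum", "class", "order", "family", "genus", "specificEpithet",
  "vernacularName", "individualCount", "sex", "lifeStage", "behavior",
  "occurrenceRemarks", "taxonRemarks", "recordedBy", "organismID",
  "associatedTaxa", "associatedOccurrences", "dynamicProperties",
  "measurementID", "measurementType", "measurementValue",
  "measurementAccuracy", "measurementUnit", "measurementDeterminedDate",
  "measurementDeterminedBy", "measurementMethod", "measurementRemarks",
  "resourceRelationshipID", "resourceID", "relatedResourceID",
  "relationshipOfResource", "relationshipOfResourceID",
  "relationshipAccordingTo", "relationshipEstablishedDate",
  "relationshipRemarks"
)

OBIS_TERMS <- c("measurementTypeID", "measurementValueID", "measurementUnitID")

# Classic Darwin Core MeasurementOrFact property set; the eMoF extension adds
# occurrenceID (a pre-existing DwC term) for star-schema linkage plus three new
# ID terms, which are the schema delta this package reports.
MOF_CLASSIC_TERMS <- c(
  "measurementID", "measurementType", "measurementValue",
  "measurementAccuracy", "measurementUnit", "measurementDeterminedDate",
  "measurementDeterminedBy", "measurementMethod", "measurementRemarks"
)

#' IRI for a term token
#'
#' Maps a column/term token to a full IRI: Darwin Core terms to the dwc
#' namespace, the three OBIS measurement ID terms to the obis namespace, and
#' anything else to this package's stable local namespace.
#'
#' @param name character vector of term tokens.
#' @return character vector of IRIs.
#' @keywords internal
term_iri <- function(name) {
  ifelse(name %in% OBIS_TERMS, paste0(NS$obis, name),
    ifelse(name %in% DWC_TERMS, paste0(NS$dwc, name),
      paste0(NS$local, name)
    )
  )
}

#' Term token for an IRI
#'
#' Inverse of [term_iri()]: strips the namespace and returns the local token.
#' Works for any slash- or hash-terminated namespace.
#'
#' @param iri character vector of IRIs.
#' @return character vector of tokens.
#' @keywords internal
iri_local_name <- function(iri) {
  sub(".*[/#:]", "", iri)
}
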