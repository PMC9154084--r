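# The in-memory interaction dataset model. One interaction is a Darwin Core
# Event; the two interacting organisms are Occurrences linked to it by
# eventID; the interaction's type, direction and source live in a
# ResourceRelationship; everything else (traits, outcomes) is a
# MeasurementOrFact attached to the event or to one occurrence.
#
# All fields are character; "" means absent. Unknown columns are preserved
# verbatim (open-world model) so serializations round-trip losslessly.

EVENT_COLS <- c(
  "eventID", "eventDate", "decimalLatitude", "decimalLongitude",
  "locationID", "locality", "samplingProtocol"
)
OCCURRENCE_COLS <- c(
  "occurrenceID", "eventID", "scientificName", "taxonRank", "organismRole",
  "occurrenceRemarks"
)
MEASUREMENT_COLS <- c(
  "measurementID", "eventID", "occurrenceID", "measurementType",
  "measurementTypeID", "measurementValue", "measurementValueID",
  "measurementUnit", "measurementUnitID"
)
RELATIONSHIP_COLS <- c(
  "resourceRelationshipID", "eventID", "resourceID", "relatedResourceID",
  "relationshipOfResource", "relationshipOfResourceID",
  "relationshipAccordingTo"
)

CANONICAL_COLS <- list(
  events = EVENT_COLS, occurrences = OCCURRENCE_COLS,
  measurements = MEASUREMENT_COLS, relationships = RELATIONSHIP_COLS
)

ID_COLS <- c(
  events = "eventID", occurrences = "occurrenceID",
  measurements = "measurementID", relationships = "resourceRelationshipID"
)

normalize_table <- function(df, canonical) {
  if (is.null(df)) df <- data.frame()
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in names(df)) {
    v <- as.character(df[[col]])
    v[is.na(v)] <- ""
    df[[col]] <- v
  }
  for (col in setdiff(canonical, names(df))) {
    df[[col]] <- character(nrow(df))
  }
  extras <- setdiff(names(df), canonical)
  df <- df[, c(canonical, extras), drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Construct an interaction dataset
#'
#' Builds the package's central container from up to four record tables. Any
#' columns beyond the canonical ones are kept verbatim and survive every
#' serialization. All values are coerced to character; `NA` becomes `""`.
#'
#' @param events,occurrences,measurements,relationships data frames (or
#'   `NULL` for empty). Canonical columns are added when missing:
#'   events `eventID, eventDate, decimalLatitude, decimalLongitude,
#'   locationID, locality, samplingProtocol`; occurrences `occurrenceID,
#'   eventID, scientificName, taxonRank, organismRole, occurrenceRemarks`;
#'   measurements `measurementID, eventID, occurrenceID, measurementType,
#'   measurementTypeID, measurementValue, measurementValueID,
#'   measurementUnit, measurementUnitID`; relationships
#'   `resourceRelationshipID, eventID, resourceID, relatedResourceID,
#'   relationshipOfResource, relationshipOfResourceID,
#'   relationshipAccordingTo`.
#' @param provenance free-text provenance note.
#' @param unresolved internal: references collected by readers that could not
#'   be resolved; reported by [validate_dataset()] as `DANGLING_REFERENCE`.
#' @return an object of class `ppi_dataset`.
#' @export
ppi_dataset <- function(events = NULL, occurrences = NULL,
                        measurements = NULL, relationships = NULL,
                        provenance = "", unresolved = NULL) {
  x <- structure(
    list(
      events = normalize_table(events, EVENT_COLS),
      occurrences = normalize_table(occurrences, OCCURRENCE_COLS),
      measurements = normalize_table(measurements, MEASUREMENT_COLS),
      relationships = normalize_table(relationships, RELATIONSHIP_COLS),
      provenance = provenance
    ),
    class = "ppi_dataset"
  )
  if (is.null(unresolved)) {
    unresolved <- data.frame(kind = character(0), record = character(0),
                             ref = character(0), stringsAsFactors = FALSE)
  }
  attr(x, "unresolved") <- unresolved
  x
}

#' @export
print.ppi_dataset <- function(x, ...) {
  cat(sprintf(
    "<ppi_dataset> %d event(s), %d occurrence(s), %d measurement(s), %d relationship(s)\n",
    nrow(x$events), nrow(x$occurrences), nrow(x$measurements),
    nrow(x$relationships)
  ))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
summary.ppi_dataset <- function(object, registry = ppi_default_registry(),
                                ...) {
  rep <- validate_dataset(object, registry)
  plants <- object$occurrences$scientificName[
    object$occurrences$organismRole == "plant"]
  animals <- object$occurrences$scientificName[
    object$occurrences$organismRole == "animal"]
  structure(
    list(
      n_events = nrow(object$events),
      n_occurrences = nrow(object$occurrences),
      n_measurements = nrow(object$measurements),
      n_relationships = nrow(object$relationships),
      n_plant_taxa = length(unique(plants[nzchar(plants)])),
      n_animal_taxa = length(unique(animals[nzchar(animals)])),
      validation = rep
    ),
    class = "summary.ppi_dataset"
  )
}

#' @export
print.summary.ppi_dataset <- function(x, ...) {
  cat(sprintf(
    "Interaction dataset: %d events, %d occurrences (%d plant taxa, %d animal taxa),\n  %d measurements, %d relationships\n",
    x$n_events, x$n_occurrences, x$n_plant_taxa, x$n_animal_taxa,
    x$n_measurements, x$n_relationships
  ))
  print(x$validation)
  invisible(x)
}

sort_key_order <- function(...) {
  order(..., method = "radix")
}

#' Canonicalize an interaction dataset
#'
#' Produces the canonical form used to define dataset equality: fields are
#' whitespace-trimmed, records are sorted by their identifiers, extra columns
#' are sorted by name and extra columns that are empty everywhere are
#' dropped. The dataset must be valid (no validation errors).
#'
#' @param dataset a `ppi_dataset`.
#' @param registry registry used for the validity pre-check.
#' @return a canonical `ppi_dataset`.
#' @export
canonicalize <- function(dataset, registry = ppi_default_registry()) {
  stopifnot(inherits(dataset, "ppi_dataset"))
  rep <- validate_dataset(dataset, registry)
  if (!rep$is_valid) {
    stop("cannot canonicalize an invalid dataset (",
         sum(rep$findings$severity == "error"), " error(s)); ",
         "see validate_dataset()", call. = FALSE)
  }
  canonicalize_core(dataset)
}

# the deterministic reordering/trimming itself, usable on datasets that do
# not (yet) satisfy the validity contract — equality must be definable for
# reconstructions from lossy serializations
canonicalize_core <- function(dataset) {
  parts <- lapply(names(CANONICAL_COLS), function(part) {
    df <- dataset[[part]]
    for (col in names(df)) df[[col]] <- trimws(df[[col]])
    canonical <- CANONICAL_COLS[[part]]
    extras <- setdiff(names(df), canonical)
    keep <- extras[vapply(extras, function(c) any(nzchar(df[[c]])), TRUE)]
    df <- df[, c(canonical, keep[sort_key_order(keep)]), drop = FALSE]
    df <- df[sort_key_order(df[[ID_COLS[[part]]]]), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  names(parts) <- names(CANONICAL_COLS)
  ppi_dataset(
    events = parts$events, occurrences = parts$occurrences,
    measurements = parts$measurements, relationships = parts$relationships,
    provenance = trimws(dataset$provenance)
  )
}

#' Compare two datasets in canonical form
#'
#' Equality is defined on canonicalized datasets. `ignore` names columns to
#' exclude from the comparison; this is how the documented lossiness of the
#' RDF mapping (which does not reify the ResourceRelationship, so
#' `resourceRelationshipID` and `relationshipAccordingTo` do not survive) is
#' expressed.
#'
#' @param a,b `ppi_dataset` objects.
#' @param registry registry for canonicalization.
#' @param ignore character vector of column names excluded everywhere.
#' @return `TRUE` or `FALSE`.
#' @export
ppi_equal <- function(a, b, registry = ppi_default_registry(),
                      ignore = character(0)) {
  ca <- canonicalize_core(a)
  cb <- canonicalize_core(b)
  for (part in names(CANONICAL_COLS)) {
    da <- ca[[part]]
    db <- cb[[part]]
    da <- da[, setdiff(names(da), ignore), drop = FALSE]
    db <- db[, setdiff(names(db), ignore), drop = FALSE]
    if (!identical(da, db)) return(FALSE)
  }
  TRUE
}
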