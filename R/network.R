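# Conversion between record-level interaction datasets and species-level
# bipartite networks. Species-level interactions are an aggregation of
# individual-level records (never the other way around), so the network side
# is always derived: cells count relationship records per (plant taxon,
# animal taxon) pair, honouring an "interaction frequency" event measurement
# when a network was expanded into records in compact form.

WEIGHT_MEASUREMENT_TYPE <- "interaction frequency"

#' Construct a bipartite plant-animal adjacency network
#'
#' @param weights non-negative integer matrix, rows = plant taxa, columns =
#'   animal taxa; dimnames supply the taxon names unless given explicitly.
#' @param plant_taxa,animal_taxa taxon name vectors (default: dimnames).
#' @param binary logical; a binary network only admits 0/1 entries.
#' @return an object of class `ppi_network`.
#' @export
ppi_network <- function(weights, plant_taxa = rownames(weights),
                        animal_taxa = colnames(weights), binary = FALSE) {
  weights <- as.matrix(weights)
  if (is.null(plant_taxa)) plant_taxa <- character(0)
  if (is.null(animal_taxa)) animal_taxa <- character(0)
  if (nrow(weights) != length(plant_taxa) ||
      ncol(weights) != length(animal_taxa)) {
    stop("weight matrix dimensions do not match the taxa lists",
         call. = FALSE)
  }
  storage.mode(weights) <- "integer"
  if (length(weights) && (anyNA(weights) || any(weights < 0))) {
    stop("weights must be non-negative integers", call. = FALSE)
  }
  if (binary && length(weights) && any(weights > 1)) {
    stop("a binary network only admits 0/1 entries", call. = FALSE)
  }
  dimnames(weights) <- list(plant_taxa, animal_taxa)
  structure(
    list(plant_taxa = as.character(plant_taxa),
         animal_taxa = as.character(animal_taxa),
         weights = weights, binary = binary),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d plant(s) x %d animal(s), %s, %d interaction(s)\n",
              length(x$plant_taxa), length(x$animal_taxa),
              if (x$binary) "binary" else "weighted", sum(x$weights)))
  if (length(x$weights)) print(x$weights)
  invisible(x)
}

default_roles <- function(occurrence_row) {
  role <- occurrence_row[["organismRole"]]
  if (role %in% c("plant", "animal")) role else "unknown"
}

#' Aggregate interaction records into a species-level bipartite network
#'
#' Each relationship contributes to the cell of its plant taxon (row) and
#' animal taxon (column); the contribution is the event's
#' `"interaction frequency"` measurement value when one is present (the
#' compact encoding written by [network_to_dataset()]), else 1. Taxa are
#' keyed by verbatim `scientificName` and sorted lexicographically.
#'
#' @param dataset a valid `ppi_dataset`.
#' @param roles function mapping one occurrence row (as a one-row data
#'   frame) to `"plant"`, `"animal"` or `"unknown"`; the default reads the
#'   `organismRole` column.
#' @param binary threshold cells at >= 1.
#' @param registry registry for the validity pre-check.
#' @return a `ppi_network`.
#' @export
aggregate_to_network <- function(dataset, roles = NULL, binary = FALSE,
                                 registry = ppi_default_registry()) {
  stopifnot(inherits(dataset, "ppi_dataset"))
  rep <- validate_dataset(dataset, registry)
  if (!rep$is_valid) {
    stop("refusing to aggregate an invalid dataset (",
         sum(rep$findings$severity == "error"), " error(s))", call. = FALSE)
  }
  if (is.null(roles)) roles <- default_roles
  oc <- dataset$occurrences
  re <- dataset$relationships
  me <- dataset$measurements

  role_of <- vapply(seq_len(nrow(oc)), function(i) {
    roles(oc[i, , drop = FALSE])
  }, "")
  names(role_of) <- oc$occurrenceID

  weight_of_event <- function(eid) {
    w <- me$measurementValue[me$eventID == eid & !nzchar(me$occurrenceID) &
                               me$measurementType == WEIGHT_MEASUREMENT_TYPE]
    if (!length(w)) return(1L)
    wi <- suppressWarnings(as.integer(w[1]))
    if (is.na(wi) || wi < 0) {
      stop("invalid interaction frequency value '", w[1], "' on event ", eid,
           call. = FALSE)
    }
    wi
  }

  pairs <- list()
  for (i in seq_len(nrow(re))) {
    ends <- c(re$resourceID[i], re$relatedResourceID[i])
    r <- role_of[ends]
    if (!setequal(r, c("plant", "animal"))) {
      stop("role error: relationship '",
           record_ref(re$resourceRelationshipID, "relationship")[i],
           "' does not connect one plant and one animal (roles: ",
           paste(r, collapse = ", "), ")", call. = FALSE)
    }
    plant_occ <- ends[r == "plant"]
    animal_occ <- ends[r == "animal"]
    pairs[[length(pairs) + 1L]] <- list(
      plant = oc$scientificName[match(plant_occ, oc$occurrenceID)],
      animal = oc$scientificName[match(animal_occ, oc$occurrenceID)],
      weight = weight_of_event(re$eventID[i])
    )
  }

  plants <- sort(unique(vapply(pairs, `[[`, "", "plant")), method = "radix")
  animals <- sort(unique(vapply(pairs, `[[`, "", "animal")), method = "radix")
  w <- matrix(0L, length(plants), length(animals),
              dimnames = list(plants, animals))
  for (p in pairs) {
    w[p$plant, p$animal] <- w[p$plant, p$animal] + p$weight
  }
  if (binary) w[] <- ifelse(w >= 1L, 1L, 0L)
  ppi_network(w, plants, animals, binary = binary)
}

#' Expand a bipartite network into an interaction dataset
#'
#' Documents each edge of the network as one interaction event carrying one
#' plant and one animal occurrence (occurrence identifiers are fresh per
#' event: in the archive star schema an occurrence row belongs to exactly
#' one core event) and one relationship. In `"compact"` mode (default) a
#' weighted edge carries one event-level measurement of type
#' `"interaction frequency"` recording the weight; in `"expanded"` mode a
#' weight-w edge becomes w replicate events. The output validates with zero
#' errors.
#'
#' @param network a `ppi_network`.
#' @param event_template named character vector/list of event fields applied
#'   to every generated event (e.g. `c(eventDate = "2021-10-05")`).
#' @param relationship_type human-readable interaction type; subject acts on
#'   object.
#' @param relationship_type_iri predicate IRI; default looks
#'   `relationship_type` up in [ro_predicates()].
#' @param according_to source of the interactions (person, organization,
#'   publication or reference); required.
#' @param subject_role which side is the relationship subject; the default
#'   `"animal"` matches animal-acts-on-plant readings such as
#'   "visits flowers of".
#' @param mode `"compact"` or `"expanded"`.
#' @return a `ppi_dataset`.
#' @export
network_to_dataset <- function(network, event_template = list(),
                               relationship_type = "visits flowers of",
                               relationship_type_iri = NULL,
                               according_to,
                               subject_role = c("animal", "plant"),
                               mode = c("compact", "expanded")) {
  stopifnot(inherits(network, "ppi_network"))
  subject_role <- match.arg(subject_role)
  mode <- match.arg(mode)
  if (missing(according_to) || !nzchar(trimws(according_to))) {
    stop("according_to must be non-empty: every relationship needs a source",
         call. = FALSE)
  }
  if (is.null(relationship_type_iri)) {
    relationship_type_iri <- ro_predicate_iri(relationship_type)
    if (is.na(relationship_type_iri)) relationship_type_iri <- ""
  }
  if (!nzchar(relationship_type) && !nzchar(relationship_type_iri)) {
    stop("a relationship type (text or IRI) is required", call. = FALSE)
  }

  events <- list(); occurrences <- list()
  measurements <- list(); relationships <- list()
  k <- 0L
  for (i in seq_along(network$plant_taxa)) {
    for (j in seq_along(network$animal_taxa)) {
      wij <- network$weights[i, j]
      if (wij == 0L) next
      reps <- if (mode == "expanded") wij else 1L
      for (r in seq_len(reps)) {
        k <- k + 1L
        eid <- sprintf("ev%04d", k)
        ev <- c(list(eventID = eid), as.list(event_template))
        events[[k]] <- ev[!duplicated(names(ev))]
        pl <- paste0(eid, "-pl"); an <- paste0(eid, "-an")
        occurrences[[2L * k - 1L]] <- list(
          occurrenceID = pl, eventID = eid,
          scientificName = network$plant_taxa[i],
          organismRole = "plant")
        occurrences[[2L * k]] <- list(
          occurrenceID = an, eventID = eid,
          scientificName = network$animal_taxa[j],
          organismRole = "animal")
        subj <- if (subject_role == "animal") an else pl
        obj <- if (subject_role == "animal") pl else an
        relationships[[k]] <- list(
          resourceRelationshipID = paste0("rel-", eid), eventID = eid,
          resourceID = subj, relatedResourceID = obj,
          relationshipOfResource = relationship_type,
          relationshipOfResourceID = relationship_type_iri,
          relationshipAccordingTo = according_to)
        if (mode == "compact" && !network$binary) {
          measurements[[length(measurements) + 1L]] <- list(
            measurementID = paste0(eid, "-m1"), eventID = eid,
            occurrenceID = "",
            measurementType = WEIGHT_MEASUREMENT_TYPE,
            measurementValue = as.character(wij))
        }
      }
    }
  }
  rows_to_df <- function(rows) {
    if (!length(rows)) return(NULL)
    cols <- unique(unlist(lapply(rows, names)))
    out <- lapply(cols, function(cn) {
      vapply(rows, function(r) as.character(r[[cn]] %||% ""), "")
    })
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  }
  ppi_dataset(
    events = rows_to_df(events), occurrences = rows_to_df(occurrences),
    measurements = rows_to_df(measurements),
    relationships = rows_to_df(relationships)
  )
}

#' Write a network as a labelled CSV matrix
#'
#' Plant names label the rows (first column), animal names the columns.
#'
#' @param network a `ppi_network`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(network, path) {
  df <- as.data.frame(network$weights, check.names = FALSE)
  df <- cbind(data.frame(scientificName = network$plant_taxa,
                         stringsAsFactors = FALSE), df)
  write_csv_min(df, path)
}

#' Read a network from a labelled CSV matrix
#'
#' @param path CSV file with plant names in the first column and animal
#'   names as the header.
#' @param binary interpret (and check) the matrix as binary.
#' @return a `ppi_network`.
#' @export
read_network_csv <- function(path, binary = FALSE) {
  df <- read_csv_strict(path)
  if (ncol(df) < 1) stop("matrix CSV has no columns", call. = FALSE)
  plants <- df[[1]]
  animals <- names(df)[-1]
  w <- as.matrix(df[, -1, drop = FALSE])
  wn <- suppressWarnings(apply(w, 2, as.numeric))
  if (length(w) && anyNA(wn)) {
    stop("matrix CSV contains non-numeric cells", call. = FALSE)
  }
  w <- matrix(as.integer(wn), nrow = length(plants),
              dimnames = list(plants, animals))
  ppi_network(w, plants, animals, binary = binary)
}
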