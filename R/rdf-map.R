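# The graph mapping: occurrences and events become typed, IRI-minted nodes
# linked by dsw:atEvent; the type and direction of an interaction is one
# triple with two occurrence instances as subject and object and a Relations
# Ontology term as predicate; measurements become MeasurementOrFact nodes
# linked from their owner via dcterms:relation, with dwciri:measurementType
# for vocabulary-term types and dwc:measurementType for free-text ones.
#
# The ResourceRelationship record is deliberately not reified (its RDF
# representation is an open question in the standard), so the relationship's
# own identifier and relationshipAccordingTo do not survive RDF round trips;
# everything else does.

DEFAULT_BASE_IRI <- "http://example.org/ppi/"

mint_iri <- function(base, kind, id) {
  paste0(base, kind, "/", utils::URLencode(id, reserved = TRUE))
}

#' Relations Ontology predicate table
#'
#' The shipped, editable mapping between human-readable interaction types and
#' Relations Ontology term IRIs, read from `extdata/ro-predicates.csv`. Used
#' to fill `relationshipOfResourceID` from text and to recover the text form
#' when reading RDF.
#'
#' @return data frame with columns `label` and `iri`.
#' @export
ro_predicates <- function() {
  if (is.null(.ppi_cache$ro)) {
    path <- system.file("extdata", "ro-predicates.csv", package = "ppitools",
                        mustWork = TRUE)
    .ppi_cache$ro <- read_csv_strict(path)
  }
  .ppi_cache$ro
}

ro_predicate_iri <- function(label) {
  tab <- ro_predicates()
  i <- match(trimws(label), tab$label)
  if (is.na(i)) NA_character_ else tab$iri[i]
}

ro_predicate_label <- function(iri) {
  tab <- ro_predicates()
  i <- match(iri, tab$iri)
  if (is.na(i)) "" else tab$label[i]
}

emit_field_literals <- function(tr, subject, row, skip) {
  for (col in names(row)) {
    val <- row[[col]]
    if (col %in% skip || !nzchar(val)) next
    tr <- add_triple(tr, subject, term_iri(col), val, "literal")
  }
  tr
}

#' Map an interaction dataset to RDF triples
#'
#' @param dataset a valid `ppi_dataset` whose relationships all carry
#'   `relationshipOfResourceID` (a free-text-only interaction type cannot
#'   become a predicate; with `strict = FALSE` such relationships are dropped
#'   with a message instead of failing).
#' @param registry registry used for validation.
#' @param base base IRI under which record IRIs are minted
#'   (`<base>event/<id>`, `<base>occurrence/<id>`, `<base>mof/<id>`).
#' @param strict fail on relationships without an IRI type (default).
#' @return a triple data frame (class `ppi_triples`).
#' @export
to_triples <- function(dataset, registry = ppi_default_registry(),
                       base = DEFAULT_BASE_IRI, strict = TRUE) {
  stopifnot(inherits(dataset, "ppi_dataset"))
  rep <- validate_dataset(dataset, registry)
  if (!rep$is_valid) {
    stop("refusing to serialize an invalid dataset (",
         sum(rep$findings$severity == "error"), " error(s))", call. = FALSE)
  }
  re <- dataset$relationships
  no_iri <- !nzchar(trimws(re$relationshipOfResourceID))
  if (any(no_iri)) {
    ids <- record_ref(re$resourceRelationshipID, "relationship")[no_iri]
    if (strict) {
      stop("RDF serialization error: relationship(s) without an IRI type ",
           "(relationshipOfResourceID): ", paste(ids, collapse = ", "),
           call. = FALSE)
    }
    message("dropping ", sum(no_iri),
            " relationship(s) without an IRI type: ",
            paste(ids, collapse = ", "))
    re <- re[!no_iri, , drop = FALSE]
  }

  tr <- empty_triples()
  ev <- dataset$events
  oc <- dataset$occurrences
  me <- dataset$measurements
  ev_iri <- stats::setNames(mint_iri(base, "event", ev$eventID), ev$eventID)
  oc_iri <- stats::setNames(mint_iri(base, "occurrence", oc$occurrenceID),
                            oc$occurrenceID)

  for (i in seq_len(nrow(ev))) {
    s <- ev_iri[[ev$eventID[i]]]
    tr <- add_triple(tr, s, paste0(NS$rdf, "type"), ROW_TYPES$event, "iri")
    tr <- emit_field_literals(tr, s, ev[i, , drop = FALSE], skip = character(0))
  }
  for (i in seq_len(nrow(oc))) {
    s <- oc_iri[[oc$occurrenceID[i]]]
    tr <- add_triple(tr, s, paste0(NS$rdf, "type"), ROW_TYPES$occurrence,
                     "iri")
    tr <- emit_field_literals(tr, s, oc[i, , drop = FALSE], skip = "eventID")
    if (nzchar(oc$eventID[i])) {
      tr <- add_triple(tr, s, paste0(NS$dsw, "atEvent"),
                       ev_iri[[oc$eventID[i]]], "iri")
    }
  }
  for (i in seq_len(nrow(re))) {
    tr <- add_triple(tr, oc_iri[[re$resourceID[i]]],
                     re$relationshipOfResourceID[i],
                     oc_iri[[re$relatedResourceID[i]]], "iri")
  }
  mof_class <- paste0(NS$dwc, "MeasurementOrFact")
  for (i in seq_len(nrow(me))) {
    s <- mint_iri(base, "mof", me$measurementID[i])
    owner <- if (nzchar(me$occurrenceID[i])) {
      oc_iri[[me$occurrenceID[i]]]
    } else {
      ev_iri[[me$eventID[i]]]
    }
    tr <- add_triple(tr, s, paste0(NS$rdf, "type"), mof_class, "iri")
    tr <- add_triple(tr, owner, paste0(NS$dcterms, "relation"), s, "iri")
    if (nzchar(me$measurementID[i])) {
      tr <- add_triple(tr, s, paste0(NS$dwc, "measurementID"),
                       me$measurementID[i], "literal")
    }
    if (nzchar(me$measurementTypeID[i])) {
      tr <- add_triple(tr, s, paste0(NS$dwciri, "measurementType"),
                       me$measurementTypeID[i], "iri")
    } else if (nzchar(me$measurementType[i])) {
      tr <- add_triple(tr, s, paste0(NS$dwc, "measurementType"),
                       me$measurementType[i], "literal")
    }
    if (nzchar(me$measurementValueID[i])) {
      tr <- add_triple(tr, s, paste0(NS$dwc, "measurementValue"),
                       me$measurementValueID[i], "literal",
                       datatype = paste0(NS$xsd, "anyURI"))
    } else if (nzchar(me$measurementValue[i])) {
      tr <- add_triple(tr, s, paste0(NS$dwc, "measurementValue"),
                       me$measurementValue[i], "literal",
                       datatype = paste0(NS$xsd, "string"))
    }
    if (nzchar(me$measurementUnit[i])) {
      tr <- add_triple(tr, s, paste0(NS$dwc, "measurementUnit"),
                       me$measurementUnit[i], "literal")
    }
  }
  tr
}

cv_value_for_iri <- function(registry, type_iri, value_iri) {
  if (!type_iri %in% names(registry$by_iri)) return("")
  term <- registry$terms[[registry$by_iri[[type_iri]]]]
  i <- match(value_iri, term$controlled_vocabulary_iris)
  if (is.na(i)) "" else term$controlled_vocabulary[i]
}

#' Reconstruct an interaction dataset from its RDF graph
#'
#' Inverse of [to_triples()] for graphs produced by this mapping. Record
#' identifiers are taken from the `dwc:eventID` / `dwc:occurrenceID` /
#' `dwc:measurementID` literals; relationship records are re-minted (the
#' mapping does not reify ResourceRelationship, so `resourceRelationshipID`
#' and `relationshipAccordingTo` are not recoverable), with
#' `relationshipOfResource` text recovered through [ro_predicates()] where
#' possible. Triples that play no role in the mapping are ignored with a
#' message.
#'
#' @param triples a triple data frame.
#' @param registry registry used to recover measurement type text and
#'   controlled-vocabulary values from IRIs.
#' @param base base IRI used when the graph was minted (unused for identity
#'   recovery, kept for interface symmetry).
#' @param according_to value used for the reconstructed relationships'
#'   `relationshipAccordingTo` (the graph does not carry it); the default
#'   empty string leaves the reconstruction honestly incomplete, so it fails
#'   the minimal-record contract until a source is supplied.
#' @return a `ppi_dataset`.
#' @export
from_triples <- function(triples, registry = ppi_default_registry(),
                         base = DEFAULT_BASE_IRI, according_to = "") {
  df <- as.data.frame(triples)
  rdf_type <- paste0(NS$rdf, "type")
  at_event <- paste0(NS$dsw, "atEvent")
  relation <- paste0(NS$dcterms, "relation")
  mof_class <- paste0(NS$dwc, "MeasurementOrFact")

  types <- df[df$predicate == rdf_type & df$object_type == "iri", ]
  node_type <- stats::setNames(types$object, types$subject)
  nodes_of <- function(class_iri) unique(types$subject[types$object == class_iri])

  ev_nodes <- nodes_of(ROW_TYPES$event)
  oc_nodes <- nodes_of(ROW_TYPES$occurrence)
  mof_nodes <- nodes_of(mof_class)

  literals_of <- function(node) {
    rows <- df[df$subject == node & df$object_type == "literal" &
                 df$datatype != paste0(NS$xsd, "anyURI"), ]
    stats::setNames(as.list(rows$object), iri_local_name(rows$predicate))
  }

  used <- df$predicate == rdf_type

  # events
  ev_rows <- list()
  ev_id_of <- character(0)
  for (node in ev_nodes) {
    row <- literals_of(node)
    used <- used | (df$subject == node & df$object_type == "literal")
    ev_rows[[length(ev_rows) + 1L]] <- row
    ev_id_of[node] <- row$eventID %||% ""
  }

  # occurrences
  oc_rows <- list()
  oc_id_of <- character(0)
  oc_event_of <- character(0)
  for (node in oc_nodes) {
    row <- literals_of(node)
    at <- df$object[df$subject == node & df$predicate == at_event &
                      df$object_type == "iri"]
    used <- used | (df$subject == node &
                      (df$object_type == "literal" | df$predicate == at_event))
    if (!length(at)) {
      stop("RDF structure error: occurrence node <", node,
           "> has no dsw:atEvent triple", call. = FALSE)
    }
    if (!at[1] %in% ev_nodes) {
      stop("RDF structure error: event node <", at[1],
           "> lacks an Event type statement", call. = FALSE)
    }
    row$eventID <- ev_id_of[[at[1]]]
    oc_rows[[length(oc_rows) + 1L]] <- row
    oc_id_of[node] <- row$occurrenceID %||% ""
    oc_event_of[node] <- row$eventID
  }

  # measurements
  me_rows <- list()
  for (node in mof_nodes) {
    rows <- df[df$subject == node, ]
    used <- used | df$subject == node
    row <- list()
    for (i in seq_len(nrow(rows))) {
      p <- rows$predicate[i]
      if (p == paste0(NS$dwciri, "measurementType")) {
        row$measurementTypeID <- rows$object[i]
        if (rows$object[i] %in% names(registry$by_iri)) {
          row$measurementType <-
            registry$terms[[registry$by_iri[[rows$object[i]]]]]$term_name
        }
      } else if (p == paste0(NS$dwc, "measurementValue")) {
        if (rows$datatype[i] == paste0(NS$xsd, "anyURI")) {
          row$measurementValueID <- rows$object[i]
        } else {
          row$measurementValue <- rows$object[i]
        }
      } else if (rows$object_type[i] == "literal") {
        row[[iri_local_name(p)]] <- rows$object[i]
      }
    }
    if (!is.null(row$measurementValueID) && is.null(row$measurementValue) &&
        !is.null(row$measurementTypeID)) {
      v <- cv_value_for_iri(registry, row$measurementTypeID,
                            row$measurementValueID)
      if (nzchar(v)) row$measurementValue <- v
    }
    owner <- df$subject[df$predicate == relation & df$object == node]
    used <- used | (df$predicate == relation & df$object == node)
    if (length(owner)) {
      o <- owner[1]
      if (identical(node_type[[o]], ROW_TYPES$occurrence)) {
        row$occurrenceID <- oc_id_of[[o]]
        row$eventID <- oc_event_of[[o]]
      } else if (identical(node_type[[o]], ROW_TYPES$event)) {
        row$eventID <- ev_id_of[[o]]
      }
    }
    me_rows[[length(me_rows) + 1L]] <- row
  }

  # relationships: occurrence -> occurrence triples with a non-structural
  # predicate
  structural <- c(rdf_type, at_event, relation)
  rel_idx <- which(
    df$object_type == "iri" &
      !(df$predicate %in% structural) &
      df$subject %in% oc_nodes &
      df$object %in% oc_nodes
  )
  re_rows <- list()
  if (length(rel_idx)) {
    rel_df <- df[rel_idx, ]
    ord <- order(oc_event_of[rel_df$subject], oc_id_of[rel_df$subject],
                 oc_id_of[rel_df$object], method = "radix")
    rel_df <- rel_df[ord, ]
    used[rel_idx] <- TRUE
    count_by_event <- list()
    for (i in seq_len(nrow(rel_df))) {
      subj <- rel_df$subject[i]
      eid <- oc_event_of[[subj]]
      n <- (count_by_event[[eid]] %||% 0L) + 1L
      count_by_event[[eid]] <- n
      rid <- if (n == 1L) paste0("rel-", eid) else
        sprintf("rel-%s-%d", eid, n)
      re_rows[[length(re_rows) + 1L]] <- list(
        resourceRelationshipID = rid,
        eventID = eid,
        resourceID = oc_id_of[[subj]],
        relatedResourceID = oc_id_of[[rel_df$object[i]]],
        relationshipOfResource = ro_predicate_label(rel_df$predicate[i]),
        relationshipOfResourceID = rel_df$predicate[i],
        relationshipAccordingTo = according_to
      )
    }
  }

  if (any(!used)) {
    message("ignoring ", sum(!used),
            " triple(s) that play no role in the interaction mapping")
  }

  rows_to_df <- function(rows) {
    if (!length(rows)) return(NULL)
    cols <- unique(unlist(lapply(rows, names)))
    out <- lapply(cols, function(cn) {
      vapply(rows, function(r) r[[cn]] %||% "", "")
    })
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  }

  ppi_dataset(
    events = rows_to_df(ev_rows),
    occurrences = rows_to_df(oc_rows),
    measurements = rows_to_df(me_rows),
    relationships = rows_to_df(re_rows)
  )
}

#' Write an interaction dataset as Turtle or N-Triples
#'
#' Convenience wrapper: [to_triples()] then [serialize_graph()].
#'
#' @inheritParams to_triples
#' @param format `"turtle"` or `"ntriples"`.
#' @param file optional path to write to.
#' @return the document text (invisibly when `file` is given).
#' @export
write_rdf <- function(dataset, format = c("turtle", "ntriples"),
                      registry = ppi_default_registry(),
                      base = DEFAULT_BASE_IRI, strict = TRUE, file = NULL) {
  format <- match.arg(format)
  doc <- serialize_graph(
    to_triples(dataset, registry, base = base, strict = strict),
    format = format
  )
  if (!is.null(file)) {
    writeLines(doc, file, sep = "", useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

#' Read an interaction dataset from Turtle or N-Triples
#'
#' Convenience wrapper: [parse_graph()] then [from_triples()].
#'
#' @param input path to a file, or document text.
#' @param format `"turtle"` or `"ntriples"`.
#' @param registry registry for IRI-to-text recovery.
#' @param according_to see [from_triples()].
#' @return a `ppi_dataset`.
#' @export
read_rdf <- function(input, format = c("turtle", "ntriples"),
                     registry = ppi_default_registry(), according_to = "") {
  format <- match.arg(format)
  text <- if (length(input) == 1 && !grepl("\n", input) &&
              file.exists(input)) {
    readChar(input, file.size(input), useBytes = TRUE)
  } else {
    input
  }
  from_triples(parse_graph(text, format = format), registry = registry,
               according_to = according_to)
}
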