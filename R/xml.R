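# XML serialization: one namespaced document holding flat Event, Occurrence,
# MeasurementOrFact and ResourceRelationship elements. One-to-many links are
# expressed by ID references: each measurement appears exactly once as a
# MeasurementOrFact element, and the event or occurrence that owns it repeats
# the measurementID as a reference child. Occurrences reference their event
# via an eventID child, mirroring the archive star schema.

XML_ROOT <- "interactionDataset"

xml_term_prefix <- function(name) {
  if (name %in% DWC_TERMS) "dwc" else "ppil"
}

add_field_children <- function(node, row, skip = character(0)) {
  for (col in names(row)) {
    val <- row[[col]]
    if (col %in% skip || !nzchar(val)) next
    xml2::xml_add_child(node, paste0(xml_term_prefix(col), ":", col), val)
  }
}

#' Serialize an interaction dataset as XML
#'
#' @param dataset a valid `ppi_dataset`.
#' @param registry registry used for the validity pre-check.
#' @param file optional path; when given the document is also written there.
#' @return the XML document as a character string (invisibly when `file` is
#'   given).
#' @export
write_ppi_xml <- function(dataset, registry = ppi_default_registry(),
                          file = NULL) {
  stopifnot(inherits(dataset, "ppi_dataset"))
  rep <- validate_dataset(dataset, registry)
  if (!rep$is_valid) {
    stop("refusing to serialize an invalid dataset (",
         sum(rep$findings$severity == "error"), " error(s))", call. = FALSE)
  }
  doc <- xml2::xml_new_root(
    XML_ROOT,
    "xmlns:dwc" = NS$dwc,
    "xmlns:ppil" = NS$local
  )
  if (nzchar(dataset$provenance)) {
    xml2::xml_set_attr(doc, "provenance", dataset$provenance)
  }
  me <- dataset$measurements
  ev_ids <- dataset$events$eventID
  oc_ids <- dataset$occurrences$occurrenceID

  refs_for <- function(owner_kind, owner_id) {
    if (owner_kind == "event") {
      me$measurementID[me$eventID == owner_id & !nzchar(me$occurrenceID)]
    } else {
      me$measurementID[me$occurrenceID == owner_id]
    }
  }

  for (i in seq_len(nrow(dataset$events))) {
    node <- xml2::xml_add_child(doc, "dwc:Event")
    add_field_children(node, dataset$events[i, , drop = FALSE])
    for (mid in refs_for("event", ev_ids[i])) {
      xml2::xml_add_child(node, "dwc:measurementID", mid)
    }
  }
  for (i in seq_len(nrow(dataset$occurrences))) {
    node <- xml2::xml_add_child(doc, "dwc:Occurrence")
    add_field_children(node, dataset$occurrences[i, , drop = FALSE])
    for (mid in refs_for("occurrence", oc_ids[i])) {
      xml2::xml_add_child(node, "dwc:measurementID", mid)
    }
  }
  # each measurement exactly once, owner links live on the owning elements
  me_unique <- me[!duplicated(me$measurementID) | !nzchar(me$measurementID), ,
                  drop = FALSE]
  for (i in seq_len(nrow(me_unique))) {
    node <- xml2::xml_add_child(doc, "dwc:MeasurementOrFact")
    add_field_children(node, me_unique[i, , drop = FALSE],
                       skip = c("eventID", "occurrenceID"))
  }
  for (i in seq_len(nrow(dataset$relationships))) {
    node <- xml2::xml_add_child(doc, "dwc:ResourceRelationship")
    add_field_children(node, dataset$relationships[i, , drop = FALSE])
  }
  out <- as.character(doc)
  if (!is.null(file)) {
    writeLines(out, file, sep = "", useBytes = TRUE)
    return(invisible(out))
  }
  out
}

xml_local_name <- function(node) {
  sub(".*:", "", xml2::xml_name(node))
}

collect_fields <- function(node) {
  kids <- xml2::xml_children(node)
  nm <- vapply(kids, xml_local_name, "")
  val <- vapply(kids, xml2::xml_text, "")
  list(names = nm, values = val)
}

#' Read an interaction dataset from XML
#'
#' Inverse of [write_ppi_xml()]: resolves `measurementID` references back to
#' event- or occurrence-level measurements. Documents carrying a DOCTYPE
#' (external entity) declaration are rejected. References to measurements
#' that have no element are collected and surface as `DANGLING_REFERENCE`
#' findings on validation, not as a read failure.
#'
#' @param input path to an XML file, or a character string holding XML.
#' @return a `ppi_dataset`.
#' @export
read_ppi_xml <- function(input) {
  text <- if (!startsWith(trimws(substr(input, 1, 100)), "<")) {
    if (!file.exists(input)) stop("no such file: ", input, call. = FALSE)
    readChar(input, file.size(input), useBytes = TRUE)
  } else {
    input
  }
  if (grepl("<!DOCTYPE", text, fixed = TRUE) ||
      grepl("<!ENTITY", text, fixed = TRUE)) {
    stop("XML parse error: DOCTYPE/entity declarations are not allowed",
         call. = FALSE)
  }
  doc <- xml2::read_xml(text)
  prov <- xml2::xml_attr(doc, "provenance")
  if (is.na(prov)) prov <- ""

  events <- list(); occurrences <- list()
  measurements <- list(); relationships <- list()
  # owner references: (kind, owner id, measurement id)
  refs <- list()

  for (node in xml2::xml_children(doc)) {
    kind <- xml_local_name(node)
    fl <- collect_fields(node)
    if (kind %in% c("Event", "Occurrence")) {
      is_ref <- fl$names == "measurementID"
      row <- as.list(fl$values[!is_ref])
      names(row) <- fl$names[!is_ref]
      row <- row[!duplicated(names(row))]
      if (kind == "Event") {
        events[[length(events) + 1L]] <- row
        owner_id <- row$eventID %||% ""
        owner_kind <- "event"
      } else {
        occurrences[[length(occurrences) + 1L]] <- row
        owner_id <- row$occurrenceID %||% ""
        owner_kind <- "occurrence"
      }
      for (mid in fl$values[is_ref]) {
        refs[[length(refs) + 1L]] <- c(owner_kind, owner_id, mid)
      }
    } else if (kind == "MeasurementOrFact") {
      row <- as.list(fl$values)
      names(row) <- fl$names
      measurements[[length(measurements) + 1L]] <- row[!duplicated(names(row))]
    } else if (kind == "ResourceRelationship") {
      row <- as.list(fl$values)
      names(row) <- fl$names
      relationships[[length(relationships) + 1L]] <-
        row[!duplicated(names(row))]
    }
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

  ev <- rows_to_df(events)
  oc <- rows_to_df(occurrences)
  me <- rows_to_df(measurements)
  re <- rows_to_df(relationships)

  # resolve ownership from the references
  unresolved <- data.frame(kind = character(0), record = character(0),
                           ref = character(0), stringsAsFactors = FALSE)
  if (!is.null(me)) {
    me$eventID <- if (is.null(me$eventID)) character(nrow(me)) else me$eventID
    me$occurrenceID <- if (is.null(me$occurrenceID)) character(nrow(me)) else
      me$occurrenceID
  }
  for (r in refs) {
    owner_kind <- r[1]; owner_id <- r[2]; mid <- r[3]
    j <- if (is.null(me)) NA_integer_ else match(mid, me$measurementID)
    if (is.na(j)) {
      unresolved <- rbind(unresolved, data.frame(
        kind = owner_kind, record = owner_id, ref = mid,
        stringsAsFactors = FALSE))
      next
    }
    if (owner_kind == "event") {
      me$eventID[j] <- owner_id
    } else {
      me$occurrenceID[j] <- owner_id
      k <- match(owner_id, oc$occurrenceID)
      if (!is.na(k)) me$eventID[j] <- oc$eventID[k]
    }
  }
  ppi_dataset(events = ev, occurrences = oc, measurements = me,
              relationships = re, provenance = prov,
              unresolved = unresolved)
}
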