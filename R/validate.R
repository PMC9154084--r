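# The minimal-record validity contract. Every interaction must carry at
# least: a scientificName on each occurrence, an eventID on the event, and a
# relationship with subject, object, a relationship type (text or IRI) and a
# source (relationshipAccordingTo). Everything else is optional; problems
# against recommendations (controlled vocabularies, unknown measurement
# types) are warnings, not errors.

KIND_ORDER <- c(event = 1L, occurrence = 2L, measurement = 3L,
                relationship = 4L)

new_finding <- function(severity, code, kind, record, message) {
  data.frame(severity = severity, code = code, kind = kind, record = record,
             message = message, stringsAsFactors = FALSE)
}

record_ref <- function(ids, kind) {
  ifelse(nzchar(ids), ids, paste0(kind, "#", seq_along(ids)))
}

#' Validate an interaction dataset
#'
#' Checks the dataset against the minimal-record contract and referential
#' integrity. Errors (any one makes the dataset invalid):
#' `MISSING_SCIENTIFIC_NAME`, `MISSING_EVENT_ID`, `DANGLING_REFERENCE`,
#' `MISSING_RELATIONSHIP_TYPE`, `MISSING_ACCORDING_TO`, `SELF_RELATIONSHIP`,
#' `DUPLICATE_ID`. Warnings: `UNKNOWN_MEASUREMENT_TYPE` (measurement type IRI
#' not in the registry, or no type at all), `CV_VIOLATION` (value outside a
#' registry term's controlled vocabulary), `EVENT_WITHOUT_RELATIONSHIP`.
#' Empty reference fields are not flagged as dangling: the defect is reported
#' once, on the record whose identifier is missing — except a relationship's
#' `resourceID`/`relatedResourceID`, which the minimal contract requires, so
#' an empty value there is itself a `DANGLING_REFERENCE`.
#'
#' Findings are deterministic: sorted by record kind (event, occurrence,
#' measurement, relationship), record identifier, then code.
#'
#' @param dataset a `ppi_dataset`.
#' @param registry a `ppi_registry` used for measurement-type and
#'   controlled-vocabulary checks.
#' @return a `ppi_validation_report`: list with `findings` (data frame:
#'   severity, code, kind, record, message) and `is_valid`.
#' @export
#' @examples
#' d <- generate_dataset(fixture_profile(seed = 1))
#' validate_dataset(d)$is_valid
validate_dataset <- function(dataset, registry = ppi_default_registry()) {
  stopifnot(inherits(dataset, "ppi_dataset"))
  stopifnot(inherits(registry, "ppi_registry"))
  f <- list()
  ev <- dataset$events
  oc <- dataset$occurrences
  me <- dataset$measurements
  re <- dataset$relationships

  ev_ids <- trimws(ev$eventID)
  oc_ids <- trimws(oc$occurrenceID)
  ev_ref <- record_ref(ev_ids, "event")
  oc_ref <- record_ref(oc_ids, "occurrence")

  # duplicate identifiers, one finding per duplicated value
  for (part in names(ID_COLS)) {
    ids <- trimws(dataset[[part]][[ID_COLS[[part]]]])
    dup <- unique(ids[nzchar(ids) & duplicated(ids)])
    kind <- sub("s$", "", part)
    if (part == "relationships") kind <- "relationship"
    for (id in dup) {
      f[[length(f) + 1L]] <- new_finding(
        "error", "DUPLICATE_ID", kind, id,
        sprintf("identifier '%s' is used by more than one %s record", id, kind)
      )
    }
  }

  # events
  for (i in seq_len(nrow(ev))) {
    if (!nzchar(ev_ids[i])) {
      f[[length(f) + 1L]] <- new_finding(
        "error", "MISSING_EVENT_ID", "event", ev_ref[i],
        "event record has no eventID"
      )
    }
  }
  rel_ev <- trimws(re$eventID)
  no_rel <- setdiff(ev_ids[nzchar(ev_ids)], rel_ev)
  for (id in no_rel) {
    f[[length(f) + 1L]] <- new_finding(
      "warning", "EVENT_WITHOUT_RELATIONSHIP", "event", id,
      "event has no ResourceRelationship record"
    )
  }

  # occurrences
  for (i in seq_len(nrow(oc))) {
    if (!nzchar(trimws(oc$scientificName[i]))) {
      f[[length(f) + 1L]] <- new_finding(
        "error", "MISSING_SCIENTIFIC_NAME", "occurrence", oc_ref[i],
        "occurrence record has no scientificName"
      )
    }
    e <- trimws(oc$eventID[i])
    if (nzchar(e) && !(e %in% ev_ids)) {
      f[[length(f) + 1L]] <- new_finding(
        "error", "DANGLING_REFERENCE", "occurrence", oc_ref[i],
        sprintf("occurrence references unknown eventID '%s'", e)
      )
    }
  }

  # measurements
  me_ref <- record_ref(trimws(me$measurementID), "measurement")
  for (i in seq_len(nrow(me))) {
    e <- trimws(me$eventID[i])
    o <- trimws(me$occurrenceID[i])
    if (nzchar(e) && !(e %in% ev_ids)) {
      f[[length(f) + 1L]] <- new_finding(
        "error", "DANGLING_REFERENCE", "measurement", me_ref[i],
        sprintf("measurement references unknown eventID '%s'", e)
      )
    }
    if (nzchar(o)) {
      j <- match(o, oc_ids)
      if (is.na(j)) {
        f[[length(f) + 1L]] <- new_finding(
          "error", "DANGLING_REFERENCE", "measurement", me_ref[i],
          sprintf("measurement references unknown occurrenceID '%s'", o)
        )
      } else if (nzchar(e) && nzchar(trimws(oc$eventID[j])) &&
                 trimws(oc$eventID[j]) != e) {
        f[[length(f) + 1L]] <- new_finding(
          "error", "DANGLING_REFERENCE", "measurement", me_ref[i],
          sprintf("measurement occurrence '%s' belongs to a different event",
                  o)
        )
      }
    }
    tiri <- trimws(me$measurementTypeID[i])
    ttxt <- trimws(me$measurementType[i])
    term <- NULL
    if (nzchar(tiri)) {
      if (tiri %in% names(registry$by_iri)) {
        term <- registry$terms[[registry$by_iri[[tiri]]]]
      } else {
        f[[length(f) + 1L]] <- new_finding(
          "warning", "UNKNOWN_MEASUREMENT_TYPE", "measurement", me_ref[i],
          sprintf("measurementTypeID '%s' is not a registry term", tiri)
        )
      }
    } else if (!nzchar(ttxt)) {
      f[[length(f) + 1L]] <- new_finding(
        "warning", "UNKNOWN_MEASUREMENT_TYPE", "measurement", me_ref[i],
        "measurement has neither measurementType nor measurementTypeID"
      )
    } else if (ttxt %in% names(registry$terms)) {
      term <- registry$terms[[ttxt]]
    }
    val <- trimws(me$measurementValue[i])
    if (!is.null(term) && length(term$controlled_vocabulary) && nzchar(val)) {
      if (!validate_controlled_value(term, val)$accepted) {
        f[[length(f) + 1L]] <- new_finding(
          "warning", "CV_VIOLATION", "measurement", me_ref[i],
          sprintf("value '%s' is not in the controlled vocabulary of '%s'",
                  val, term$term_name)
        )
      }
    }
  }

  # relationships
  re_ref <- record_ref(trimws(re$resourceRelationshipID), "relationship")
  for (i in seq_len(nrow(re))) {
    e <- trimws(re$eventID[i])
    if (nzchar(e) && !(e %in% ev_ids)) {
      f[[length(f) + 1L]] <- new_finding(
        "error", "DANGLING_REFERENCE", "relationship", re_ref[i],
        sprintf("relationship references unknown eventID '%s'", e)
      )
    }
    subj <- trimws(re$resourceID[i])
    obj <- trimws(re$relatedResourceID[i])
    for (side in list(c("resourceID (subject)", subj),
                      c("relatedResourceID (object)", obj))) {
      id <- side[2]
      j <- match(id, oc_ids)
      if (!nzchar(id) || is.na(j)) {
        f[[length(f) + 1L]] <- new_finding(
          "error", "DANGLING_REFERENCE", "relationship", re_ref[i],
          sprintf("relationship %s does not resolve to an occurrence (value '%s')",
                  side[1], id)
        )
      } else if (nzchar(e) && nzchar(trimws(oc$eventID[j])) &&
                 trimws(oc$eventID[j]) != e) {
        f[[length(f) + 1L]] <- new_finding(
          "error", "DANGLING_REFERENCE", "relationship", re_ref[i],
          sprintf("relationship %s '%s' belongs to a different event",
                  side[1], id)
        )
      }
    }
    if (nzchar(subj) && subj == obj) {
      f[[length(f) + 1L]] <- new_finding(
        "error", "SELF_RELATIONSHIP", "relationship", re_ref[i],
        "relationship subject and object are the same occurrence"
      )
    }
    if (!nzchar(trimws(re$relationshipOfResource[i])) &&
        !nzchar(trimws(re$relationshipOfResourceID[i]))) {
      f[[length(f) + 1L]] <- new_finding(
        "error", "MISSING_RELATIONSHIP_TYPE", "relationship", re_ref[i],
        "relationship has neither relationshipOfResource nor relationshipOfResourceID"
      )
    }
    if (!nzchar(trimws(re$relationshipAccordingTo[i]))) {
      f[[length(f) + 1L]] <- new_finding(
        "error", "MISSING_ACCORDING_TO", "relationship", re_ref[i],
        "relationship has no relationshipAccordingTo (source of the interaction)"
      )
    }
  }

  # unresolved references collected by readers
  un <- attr(dataset, "unresolved")
  if (!is.null(un) && nrow(un)) {
    for (i in seq_len(nrow(un))) {
      f[[length(f) + 1L]] <- new_finding(
        "error", "DANGLING_REFERENCE", un$kind[i], un$record[i],
        sprintf("unresolved reference '%s' found while reading", un$ref[i])
      )
    }
  }

  findings <- if (length(f)) {
    do.call(rbind, f)
  } else {
    new_finding(character(0), character(0), character(0), character(0),
                character(0))
  }
  ord <- order(KIND_ORDER[findings$kind], findings$record, findings$code,
               method = "radix")
  findings <- findings[ord, , drop = FALSE]
  rownames(findings) <- NULL
  structure(
    list(findings = findings,
         is_valid = !any(findings$severity == "error")),
    class = "ppi_validation_report"
  )
}

#' @export
print.ppi_validation_report <- function(x, ...) {
  ne <- sum(x$findings$severity == "error")
  nw <- sum(x$findings$severity == "warning")
  cat(sprintf("<ppi_validation_report> %s (%d error(s), %d warning(s))\n",
              if (x$is_valid) "VALID" else "INVALID", ne, nw))
  if (nrow(x$findings)) {
    for (i in seq_len(nrow(x$findings))) {
      cat(sprintf("  %-7s %-25s %-12s %s\n", x$findings$severity[i],
                  x$findings$code[i], x$findings$record[i],
                  x$findings$message[i]))
    }
  }
  invisible(x)
}

#' Format a validation report for machine consumption
#'
#' One finding per line: `severity<TAB>code<TAB>record<TAB>message`.
#'
#' @param x a `ppi_validation_report`.
#' @param ... unused.
#' @return character vector of lines.
#' @export
format.ppi_validation_report <- function(x, ...) {
  if (!nrow(x$findings)) return(character(0))
  paste(x$findings$severity, x$findings$code, x$findings$record,
        x$findings$message, sep = "\t")
}
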