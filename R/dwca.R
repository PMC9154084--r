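# Darwin Core Archive serialization: the sampling-event star schema with an
# Event core and Occurrence, ExtendedMeasurementOrFact and ResourceRelationship
# extensions, all keyed by eventID. The eMoF rows additionally carry
# occurrenceID — empty for measurements of the interaction itself, filled for
# measurements of one participating organism — which is how measurement rows
# escape the one-core-id limitation of the star schema.

DWCA_FILES <- c(
  event = "event.csv", occurrence = "occurrence.csv",
  emof = "extendedmeasurementorfact.csv",
  relationship = "resourcerelationship.csv"
)

emof_columns <- function(extras = character(0)) {
  c("eventID", "occurrenceID", "measurementID", "measurementType",
    "measurementTypeID", "measurementValue", "measurementValueID",
    "measurementUnit", "measurementUnitID", extras)
}

#' The eMoF table schema and its delta against classic MeasurementOrFact
#'
#' Returns the column set of the written ExtendedMeasurementOrFact extension
#' table and, as the `"new_terms"` attribute, the columns absent from the
#' classic Darwin Core MeasurementOrFact property set (the star-schema
#' linkage key `eventID`/`occurrenceID` excluded, since those are
#' pre-existing Darwin Core terms): `measurementTypeID`,
#' `measurementValueID`, `measurementUnitID`.
#'
#' @return character vector of column names with attribute `new_terms`.
#' @export
emof_schema <- function() {
  cols <- emof_columns()
  new_terms <- setdiff(cols, c(MOF_CLASSIC_TERMS, "eventID", "occurrenceID"))
  structure(cols, new_terms = new_terms)
}

order_columns <- function(df, lead) {
  df[, c(lead, setdiff(names(df), lead)), drop = FALSE]
}

enrich_measurements <- function(me, registry) {
  for (i in seq_len(nrow(me))) {
    ttxt <- trimws(me$measurementType[i])
    if (!nzchar(me$measurementTypeID[i]) && nzchar(ttxt) &&
        ttxt %in% names(registry$terms)) {
      term <- registry$terms[[ttxt]]
      me$measurementTypeID[i] <- term$iri
      val <- trimws(me$measurementValue[i])
      if (!nzchar(me$measurementValueID[i]) && nzchar(val)) {
        v <- validate_controlled_value(term, val)
        if (v$accepted && !is.na(v$value_iri)) {
          me$measurementValueID[i] <- v$value_iri
        }
      }
    }
  }
  me
}

meta_table_node <- function(doc, parent, tag, row_type, file, cols,
                            is_core) {
  node <- xml2::xml_add_child(parent, tag)
  xml2::xml_set_attrs(node, c(
    rowType = row_type, encoding = "UTF-8",
    fieldsTerminatedBy = ",", linesTerminatedBy = "\\n",
    fieldsEnclosedBy = "\"", ignoreHeaderLines = "1"
  ))
  files <- xml2::xml_add_child(node, "files")
  xml2::xml_add_child(files, "location", file)
  idnode <- xml2::xml_add_child(node, if (is_core) "id" else "coreid")
  xml2::xml_set_attr(idnode, "index", "0")
  for (i in seq_along(cols)) {
    fnode <- xml2::xml_add_child(node, "field")
    xml2::xml_set_attrs(fnode, c(index = as.character(i - 1),
                                 term = term_iri(cols[i])))
  }
  node
}

#' Write an interaction dataset as a Darwin Core Archive
#'
#' Emits a zip with `meta.xml`, a minimal metadata stub (`eml.xml`) and four
#' tables: the Event core plus Occurrence, ExtendedMeasurementOrFact and
#' ResourceRelationship extensions (see [emof_schema()] for the eMoF
#' columns). When a measurement's human-readable type names a registry term
#' and its `measurementTypeID` is empty, the term IRI (and a matching
#' controlled-vocabulary value IRI, if the registry carries one) is filled
#' in, following the recommendation that the ID terms reference controlled
#' vocabularies by URI.
#'
#' @param dataset a valid `ppi_dataset`.
#' @param path destination `.zip` path.
#' @param registry registry used for validation and measurement enrichment.
#' @return `path`, invisibly.
#' @export
write_dwca <- function(dataset, path, registry = ppi_default_registry()) {
  stopifnot(inherits(dataset, "ppi_dataset"))
  rep <- validate_dataset(dataset, registry)
  if (!rep$is_valid) {
    stop("refusing to write an invalid dataset (",
         sum(rep$findings$severity == "error"), " error(s))", call. = FALSE)
  }
  ev <- order_columns(dataset$events, "eventID")
  oc <- order_columns(dataset$occurrences,
                      c("eventID", "occurrenceID", "scientificName",
                        "taxonRank", "occurrenceRemarks"))
  me <- enrich_measurements(dataset$measurements, registry)
  me <- order_columns(me, emof_columns())
  re <- order_columns(dataset$relationships,
                      c("eventID", "resourceRelationshipID", "resourceID",
                        "relatedResourceID", "relationshipOfResource",
                        "relationshipOfResourceID", "relationshipAccordingTo"))

  doc <- xml2::xml_new_root("archive",
                            xmlns = "http://rs.tdwg.org/dwc/text/",
                            metadata = "eml.xml")
  meta_table_node(doc, doc, "core", ROW_TYPES$event, DWCA_FILES[["event"]],
                  names(ev), is_core = TRUE)
  ext <- list(
    list(ROW_TYPES$occurrence, "occurrence", oc),
    list(ROW_TYPES$emof, "emof", me),
    list(ROW_TYPES$relationship, "relationship", re)
  )
  for (e in ext) {
    meta_table_node(doc, doc, "extension", e[[1]], DWCA_FILES[[e[[2]]]],
                    names(e[[3]]), is_core = FALSE)
  }
  meta_xml <- as.character(doc)

  title <- if (nzchar(dataset$provenance)) dataset$provenance else
    "Plant-pollinator interaction dataset"
  eml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<eml:eml xmlns:eml=\"https://eml.ecoinformatics.org/eml-2.2.0\" ",
    "packageId=\"ppitools-dataset\" system=\"ppitools\">\n",
    "  <dataset>\n",
    "    <title>", xml_escape(title), "</title>\n",
    "    <abstract><para>", xml_escape(dataset$provenance),
    "</para></abstract>\n",
    "  </dataset>\n</eml:eml>\n"
  )

  zip_write(path, list(
    "meta.xml" = meta_xml,
    "eml.xml" = eml,
    "event.csv" = format_csv(ev),
    "occurrence.csv" = format_csv(oc),
    "extendedmeasurementorfact.csv" = format_csv(me),
    "resourcerelationship.csv" = format_csv(re)
  ))
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# meta.xml queries must work whether or not the document declares the
# Darwin Core text namespace; build the xpath for whichever applies
meta_find <- function(node, names, nested = FALSE, first = FALSE) {
  ns <- xml2::xml_ns(node)
  pre <- if ("d1" %in% names(ns)) "d1:" else ""
  path <- if (nested) {
    paste0(".//", pre, names[1], "/", pre, names[2])
  } else {
    paste(paste0(pre, names), collapse = "|")
  }
  if (nzchar(pre)) {
    if (first) xml2::xml_find_first(node, path, ns) else
      xml2::xml_find_all(node, path, ns)
  } else {
    if (first) xml2::xml_find_first(node, path) else
      xml2::xml_find_all(node, path)
  }
}

read_dwca_table <- function(dir, node) {
  loc <- xml2::xml_text(meta_find(node, c("files", "location"),
                                  nested = TRUE, first = TRUE))
  sep <- xml2::xml_attr(node, "fieldsTerminatedBy")
  if (is.na(sep) || sep == "\\t") sep <- if (is.na(sep)) "," else "\t"
  skip <- xml2::xml_attr(node, "ignoreHeaderLines")
  skip <- if (is.na(skip)) 0L else as.integer(skip)
  quote_ch <- xml2::xml_attr(node, "fieldsEnclosedBy")
  if (is.na(quote_ch)) quote_ch <- "\""

  fields <- meta_find(node, "field")
  idx <- as.integer(xml2::xml_attr(fields, "index"))
  terms <- iri_local_name(xml2::xml_attr(fields, "term"))
  idnode <- meta_find(node, c("id", "coreid"), first = TRUE)
  id_idx <- as.integer(xml2::xml_attr(idnode, "index"))

  path <- file.path(dir, loc)
  if (!file.exists(path)) {
    stop("archive table file missing: ", loc, call. = FALSE)
  }
  n_lines <- length(readLines(path, warn = FALSE))
  df <- if (n_lines <= skip) {
    # header-only (or empty) table: zero data rows
    as.data.frame(stats::setNames(
      rep(list(character(0)), max(c(idx, id_idx), na.rm = TRUE) + 1L),
      paste0("col", seq_len(max(c(idx, id_idx), na.rm = TRUE) + 1L) - 1L)
    ), check.names = FALSE)
  } else {
    utils::read.table(
      path, sep = sep, quote = quote_ch, skip = skip, header = FALSE,
      colClasses = "character", na.strings = character(0),
      fileEncoding = "UTF-8", fill = TRUE, comment.char = ""
    )
  }
  ncol_needed <- max(c(idx, id_idx), na.rm = TRUE) + 1L
  while (ncol(df) < ncol_needed) df[[ncol(df) + 1L]] <- ""
  cols <- paste0("col", seq_len(ncol(df)) - 1L)
  cols[idx + 1L] <- terms
  if (!is.na(id_idx) && !((id_idx) %in% idx)) cols[id_idx + 1L] <- "eventID"
  names(df) <- cols
  df <- df[, !startsWith(names(df), "col"), drop = FALSE]
  df[, !duplicated(names(df)), drop = FALSE]
}

#' Read a Darwin Core Archive into an interaction dataset
#'
#' Column meaning is taken from the term IRIs declared in `meta.xml`, not
#' from column position; columns with terms outside the data model land in
#' the extra columns of each table. The core row type must be the Darwin
#' Core Event class.
#'
#' @param path path to a DwC-A zip file.
#' @return a `ppi_dataset`.
#' @export
read_dwca <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dir <- tempfile("dwca")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  utils::unzip(path, exdir = dir)
  meta_path <- file.path(dir, "meta.xml")
  if (!file.exists(meta_path)) {
    stop("archive manifest error: no meta.xml in ", path, call. = FALSE)
  }
  meta <- xml2::read_xml(meta_path)
  core <- meta_find(meta, "core", first = TRUE)
  core_type <- xml2::xml_attr(core, "rowType")
  if (!identical(core_type, ROW_TYPES$event)) {
    stop("archive schema error: core row type is '", core_type,
         "', expected the Event class (", ROW_TYPES$event, ")",
         call. = FALSE)
  }
  events <- read_dwca_table(dir, core)
  exts <- meta_find(meta, "extension")
  occurrences <- measurements <- relationships <- NULL
  for (node in exts) {
    rt <- xml2::xml_attr(node, "rowType")
    tab <- read_dwca_table(dir, node)
    if (identical(rt, ROW_TYPES$occurrence)) {
      occurrences <- tab
    } else if (identical(rt, ROW_TYPES$emof)) {
      measurements <- tab
    } else if (identical(rt, ROW_TYPES$relationship)) {
      relationships <- tab
    } else {
      message("ignoring extension with unhandled row type: ", rt)
    }
  }
  prov <- ""
  eml_path <- file.path(dir, "eml.xml")
  if (file.exists(eml_path)) {
    eml <- xml2::read_xml(eml_path)
    para <- xml2::xml_find_first(eml, ".//abstract/para")
    if (!inherits(para, "xml_missing")) prov <- xml2::xml_text(para)
  }
  ppi_dataset(events = events, occurrences = occurrences,
              measurements = measurements, relationships = relationships,
              provenance = prov)
}
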