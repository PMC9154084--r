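# The PPI vocabulary registry: terms defined with the normative elements of
# the TDWG Standards Documentation Standard (name, IRI, definition, modified
# date, type "Property"), organized in six informal categories, with optional
# recommended controlled vocabularies.

PPI_CATEGORIES <- c(
  "Animal", "Plant", "Flower", "Interaction",
  "Reproductive Success", "Nectar Dynamics"
)

REGISTRY_REQUIRED_COLS <- c("term_name", "iri", "category", "definition")
REGISTRY_ALL_COLS <- c(
  "term_name", "label", "iri", "category", "definition", "comments",
  "details", "protocol", "controlled_vocabulary", "controlled_vocabulary_iris",
  "examples", "modified", "term_type"
)

new_ppi_term <- function(term_name, label, iri, category, definition,
                         comments = "", details = "", protocol = "",
                         controlled_vocabulary = character(0),
                         controlled_vocabulary_iris = character(0),
                         examples = "", modified = "", term_type = "Property") {
  structure(
    list(
      term_name = term_name, label = label, iri = iri, category = category,
      definition = definition, comments = comments, details = details,
      protocol = protocol,
      controlled_vocabulary = controlled_vocabulary,
      controlled_vocabulary_iris = controlled_vocabulary_iris,
      examples = examples, modified = modified, term_type = term_type
    ),
    class = "ppi_term"
  )
}

#' @export
print.ppi_term <- function(x, ...) {
  cat(sprintf("<ppi_term> %s [%s]\n", x$term_name, x$category))
  cat("  IRI:        ", x$iri, "\n", sep = "")
  cat("  Definition: ", x$definition, "\n", sep = "")
  if (length(x$controlled_vocabulary)) {
    cat("  CV:         ", paste(x$controlled_vocabulary, collapse = "; "),
        "\n", sep = "")
  }
  invisible(x)
}

split_cv <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  v <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  v[nzchar(v)]
}

#' Load a PPI term registry
#'
#' Reads a vocabulary of terms from a tabular (CSV) file or a structured
#' configuration (YAML) file and builds an indexed registry. The tabular form
#' has one row per term with a `;`-delimited `controlled_vocabulary` column,
#' mirroring the term template used to define the vocabulary. Required columns
#' (or keys): `term_name`, `iri`, `category`, `definition`.
#'
#' @param source path to the registry file.
#' @param format `"csv"` (tabular) or `"yaml"` (structured config). Default is
#'   guessed from the file extension.
#' @param version optional version string stored on the registry.
#' @return an object of class `ppi_registry`.
#' @export
#' @examples
#' reg <- ppi_default_registry()
#' length(reg$terms)
load_registry <- function(source, format = c("auto", "csv", "yaml"),
                          version = "") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(source))
    format <- if (ext %in% c("yml", "yaml")) "yaml" else "csv"
  }
  if (format == "csv") {
    df <- read_csv_strict(source)
    missing <- setdiff(REGISTRY_REQUIRED_COLS, names(df))
    if (length(missing)) {
      stop("registry schema error: missing required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    for (col in setdiff(REGISTRY_ALL_COLS, names(df))) {
      df[[col]] <- character(nrow(df))
    }
    rows <- lapply(seq_len(nrow(df)), function(i) {
      new_ppi_term(
        term_name = trimws(df$term_name[i]),
        label = trimws(df$label[i]),
        iri = trimws(df$iri[i]),
        category = trimws(df$category[i]),
        definition = trimws(df$definition[i]),
        comments = df$comments[i],
        details = df$details[i],
        protocol = df$protocol[i],
        controlled_vocabulary = split_cv(df$controlled_vocabulary[i]),
        controlled_vocabulary_iris = split_cv(df$controlled_vocabulary_iris[i]),
        examples = df$examples[i],
        modified = df$modified[i],
        term_type = if (nzchar(trimws(df$term_type[i]))) {
          trimws(df$term_type[i])
        } else {
          "Property"
        }
      )
    })
  } else {
    doc <- yaml::read_yaml(source)
    entries <- if (!is.null(doc$terms)) doc$terms else doc
    if (!is.null(doc$version) && !nzchar(version)) version <- doc$version
    rows <- lapply(entries, function(e) {
      missing <- setdiff(REGISTRY_REQUIRED_COLS, names(e))
      if (length(missing)) {
        stop("registry schema error: missing required column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      cv <- e$controlled_vocabulary
      if (is.null(cv)) cv <- character(0)
      if (length(cv) == 1L && grepl(";", cv)) cv <- split_cv(cv)
      cvi <- e$controlled_vocabulary_iris
      if (is.null(cvi)) cvi <- character(0)
      new_ppi_term(
        term_name = e$term_name, label = e$label %||% "", iri = e$iri,
        category = e$category, definition = e$definition,
        comments = e$comments %||% "", details = e$details %||% "",
        protocol = e$protocol %||% "",
        controlled_vocabulary = trimws(as.character(cv)),
        controlled_vocabulary_iris = trimws(as.character(cvi)),
        examples = e$examples %||% "", modified = e$modified %||% "",
        term_type = e$term_type %||% "Property"
      )
    })
  }
  build_registry(rows, version = version)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_registry <- function(terms, version = "") {
  names(terms) <- vapply(terms, `[[`, "", "term_name")
  iris <- vapply(terms, `[[`, "", "iri")
  if (any(!nzchar(iris))) {
    stop("registry error: every term must have a non-empty IRI", call. = FALSE)
  }
  dup <- iris[duplicated(iris)]
  if (length(dup)) {
    stop("registry uniqueness error: duplicate IRI(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  dupn <- names(terms)[duplicated(names(terms))]
  if (length(dupn)) {
    stop("registry uniqueness error: duplicate term name(s): ",
         paste(unique(dupn), collapse = ", "), call. = FALSE)
  }
  cats <- vapply(terms, `[[`, "", "category")
  bad <- setdiff(unique(cats), PPI_CATEGORIES)
  if (length(bad)) {
    stop("registry category error: unknown category token(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (t in terms) {
    cv <- t$controlled_vocabulary
    if (length(cv) && anyDuplicated(cv)) {
      stop("registry error: duplicate controlled-vocabulary values for term ",
           t$term_name, call. = FALSE)
    }
  }
  structure(
    list(
      terms = terms,
      by_iri = stats::setNames(names(terms), iris),
      version = version
    ),
    class = "ppi_registry"
  )
}

#' @export
print.ppi_registry <- function(x, ...) {
  cats <- table(vapply(x$terms, `[[`, "", "category"))
  cat(sprintf("<ppi_registry> %d terms in %d categories\n",
              length(x$terms), length(cats)))
  for (nm in names(cats)) cat(sprintf("  %-20s %d\n", nm, cats[[nm]]))
  invisible(x)
}

#' The bundled PPI vocabulary
#'
#' Returns the registry bundled with the package: 48 Property terms in six
#' categories (Animal, Plant, Flower, Interaction, Reproductive Success,
#' Nectar Dynamics). The handful of terms that are fixed points of the
#' published vocabulary (e.g. `flowerOpeningType` with its controlled
#' vocabulary, `flowerColor`, `floralAttractants`, `caste`,
#' `resourceCollected`, `nectarCollectingBodyPart`,
#' `numberOfRemovedPollenGrains`) carry their published names and IRIs; the
#' remaining entries are a synthetic reconstruction of a working pollination
#' vocabulary and are shipped in a file whose name says so
#' (`extdata/ppi-terms-synthetic.csv`).
#'
#' @return a `ppi_registry`.
#' @export
ppi_default_registry <- function() {
  if (is.null(.ppi_cache$registry)) {
    path <- system.file("extdata", "ppi-terms-synthetic.csv",
                        package = "ppitools", mustWork = TRUE)
    .ppi_cache$registry <- load_registry(path, format = "csv",
                                         version = "synthetic-1.0")
  }
  .ppi_cache$registry
}

.ppi_cache <- new.env(parent = emptyenv())

#' Look up a term by name or IRI
#'
#' Resolves by term name first, then by IRI.
#'
#' @param registry a `ppi_registry`.
#' @param key term name token or full IRI.
#' @return a `ppi_term`.
#' @export
#' @examples
#' get_term(ppi_default_registry(), "flowerOpeningType")$category
get_term <- function(registry, key) {
  stopifnot(inherits(registry, "ppi_registry"))
  if (key %in% names(registry$terms)) return(registry$terms[[key]])
  if (key %in% names(registry$by_iri)) {
    return(registry$terms[[registry$by_iri[[key]]]])
  }
  stop("term not found in registry: ", key, call. = FALSE)
}

#' Test a value against a term's controlled vocabulary
#'
#' Controlled vocabularies in this standard are recommendations, not
#' restrictions: a term without one accepts any non-empty value. For a term
#' with a controlled vocabulary, membership is tested after trimming
#' whitespace; comparison is case-sensitive by default.
#'
#' @param term a `ppi_term`.
#' @param value character value to test.
#' @param case_sensitive compare case-sensitively (default `TRUE`).
#' @return a list with `accepted` (logical) and `value_iri` (the IRI paired
#'   with the matched value, or `NA_character_`).
#' @export
#' @examples
#' t <- get_term(ppi_default_registry(), "flowerOpeningType")
#' validate_controlled_value(t, "cleistogamous")$accepted
validate_controlled_value <- function(term, value, case_sensitive = TRUE) {
  stopifnot(inherits(term, "ppi_term"))
  value <- trimws(value)
  cv <- term$controlled_vocabulary
  if (!length(cv)) {
    return(list(accepted = nzchar(value), value_iri = NA_character_))
  }
  hit <- if (case_sensitive) {
    match(value, cv)
  } else {
    match(tolower(value), tolower(cv))
  }
  if (is.na(hit)) return(list(accepted = FALSE, value_iri = NA_character_))
  iri <- if (length(term$controlled_vocabulary_iris) >= hit) {
    term$controlled_vocabulary_iris[[hit]]
  } else {
    NA_character_
  }
  if (!is.na(iri) && !nzchar(iri)) iri <- NA_character_
  list(accepted = TRUE, value_iri = iri)
}

registry_to_data_frame <- function(registry) {
  if (!length(registry$terms)) return(NULL)
  rows <- lapply(registry$terms, function(t) {
    data.frame(
      term_name = t$term_name, label = t$label, iri = t$iri,
      category = t$category, definition = t$definition,
      comments = t$comments, details = t$details, protocol = t$protocol,
      controlled_vocabulary = paste(t$controlled_vocabulary, collapse = ";"),
      controlled_vocabulary_iris =
        paste(t$controlled_vocabulary_iris, collapse = ";"),
      examples = t$examples, modified = t$modified, term_type = t$term_type,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Export a registry
#'
#' Tabular export round-trips through [load_registry()]; RDF export declares
#' each term as an `rdf:Property` with label, definition (`rdfs:comment`) and
#' modified date statements, serialized as Turtle.
#'
#' @param registry a `ppi_registry`.
#' @param format `"csv"` or `"rdf"`.
#' @param file optional path; when given the document is also written there.
#' @return the document as a single character string (invisibly when `file`
#'   is given).
#' @export
export_term_list <- function(registry, format = c("csv", "rdf"), file = NULL) {
  stopifnot(inherits(registry, "ppi_registry"))
  if (!is.character(format) || !format[1] %in% c("csv", "rdf")) {
    stop("unsupported export format: ", format[1], call. = FALSE)
  }
  format <- format[1]
  if (format == "csv") {
    df <- registry_to_data_frame(registry)
    if (is.null(df)) {
      df <- as.data.frame(
        stats::setNames(rep(list(character(0)), length(REGISTRY_ALL_COLS)),
                        REGISTRY_ALL_COLS)
      )
    }
    doc <- format_csv(df)
  } else {
    tr <- empty_triples()
    for (t in registry$terms) {
      s <- t$iri
      tr <- add_triple(tr, s, paste0(NS$rdf, "type"),
                       paste0(NS$rdf, "Property"), "iri")
      if (nzchar(t$label)) {
        tr <- add_triple(tr, s, paste0(NS$rdfs, "label"), t$label, "literal")
      }
      tr <- add_triple(tr, s, paste0(NS$rdfs, "comment"), t$definition,
                       "literal")
      if (nzchar(t$modified)) {
        tr <- add_triple(tr, s, paste0(NS$dcterms, "modified"), t$modified,
                         "literal", datatype = paste0(NS$xsd, "date"))
      }
    }
    doc <- serialize_graph(tr, format = "turtle")
  }
  if (!is.null(file)) {
    writeLines(doc, file, sep = "", useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}
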