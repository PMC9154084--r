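# A small triple store with Turtle and N-Triples writers/parsers. Nothing in
# the installed R library speaks RDF, so the graph machinery is part of the
# package. The Turtle writer emits a prefix prologue and one statement per
# line; the parser reads that dialect (@prefix declarations, prefixed names,
# full IRIs, plain and datatyped literals, `a` for rdf:type), which keeps the
# grammar small while staying valid Turtle for any conformant consumer.

empty_triples <- function() {
  structure(
    data.frame(subject = character(0), predicate = character(0),
               object = character(0), object_type = character(0),
               datatype = character(0), stringsAsFactors = FALSE),
    class = c("ppi_triples", "data.frame")
  )
}

add_triple <- function(triples, subject, predicate, object,
                       object_type = c("iri", "literal"), datatype = "") {
  object_type <- match.arg(object_type)
  row <- data.frame(subject = subject, predicate = predicate, object = object,
                    object_type = object_type, datatype = datatype,
                    stringsAsFactors = FALSE)
  structure(rbind(triples, row), class = c("ppi_triples", "data.frame"))
}

as_triples <- function(df) {
  stopifnot(all(c("subject", "predicate", "object", "object_type",
                  "datatype") %in% names(df)))
  rownames(df) <- NULL
  structure(df, class = c("ppi_triples", "data.frame"))
}

#' @export
print.ppi_triples <- function(x, ...) {
  cat(sprintf("<ppi_triples> %d triple(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

canonical_triples <- function(triples) {
  df <- as.data.frame(triples)[, c("subject", "predicate", "object",
                                   "object_type", "datatype")]
  df <- unique(df)
  df <- df[order(df$subject, df$predicate, df$object, df$object_type,
                 df$datatype, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Set equality of two triple collections
#' @param a,b triple data frames.
#' @return `TRUE` or `FALSE`.
#' @export
triples_equal <- function(a, b) {
  identical(canonical_triples(a), canonical_triples(b))
}

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (k in seq_along(x)) {
    s <- x[k]
    res <- character(0)
    i <- 1L
    n <- nchar(s)
    while (i <= n) {
      ch <- substr(s, i, i)
      if (ch == "\\" && i < n) {
        nxt <- substr(s, i + 1L, i + 1L)
        rep <- switch(nxt, n = "\n", r = "\r", t = "\t",
                      '"' = '"', "\\" = "\\", u = NA, U = NA, nxt)
        if (is.na(rep)) {
          width <- if (nxt == "u") 4L else 8L
          code <- strtoi(substr(s, i + 2L, i + 1L + width), 16L)
          res <- c(res, intToUtf8(code))
          i <- i + 2L + width
          next
        }
        res <- c(res, rep)
        i <- i + 2L
      } else {
        res <- c(res, ch)
        i <- i + 1L
      }
    }
    out[k] <- paste(res, collapse = "")
  }
  out
}

# prefixes used in the Turtle prologue, longest-namespace first for
# unambiguous abbreviation (obo is a prefix of ro's expansion)
turtle_prefixes <- function() {
  ns <- unlist(NS)
  ns[order(-nchar(ns))]
}

abbreviate_iri <- function(iri, prefixes) {
  for (p in names(prefixes)) {
    base <- prefixes[[p]]
    if (startsWith(iri, base)) {
      local <- substr(iri, nchar(base) + 1L, nchar(iri))
      if (grepl("^[A-Za-z_][A-Za-z0-9_-]*$", local) ||
          grepl("^[0-9]+$", local)) {
        return(paste0(p, ":", local))
      }
    }
  }
  paste0("<", iri, ">")
}

format_term <- function(iri, format, prefixes) {
  if (format == "ntriples") return(paste0("<", iri, ">"))
  abbreviate_iri(iri, prefixes)
}

format_object <- function(o, type, datatype, format, prefixes) {
  if (type == "iri") return(format_term(o, format, prefixes))
  lit <- paste0('"', escape_literal(o), '"')
  if (nzchar(datatype)) {
    lit <- paste0(lit, "^^", format_term(datatype, format, prefixes))
  }
  lit
}

#' Serialize a triple collection
#'
#' @param triples a triple data frame (from [to_triples()] or built with the
#'   internal constructors).
#' @param format `"turtle"` or `"ntriples"`.
#' @return the document as a single character string.
#' @export
serialize_graph <- function(triples, format = c("turtle", "ntriples")) {
  format <- match.arg(format)
  df <- canonical_triples(triples)
  prefixes <- turtle_prefixes()
  lines <- character(0)
  if (format == "turtle") {
    lines <- sprintf("@prefix %s: <%s> .", names(prefixes), prefixes)
    lines <- c(lines, "")
  }
  if (nrow(df)) {
    stmt <- vapply(seq_len(nrow(df)), function(i) {
      pred <- df$predicate[i]
      pred_txt <- if (format == "turtle" &&
                      pred == paste0(NS$rdf, "type")) {
        "a"
      } else {
        format_term(pred, format, prefixes)
      }
      paste(
        format_term(df$subject[i], format, prefixes),
        pred_txt,
        format_object(df$object[i], df$object_type[i], df$datatype[i],
                      format, prefixes),
        "."
      )
    }, "")
    lines <- c(lines, stmt)
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

tokenize_statement <- function(line) {
  tokens <- character(0)
  i <- 1L
  n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch == "<") {
      j <- regexpr(">", substr(line, i, n), fixed = TRUE)
      if (j < 0) stop("RDF parse error: unterminated IRI", call. = FALSE)
      tokens <- c(tokens, substr(line, i, i + j - 1L))
      i <- i + j
    } else if (ch == '"') {
      j <- i + 1L
      while (j <= n) {
        cj <- substr(line, j, j)
        if (cj == "\\") { j <- j + 2L; next }
        if (cj == '"') break
        j <- j + 1L
      }
      if (j > n) stop("RDF parse error: unterminated literal", call. = FALSE)
      end <- j
      # optional ^^datatype
      if (substr(line, j + 1L, j + 2L) == "^^") {
        k <- j + 3L
        if (substr(line, k, k) == "<") {
          m <- regexpr(">", substr(line, k, n), fixed = TRUE)
          end <- k + m - 1L
        } else {
          m <- regexpr("[ \t]|$", substr(line, k, n))
          end <- k + m - 2L
        }
      }
      tokens <- c(tokens, substr(line, i, end))
      i <- end + 1L
    } else if (ch == ".") {
      tokens <- c(tokens, ".")
      i <- i + 1L
    } else {
      m <- regexpr("[ \t]|$", substr(line, i, n))
      tokens <- c(tokens, substr(line, i, i + m - 2L))
      i <- i + m
    }
  }
  tokens
}

resolve_term <- function(token, prefixes) {
  if (startsWith(token, "<")) {
    return(substr(token, 2L, nchar(token) - 1L))
  }
  if (token == "a") return(paste0(NS$rdf, "type"))
  colon <- regexpr(":", token, fixed = TRUE)
  if (colon < 0) {
    stop("RDF parse error: cannot resolve term '", token, "'", call. = FALSE)
  }
  p <- substr(token, 1L, colon - 1L)
  if (!p %in% names(prefixes)) {
    stop("RDF parse error: undeclared prefix '", p, "'", call. = FALSE)
  }
  paste0(prefixes[[p]], substr(token, colon + 1L, nchar(token)))
}

parse_object_token <- function(token, prefixes) {
  if (startsWith(token, '"')) {
    n <- nchar(token)
    j <- 2L
    while (j <= n) {
      cj <- substr(token, j, j)
      if (cj == "\\") { j <- j + 2L; next }
      if (cj == '"') break
      j <- j + 1L
    }
    lex <- substr(token, 2L, j - 1L)
    dt <- ""
    if (substr(token, j + 1L, j + 2L) == "^^") {
      dt <- resolve_term(substr(token, j + 3L, n), prefixes)
    }
    return(list(object = unescape_literal(lex), type = "literal",
                datatype = dt))
  }
  list(object = resolve_term(token, prefixes), type = "iri", datatype = "")
}

#' Parse a Turtle or N-Triples document
#'
#' Reads the dialect written by [serialize_graph()]: one statement per line,
#' `@prefix` declarations, prefixed names or angle-bracketed IRIs, plain or
#' datatyped literals.
#'
#' @param text document text (single string or character vector of lines).
#' @param format `"turtle"` or `"ntriples"`.
#' @return a triple data frame.
#' @export
parse_graph <- function(text, format = c("turtle", "ntriples")) {
  format <- match.arg(format)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  prefixes <- character(0)
  out <- vector("list", length(lines))
  for (li in seq_along(lines)) {
    line <- lines[li]
    if (startsWith(line, "@prefix")) {
      if (format == "ntriples") {
        stop("RDF parse error: @prefix is not valid N-Triples", call. = FALSE)
      }
      m <- regmatches(line,
                      regexec("^@prefix\\s+([^:]*):\\s*<([^>]*)>\\s*\\.\\s*$",
                              line))[[1]]
      if (length(m) != 3) {
        stop("RDF parse error: malformed @prefix line: ", line, call. = FALSE)
      }
      prefixes[m[2]] <- m[3]
      next
    }
    tokens <- tokenize_statement(line)
    if (length(tokens) && tokens[length(tokens)] == ".") {
      tokens <- tokens[-length(tokens)]
    } else {
      stop("RDF parse error: statement not terminated by '.': ", line,
           call. = FALSE)
    }
    if (length(tokens) != 3) {
      stop("RDF parse error: expected subject predicate object: ", line,
           call. = FALSE)
    }
    if (format == "ntriples" &&
        !all(startsWith(tokens[1:2], "<"))) {
      stop("RDF parse error: N-Triples requires full IRIs: ", line,
           call. = FALSE)
    }
    obj <- parse_object_token(tokens[3], prefixes)
    out[[li]] <- data.frame(
      subject = resolve_term(tokens[1], prefixes),
      predicate = resolve_term(tokens[2], prefixes),
      object = obj$object, object_type = obj$type, datatype = obj$datatype,
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty_triples())
  as_triples(do.call(rbind, out))
}
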