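# Legacy "Association terms" support. dwc:associatedTaxa packs a list of
# (relationship, taxon) pairs into one string; the dominant dialect separates
# entries with "|" and splits each entry at the first ":" into a relationship
# qualifier and a taxon name, both optionally quoted, e.g.
#   "pollinator of":"Fuchsia magellanica"

strip_quotes <- function(x) {
  x <- trimws(x)
  has <- nchar(x) >= 2 &
    ((startsWith(x, '"') & endsWith(x, '"')) |
       (startsWith(x, "'") & endsWith(x, "'")))
  x[has] <- substr(x[has], 2, nchar(x[has]) - 1)
  trimws(x)
}

#' Parse a legacy associatedTaxa string
#'
#' Splits entries on `|`, then each entry at its first `:` into a
#' relationship qualifier and a taxon name, stripping surrounding quotes and
#' whitespace. An entry with no `:` yields an empty relationship and the
#' whole entry as taxon.
#'
#' @param raw the associatedTaxa value.
#' @return data frame with columns `relationship` and `taxon`, one row per
#'   entry (zero rows for empty input).
#' @export
#' @examples
#' parse_associated_taxa('"pollinator of":"Fuchsia magellanica"')
parse_associated_taxa <- function(raw) {
  empty <- data.frame(relationship = character(0), taxon = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(raw) || is.na(raw) || !nzchar(trimws(raw))) return(empty)
  entries <- trimws(strsplit(raw, "|", fixed = TRUE)[[1]])
  entries <- entries[nzchar(entries)]
  if (!length(entries)) return(empty)
  rel <- character(length(entries))
  tax <- character(length(entries))
  for (i in seq_along(entries)) {
    m <- regexpr(":", entries[i], fixed = TRUE)
    if (m > 0) {
      rel[i] <- strip_quotes(substr(entries[i], 1, m - 1))
      tax[i] <- strip_quotes(substr(entries[i], m + 1, nchar(entries[i])))
    } else {
      rel[i] <- ""
      tax[i] <- strip_quotes(entries[i])
    }
  }
  data.frame(relationship = rel, taxon = tax, stringsAsFactors = FALSE)
}

#' Format (relationship, taxon) pairs as an associatedTaxa string
#'
#' Companion formatter to [parse_associated_taxa()]: emits
#' `"relationship":"taxon"` entries joined by `" | "`. Round-trips through the
#' parser for values free of the delimiters.
#'
#' @param pairs data frame with columns `relationship` and `taxon`.
#' @return a single character string (`""` for zero rows).
#' @export
format_associated_taxa <- function(pairs) {
  if (!nrow(pairs)) return("")
  entries <- ifelse(
    nzchar(pairs$relationship),
    sprintf('"%s":"%s"', pairs$relationship, pairs$taxon),
    sprintf('"%s"', pairs$taxon)
  )
  paste(entries, collapse = " | ")
}
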