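# CSV helpers shared by the registry, the flat-table interface and the
# archive writer. Reading goes through utils::read.csv (RFC 4180 quoting);
# writing uses a minimal-quoting formatter so archives stay friendly to
# line-oriented tools.

read_csv_strict <- function(source, text = NULL) {
  df <- utils::read.csv(
    if (is.null(text)) source else textConnection(text),
    colClasses = "character", check.names = FALSE,
    na.strings = character(0), fileEncoding = if (is.null(text)) "UTF-8" else ""
  )
  names(df) <- trimws(names(df))
  df
}

csv_quote_field <- function(x) {
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs], fixed = TRUE), '"')
  x
}

#' Format a data frame as minimally quoted CSV text
#' @noRd
format_csv <- function(df, eol = "\n") {
  header <- paste(csv_quote_field(names(df)), collapse = ",")
  if (!nrow(df)) return(paste0(header, eol))
  cols <- lapply(df, function(col) csv_quote_field(as.character(col)))
  body <- do.call(paste, c(cols, sep = ","))
  paste0(paste(c(header, body), collapse = eol), eol)
}

write_csv_min <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(format_csv(df)), con)
  invisible(path)
}

# Flat four-table interface: events.csv, occurrences.csv, measurements.csv,
# relationships.csv in one directory, header tokens equal to the DwC/PPI term
# names used by the data model.

FLAT_FILES <- c(
  events = "events.csv", occurrences = "occurrences.csv",
  measurements = "measurements.csv", relationships = "relationships.csv"
)

#' Write an interaction dataset as four flat CSV tables
#'
#' @param dataset a `ppi_dataset`.
#' @param dir destination directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_flat_csv <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ppi_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (part in names(FLAT_FILES)) {
    write_csv_min(dataset[[part]], file.path(dir, FLAT_FILES[[part]]))
  }
  invisible(dir)
}

#' Read an interaction dataset from four flat CSV tables
#'
#' Missing table files are treated as empty tables.
#'
#' @param dir directory containing `events.csv`, `occurrences.csv`,
#'   `measurements.csv`, `relationships.csv`.
#' @return a `ppi_dataset`.
#' @export
read_flat_csv <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  parts <- lapply(FLAT_FILES, function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) read_csv_strict(p) else NULL
  })
  ppi_dataset(
    events = parts$events, occurrences = parts$occurrences,
    measurements = parts$measurements, relationships = parts$relationships
  )
}
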