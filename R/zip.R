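# Minimal deterministic ZIP writer for Darwin Core Archives. Entries are
# deflate-compressed via memCompress(type = "gzip") with the gzip framing
# stripped (the gzip trailer conveniently carries the CRC32 the ZIP headers
# need). Timestamps are fixed to the DOS epoch so identical datasets produce
# byte-identical archives. Reading archives goes through utils::unzip, an
# independent code path.

u16 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256))
}

u32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

DOS_EPOCH_DATE <- u16(0x21) # 1980-01-01
DOS_EPOCH_TIME <- u16(0)

crc32_table <- function() {
  if (is.null(.ppi_cache$crc_table)) {
    poly <- -306674912L # 0xEDB88320 as a signed 32-bit integer
    tab <- integer(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8) {
        c <- if (bitwAnd(c, 1L)) {
          bitwXor(poly, bitwShiftR(c, 1L))
        } else {
          bitwShiftR(c, 1L)
        }
      }
      tab[n + 1L] <- c
    }
    .ppi_cache$crc_table <- tab
  }
  .ppi_cache$crc_table
}

crc32 <- function(data) {
  tab <- crc32_table()
  crc <- -1L
  bytes <- as.integer(data)
  for (b in bytes) {
    crc <- bitwXor(tab[bitwAnd(bitwXor(crc, b), 255L) + 1L],
                   bitwShiftR(crc, 8L))
  }
  crc <- bitwXor(crc, -1L)
  writeBin(crc, raw(), size = 4L, endian = "little")
}

deflate_raw <- function(data) {
  gz <- memCompress(data, type = "gzip")
  deflated <- if (length(gz) >= 18 && gz[1] == as.raw(0x1f) &&
                  gz[2] == as.raw(0x8b)) {
    gz[11:(length(gz) - 8)]           # gzip framing
  } else if (length(gz) >= 6 && gz[1] == as.raw(0x78)) {
    gz[3:(length(gz) - 4)]            # zlib framing
  } else {
    stop("unexpected compression framing from memCompress", call. = FALSE)
  }
  list(deflated = deflated, crc32 = crc32(data))
}

#' Write a ZIP file from in-memory entries
#'
#' @param path destination file.
#' @param entries named list; names are entry paths inside the archive,
#'   values are raw vectors or character scalars (encoded as UTF-8).
#' @return `path`, invisibly.
#' @keywords internal
zip_write <- function(path, entries) {
  stopifnot(length(entries) > 0, !is.null(names(entries)))
  con <- file(path, "wb")
  on.exit(close(con))
  offset <- 0
  central <- raw(0)
  for (name in names(entries)) {
    data <- entries[[name]]
    if (is.character(data)) data <- charToRaw(enc2utf8(data))
    d <- deflate_raw(data)
    fname <- charToRaw(name)
    common <- c(
      u16(20),            # version needed
      u16(0),             # flags
      u16(8),             # method: deflate
      DOS_EPOCH_TIME, DOS_EPOCH_DATE,
      d$crc32,
      u32(length(d$deflated)),
      u32(length(data)),
      u16(length(fname)),
      u16(0)              # extra length
    )
    local <- c(u32(0x04034b50), common, fname)
    writeBin(local, con)
    writeBin(d$deflated, con)
    central <- c(
      central,
      u32(0x02014b50), u16(20), common,
      u16(0),             # comment length
      u16(0),             # disk number
      u16(0),             # internal attrs
      u32(0),             # external attrs
      u32(offset),
      fname
    )
    offset <- offset + length(local) + length(d$deflated)
  }
  writeBin(central, con)
  writeBin(c(
    u32(0x06054b50), u16(0), u16(0),
    u16(length(entries)), u16(length(entries)),
    u32(length(central)), u32(offset), u16(0)
  ), con)
  invisible(path)
}
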