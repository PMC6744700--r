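# FFindex-style packed database: one flat data blob holding NUL-terminated
# records plus a (name, offset, length) index sorted by name. The on-disk
# layout is the published flat-file convention: a binary data file and a
# text index with "name<TAB>offset<TAB>length" lines.

#' Pack records into an FFindex database
#'
#' @param records Named list; each element a raw vector or a single
#'   character string (stored as its UTF-8 bytes). Names must be unique.
#' @return An object of class `ffindex_db` with fields `data` (raw vector,
#'   each record NUL-terminated) and `index` (data.frame with `name`,
#'   `offset` (0-based), `length` in bytes excluding the NUL), sorted
#'   lexicographically by name (C locale).
#' @export
ffindex_pack <- function(records) {
  nm <- names(records)
  if (length(records) == 0L) nm <- character(0)
  if (length(records) > 0L && (is.null(nm) || any(!nzchar(nm)))) {
    stop("all records must be named")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate record name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  payload <- lapply(records, function(r) {
    if (is.character(r)) r <- charToRaw(r)
    if (!is.raw(r)) stop("records must be raw vectors or character strings")
    r
  })
  ord <- order(nm, method = "radix")
  payload <- payload[ord]
  nm <- nm[ord]
  lens <- vapply(payload, length, 0L)
  offsets <- if (length(lens)) cumsum(c(0L, head(lens + 1L, -1L))) else integer(0)
  data <- if (length(payload)) {
    unlist(lapply(payload, function(r) c(r, as.raw(0L))), use.names = FALSE)
  } else raw(0)
  structure(list(data = data,
                 index = data.frame(name = nm, offset = offsets,
                                    length = lens, stringsAsFactors = FALSE,
                                    row.names = NULL)),
            class = "ffindex_db")
}

#' Retrieve a record from an FFindex database
#'
#' @param db An `ffindex_db`.
#' @param name Record name.
#' @param as One of `"raw"` or `"character"`.
#' @return The stored bytes (exact), or their character decoding.
#' @export
ffindex_get <- function(db, name, as = c("raw", "character")) {
  as <- match.arg(as)
  i <- match(name, db$index$name)
  if (is.na(i)) stop("record not found in FFindex database: ", name)
  off <- db$index$offset[[i]]
  len <- db$index$length[[i]]
  r <- db$data[seq_len(len) + off]
  if (as == "character") rawToChar(r) else r
}

#' List record names of an FFindex database
#' @param db An `ffindex_db`.
#' @return Character vector in index (name-sorted) order.
#' @export
ffindex_names <- function(db) db$index$name

#' Write / read an FFindex database as a data + index file pair
#'
#' @param db An `ffindex_db`.
#' @param data_path,index_path Paths for the data blob and the text index.
#' @return `ffindex_write` returns `db` invisibly; `ffindex_read` returns
#'   an `ffindex_db`.
#' @export
ffindex_write <- function(db, data_path, index_path) {
  stopifnot(inherits(db, "ffindex_db"))
  writeBin(db$data, data_path)
  writeLines(sprintf("%s\t%d\t%d", db$index$name, db$index$offset,
                     db$index$length),
             index_path)
  invisible(db)
}

#' @rdname ffindex_write
#' @export
ffindex_read <- function(data_path, index_path) {
  data <- readBin(data_path, what = "raw", n = file.size(data_path))
  lines <- readLines(index_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  idx <- data.frame(
    name = vapply(parts, `[[`, "", 1L),
    offset = as.integer(vapply(parts, `[[`, "", 2L)),
    length = as.integer(vapply(parts, `[[`, "", 3L)),
    stringsAsFactors = FALSE)
  db <- structure(list(data = data, index = idx), class = "ffindex_db")
  .validate_ffindex(db)
  db
}

.validate_ffindex <- function(db) {
  idx <- db$index
  if (anyDuplicated(idx$name)) stop("duplicate names in FFindex index")
  if (nrow(idx) > 1L && any(diff(idx$offset) <= 0)) {
    stop("FFindex offsets must be strictly increasing")
  }
  if (nrow(idx) > 0L && any(idx$offset + idx$length > length(db$data))) {
    stop("FFindex record extends past end of data")
  }
  invisible(db)
}

#' @export
print.ffindex_db <- function(x, ...) {
  cat(sprintf("FFindex database: %d records, %d bytes\n",
              nrow(x$index), length(x$data)))
  invisible(x)
}
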