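# MSA container and A3M input/output.
#
# A3M convention: uppercase letters and '-' occupy match columns; lowercase
# letters are insertions relative to the match columns. Every row must
# yield the same number of match columns once lowercase letters are removed.

#' Construct a multiple sequence alignment (MSA) object
#'
#' @param names Character vector of sequence identifiers.
#' @param rows Character vector of aligned rows in A3M convention:
#'   uppercase residues and `-` in match columns, lowercase residues for
#'   insertions. `X`/`x` is permitted as unknown residue.
#' @return An object of class `msa` with fields `names`, `rows` and
#'   `length` (the number of match columns).
#' @export
msa <- function(names, rows) {
  if (length(rows) < 1L) stop("MSA must contain at least one row")
  if (length(names) != length(rows)) {
    stop("'names' and 'rows' must have equal length")
  }
  bad <- grepl("[^A-Za-z-]", rows)
  if (any(bad)) {
    stop("illegal character in MSA row(s): ", paste(names[bad], collapse = ", "))
  }
  letters_only <- gsub("-", "", rows)
  legal <- paste(c(aa_alphabet(), "X"), collapse = "")
  if (any(grepl(sprintf("[^%s%s]", legal, tolower(legal)), letters_only))) {
    stop("non-amino-acid residue character in MSA")
  }
  nmatch <- nchar(gsub("[a-z]", "", rows))
  if (length(unique(nmatch)) != 1L) {
    stop("inconsistent match-column counts across rows: ",
         paste(unique(nmatch), collapse = ", "))
  }
  structure(list(names = as.character(names), rows = as.character(rows),
                 length = nmatch[[1L]]),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("MSA: %d sequences, %d match columns\n",
              length(x$rows), x$length))
  show <- utils::head(seq_along(x$rows), 8L)
  for (i in show) {
    row <- x$rows[[i]]
    if (nchar(row) > 60L) row <- paste0(substr(row, 1L, 57L), "...")
    cat(sprintf("  %-12s %s\n", substr(x$names[[i]], 1L, 12L), row))
  }
  if (length(x$rows) > 8L) cat(sprintf("  ... %d more\n", length(x$rows) - 8L))
  invisible(x)
}

#' Number of sequences in an MSA
#' @param x An `msa` object.
#' @return Integer count of rows.
#' @export
n_sequences <- function(x) length(x$rows)

# Match-column residues as an N x L integer matrix (0 = gap, 1..20 = amino
# acid, 21 = X). Lowercase insertions are dropped.
msa_match_matrix <- function(m) {
  rows <- gsub("[a-z]", "", m$rows)
  out <- matrix(0L, nrow = length(rows), ncol = m$length)
  for (i in seq_along(rows)) {
    if (m$length > 0L) out[i, ] <- encode_residues(rows[[i]])
  }
  rownames(out) <- m$names
  out
}

#' Read an A3M/FASTA alignment
#'
#' Accepts plain aligned FASTA (all rows equal length) as the special case
#' of A3M with no insertions. `.` characters (null insertions emitted by
#' some aligners) are dropped on input.
#'
#' @param input Path to a file, or a character vector of lines, or a
#'   single string containing the full text.
#' @return An [msa()] object.
#' @export
read_a3m <- function(input) {
  lines <- .as_lines(input)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty A3M input")
  is_header <- startsWith(lines, ">")
  if (!is_header[[1L]]) stop("A3M input must start with a '>' header")
  grp <- cumsum(is_header)
  headers <- sub("^>", "", trimws(lines[is_header]))
  names <- vapply(strsplit(headers, "[ \t]"), `[[`, "", 1L)
  seqs <- vapply(split(lines[!is_header], grp[!is_header]),
                 function(x) paste(gsub("[ \t.]", "", x), collapse = ""),
                 "")
  if (length(seqs) != length(names) || any(!nzchar(seqs))) {
    stop("A3M record(s) without sequence lines")
  }
  msa(names, unname(seqs))
}

#' Write an MSA in A3M format
#'
#' @param m An [msa()] object.
#' @param path Optional output file; when `NULL` the text is returned.
#' @return The A3M text (invisibly when `path` is given).
#' @export
write_a3m <- function(m, path = NULL) {
  stopifnot(inherits(m, "msa"))
  text <- paste0(">", m$names, "\n", m$rows, "\n", collapse = "")
  if (is.null(path)) return(text)
  writeLines(sub("\n$", "", text), path)
  invisible(text)
}

.as_lines <- function(input) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    return(readLines(input, warn = FALSE))
  }
  unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
}
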