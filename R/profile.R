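# ProfileHMM container, validation, and the text file dialect.

#' Construct a profile HMM
#'
#' A profile HMM has one match state per retained alignment column. Match
#' states emit amino acids with column-specific probabilities; insert
#' states emit from the background distribution; delete states are silent.
#'
#' @param name Identifier.
#' @param match_emission L x 20 matrix of match-state emission
#'   probabilities, rows summing to 1, columns in [aa_alphabet()] order.
#' @param transition L x 7 matrix of transition probabilities in slot
#'   order `MM, MI, MD, IM, II, DM, DD`; each of the three groups
#'   (`MM+MI+MD`, `IM+II`, `DM+DD`) sums to 1 per row.
#' @param neff Per-column effective number of sequences (length L, >= 1).
#' @param background Background frequencies f_a (default [aa_background()]).
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `profile_hmm`.
#' @export
profile_hmm <- function(name, match_emission, transition, neff,
                        background = aa_background(), validate = TRUE) {
  match_emission <- as.matrix(match_emission)
  transition <- as.matrix(transition)
  h <- structure(
    list(name = as.character(name),
         L = nrow(match_emission),
         match_emission = unname(match_emission),
         transition = unname(transition),
         neff = as.numeric(neff),
         background = as.numeric(background)),
    class = "profile_hmm")
  if (validate) validate_profile_hmm(h)
  h
}

#' Validate profile HMM invariants
#'
#' @param h A `profile_hmm`.
#' @param tol Tolerance on probability-sum invariants.
#' @param maxres Maximum allowed number of match columns.
#' @return `h` invisibly; stops on violation.
#' @export
validate_profile_hmm <- function(h, tol = 1e-9, maxres = 15000L) {
  stopifnot(inherits(h, "profile_hmm"))
  if (h$L < 1L) stop("profile HMM must have at least one match column")
  if (h$L > maxres) stop("profile HMM exceeds maxres = ", maxres)
  if (!is.matrix(h$match_emission) || ncol(h$match_emission) != 20L ||
      nrow(h$match_emission) != h$L) {
    stop("match_emission must be an L x 20 matrix")
  }
  if (!is.matrix(h$transition) || ncol(h$transition) != 7L ||
      nrow(h$transition) != h$L) {
    stop("transition must be an L x 7 matrix")
  }
  if (any(h$match_emission < 0) || any(h$transition < 0)) {
    stop("negative probability in profile HMM")
  }
  if (any(abs(rowSums(h$match_emission) - 1) > tol)) {
    stop("match emission rows must sum to 1")
  }
  grp <- list(1:3, 4:5, 6:7)
  for (g in grp) {
    if (any(abs(rowSums(h$transition[, g, drop = FALSE]) - 1) > tol)) {
      stop("transition group ", paste(transition_names()[g], collapse = "+"),
           " must sum to 1 per column")
    }
  }
  if (length(h$neff) != h$L || any(h$neff < 1 - tol)) {
    stop("neff must have length L with all values >= 1")
  }
  if (length(h$background) != 20L || abs(sum(h$background) - 1) > tol ||
      any(h$background <= 0)) {
    stop("background must be 20 positive frequencies summing to 1")
  }
  invisible(h)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("Profile HMM '%s': %d match columns, mean Neff %.2f\n",
              x$name, x$L, mean(x$neff)))
  invisible(x)
}

# --- text dialect ----------------------------------------------------------
#
# Self-describing, line-oriented, lossless at a documented precision:
# probabilities are stored as round(-1000 * log2(p)) with sentinel 99999
# for p = 0, so the stored integers round-trip exactly and 2^(-v/1000)
# recovers the probability to ~0.07% relative precision. Neff values are
# stored as round(1000 * neff).

.PROFILE_MAGIC <- "HMMPAIR-PROFILE"
.PROFILE_VERSION <- "1"
.LOG0_SENTINEL <- 99999L

.prob_to_int <- function(p) {
  v <- ifelse(p <= 0, .LOG0_SENTINEL, as.integer(round(-1000 * log2(pmax(p, 1e-30))))) # nolint
  as.integer(pmin(v, .LOG0_SENTINEL))
}

.int_to_prob <- function(v) {
  ifelse(v >= .LOG0_SENTINEL, 0, 2^(-v / 1000))
}

#' Write a profile HMM to the package text dialect
#'
#' Probabilities are stored as integers `round(-1000 * log2(p))` (sentinel
#' `99999` for zero), so writing and re-reading is exact after the first
#' quantization.
#'
#' @param h A [profile_hmm()].
#' @param path Optional file path; when `NULL` the text is returned.
#' @return Profile text (invisibly when `path` is given).
#' @export
write_profile <- function(h, path = NULL) {
  validate_profile_hmm(h, tol = 5e-3)
  lines <- c(
    paste(.PROFILE_MAGIC, .PROFILE_VERSION),
    paste("NAME", h$name),
    paste("LENG", h$L),
    paste("ALPH", paste(aa_alphabet(), collapse = "")),
    paste("BACKGROUND", paste(.prob_to_int(h$background), collapse = " ")),
    paste("NEFF", paste(as.integer(round(1000 * h$neff)), collapse = " ")),
    "COLUMNS")
  em <- apply(h$match_emission, 1L, function(p) paste(.prob_to_int(p), collapse = " "))
  tr <- apply(h$transition, 1L, function(p) paste(.prob_to_int(p), collapse = " "))
  lines <- c(lines, paste0(seq_len(h$L), " E ", em), paste0(seq_len(h$L), " T ", tr), "END")
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(lines, path)
  invisible(text)
}

#' Read a profile HMM from the package text dialect
#'
#' @param input File path, character vector of lines, or full text.
#' @return A [profile_hmm()].
#' @export
read_profile <- function(input) {
  lines <- .as_lines(input)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 8L) stop("truncated profile file")
  head_tok <- strsplit(lines[[1L]], " ", fixed = TRUE)[[1L]]
  if (!identical(head_tok[[1L]], .PROFILE_MAGIC)) {
    stop("not a profile file (bad magic line)")
  }
  if (!identical(head_tok[[2L]], .PROFILE_VERSION)) {
    stop("unsupported profile file version: ", head_tok[[2L]])
  }
  if (!identical(lines[[length(lines)]], "END")) stop("truncated profile file")
  field <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, " "))]
    if (length(ln) != 1L) stop("missing or duplicate field: ", key)
    sub(paste0("^", key, " "), "", ln)
  }
  name <- field("NAME")
  L <- as.integer(field("LENG"))
  if (is.na(L) || L < 1L) stop("profile length must be >= 1")
  if (!identical(field("ALPH"), paste(aa_alphabet(), collapse = ""))) {
    stop("unsupported alphabet order in profile file")
  }
  ints <- function(s) as.integer(strsplit(trimws(s), "[ \t]+")[[1L]])
  background <- .int_to_prob(ints(field("BACKGROUND")))
  neff <- ints(field("NEFF")) / 1000
  col_lines <- lines[grepl("^[0-9]+ [ET] ", lines)]
  if (length(col_lines) != 2L * L) stop("truncated profile file: column lines missing")
  parse_block <- function(tag, ncol) {
    blk <- col_lines[grepl(paste0("^[0-9]+ ", tag, " "), col_lines)]
    if (length(blk) != L) stop("truncated profile file: ", tag, " block")
    idx <- as.integer(sub(" .*", "", blk))
    vals <- t(vapply(sub(paste0("^[0-9]+ ", tag, " "), "", blk), ints,
                     integer(ncol), USE.NAMES = FALSE))
    vals[order(idx), , drop = FALSE]
  }
  em <- .int_to_prob(parse_block("E", 20L))
  tr <- .int_to_prob(parse_block("T", 7L))
  dim(em) <- c(L, 20L)
  dim(tr) <- c(L, 7L)
  profile_hmm(name, em, tr, neff, background, validate = FALSE)
}
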