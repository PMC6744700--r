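# Amino-acid alphabet, background frequencies and substitution-matrix
# pseudocount machinery shared by all modules.

#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard amino acids in the fixed column order
#' `ARNDCQEGHILKMFPSTWYV`. All emission vectors, profile files and
#' column-state archetypes use this order.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# Robinson & Robinson (1991) amino-acid frequencies, reordered to the
# package alphabet and normalized to sum exactly 1.
.aa_background_raw <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

#' Background amino-acid frequencies
#'
#' Standard background frequencies f_a (Robinson-Robinson counts),
#' normalized to sum to 1, in [aa_alphabet()] order. Used as the null
#' model in column similarity scores, as the insert-state emission
#' distribution, and in pseudocount construction.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aa_background <- function() {
  f <- .aa_background_raw
  f / sum(f)
}

# Transition slot order of the 7-column transition matrix of a ProfileHMM.
transition_names <- function() {
  c("MM", "MI", "MD", "IM", "II", "DM", "DD")
}

# Pair states and their 3-bit backtrace codes. The code order doubles as
# the tie-breaking priority in the Viterbi maximization (STOP first).
pair_state_codes <- function() {
  c(STOP = 0L, MM = 1L, IM = 2L, MI = 3L, GD = 4L, DG = 5L)
}

.pkg_cache <- new.env(parent = emptyenv())

#' Substitution-matrix conditional probabilities for pseudocounts
#'
#' Derives the conditional probability matrix g(a | b) from the BLOSUM62
#' score matrix via the standard inversion of the log-odds construction:
#' the joint probability is taken proportional to f_a f_b 2^(S_ab / 2)
#' (BLOSUM62 scores are in half-bits), then normalized per conditioning
#' residue. Row a, column b holds g(a | b).
#'
#' @return 20 x 20 matrix with columns summing to 1.
#' @export
blosum62_conditional <- function() {
  if (!is.null(.pkg_cache$b62cond)) return(.pkg_cache$b62cond)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aa <- aa_alphabet()
  s <- e$BLOSUM62[aa, aa]
  f <- aa_background()
  joint <- outer(f, f) * 2^(s / 2)
  g <- sweep(joint, 2, colSums(joint), "/")
  dimnames(g) <- list(aa, aa)
  .pkg_cache$b62cond <- g
  g
}

# Map residue characters to integer codes 1..20, 21 for 'X' (unknown),
# 0 for gap '-'. Case-insensitive. Unknown characters give NA.
encode_residues <- function(chars) {
  lut <- .pkg_cache$residue_lut
  if (is.null(lut)) {
    lut <- rep(NA_integer_, 128)
    aa <- aa_alphabet()
    lut[utf8ToInt(paste(aa, collapse = "")) + 1L] <- seq_len(20L)
    lut[utf8ToInt(paste(tolower(aa), collapse = "")) + 1L] <- seq_len(20L)
    lut[utf8ToInt("X") + 1L] <- 21L
    lut[utf8ToInt("x") + 1L] <- 21L
    lut[utf8ToInt("-") + 1L] <- 0L
    .pkg_cache$residue_lut <- lut
  }
  lut[utf8ToInt(chars) + 1L]
}
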