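# From MSA to profile HMM: match-column assignment, redundancy filtering,
# position-specific sequence weighting, and emission/transition estimation
# with substitution-matrix pseudocounts.

#' Assign match columns by gap fraction
#'
#' A column of the alignment becomes a match column when its (unweighted)
#' gap fraction is below `gap_fraction_threshold`; all other columns are
#' modeled as insertions.
#'
#' @param m An [msa()] object; the rule is applied to its current match
#'   columns (for aligned FASTA input, all columns).
#' @param gap_fraction_threshold Columns with a gap fraction below this
#'   value become match columns (default 0.5).
#' @return Logical vector over the columns, `TRUE` = match.
#' @export
assign_match_columns <- function(m, gap_fraction_threshold = 0.5) {
  X <- msa_match_matrix(m)
  colMeans(X == 0L) < gap_fraction_threshold
}

#' Demote alignment columns to insertions
#'
#' Applies a match-column mask: residues in demoted columns become
#' lowercase insertions, gaps in demoted columns are removed.
#'
#' @param m An [msa()] object.
#' @param mask Logical vector over the current match columns.
#' @return A new [msa()] whose match columns are those with `mask = TRUE`.
#' @export
remaster_msa <- function(m, mask) {
  stopifnot(length(mask) == m$length)
  rows <- vapply(m$rows, function(row) {
    ch <- strsplit(row, "", fixed = TRUE)[[1L]]
    is_match <- !grepl("[a-z]", ch)
    pos <- cumsum(is_match)
    keep <- rep(TRUE, length(ch))
    for (k in which(is_match)) {
      if (!mask[[pos[[k]]]]) {
        if (ch[[k]] == "-") keep[[k]] <- FALSE else ch[[k]] <- tolower(ch[[k]])
      }
    }
    paste(ch[keep], collapse = "")
  }, "", USE.NAMES = FALSE)
  msa(m$names, rows)
}

#' Pairwise sequence identity over match columns
#'
#' Fraction of positions carrying identical non-gap residues, divided by
#' the smaller number of non-gap residues of the two sequences (symmetric,
#' robust to fragments). Returns 0 when either sequence is all-gap.
#'
#' @param x,y Equal-length aligned residue strings over match columns
#'   (uppercase and `-`).
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(x, y) {
  xi <- encode_residues(x)
  yi <- encode_residues(y)
  if (length(xi) != length(yi)) stop("sequences must have equal length")
  .pairwise_identity_codes(xi, yi)
}

# Vectorized (chunk-free) production kernel on residue codes; the naive
# per-position loop used as test oracle lives in the test helpers.
.pairwise_identity_codes <- function(xi, yi) {
  nid <- sum(xi == yi & xi > 0L)
  denom <- min(sum(xi > 0L), sum(yi > 0L))
  if (denom == 0L) return(0)
  nid / denom
}

#' Greedy MSA redundancy filter
#'
#' Removes sequences with identity above `seqid_max` to a retained
#' sequence. The first sequence (the query) is always kept; remaining
#' rows are scanned in input order and discarded when their identity to
#' any already-kept sequence exceeds the cutoff. Identity is computed on
#' match columns only.
#'
#' @param m An [msa()] object.
#' @param seqid_max Maximum allowed pairwise identity (default 0.9).
#' @return The filtered [msa()]; row order preserved.
#' @export
filter_redundancy <- function(m, seqid_max = 0.9) {
  X <- msa_match_matrix(m)
  N <- nrow(X)
  keep <- .filter_redundancy_codes(X, seqid_max)
  if (all(keep)) return(m)
  msa(m$names[keep], m$rows[keep])
}

.filter_redundancy_codes <- function(X, seqid_max) {
  N <- nrow(X)
  keep <- logical(N)
  keep[[1L]] <- TRUE
  if (N == 1L) return(keep)
  kept_idx <- 1L
  nongap <- rowSums(X > 0L)
  for (i in 2:N) {
    K <- X[kept_idx, , drop = FALSE]
    nid <- rowSums(K == matrix(X[i, ], nrow = length(kept_idx),
                               ncol = ncol(X), byrow = TRUE) &
                     K > 0L)
    denom <- pmin(nongap[kept_idx], nongap[[i]])
    ident <- ifelse(denom == 0L, 0, nid / denom)
    if (all(ident <= seqid_max)) {
      keep[[i]] <- TRUE
      kept_idx <- c(kept_idx, i)
    }
  }
  keep
}

# Position-based (Henikoff-style) sequence weights for an integer residue
# matrix (0 = gap). Each column contributes 1/(r * count) to each non-gap
# row, where r is the number of distinct residue types in the column and
# count the multiplicity of the row's residue. Normalized to sum 1.
henikoff_weights <- function(X) {
  N <- nrow(X)
  w <- numeric(N)
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    nz <- x > 0L
    if (!any(nz)) next
    cnt <- tabulate(x[nz], 21L)
    r <- sum(cnt > 0L)
    w[nz] <- w[nz] + 1 / (r * cnt[x[nz]])
  }
  if (sum(w) <= 0) rep(1 / N, N) else w / sum(w)
}

#' Column-specific sequence weights
#'
#' For each match column i, position-based weights are computed on the
#' subalignment of sequences that have no gap in column i, and normalized
#' to sum 1 over those sequences (0 for the others). Columns where every
#' sequence has a gap fall back to uniform weights over all sequences and
#' are flagged in the `"uniform_fallback"` attribute.
#'
#' @param m An [msa()] object.
#' @param match_mask Optional logical mask restricting which of the MSA's
#'   match columns participate (default: all).
#' @return N x L weight matrix with columns summing to 1; attribute
#'   `uniform_fallback` is a logical vector over columns.
#' @export
column_sequence_weights <- function(m, match_mask = NULL) {
  X <- msa_match_matrix(m)
  if (!is.null(match_mask)) X <- X[, match_mask, drop = FALSE]
  L <- ncol(X)
  if (L < 1L) stop("MSA has no match columns")
  N <- nrow(X)
  W <- matrix(0, N, L)
  fallback <- logical(L)
  for (i in seq_len(L)) {
    members <- which(X[, i] > 0L)
    if (length(members) == 0L) {
      W[, i] <- 1 / N
      fallback[[i]] <- TRUE
    } else if (length(members) == 1L) {
      W[members, i] <- 1
    } else {
      W[members, i] <- henikoff_weights(X[members, , drop = FALSE])
    }
  }
  attr(W, "uniform_fallback") <- fallback
  W
}

#' Build a profile HMM from an MSA
#'
#' Emission probabilities are column-weighted residue frequencies mixed
#' with substitution-matrix pseudocounts using the diversity-dependent
#' admixture `tau_i = min(1, pca / (1 + neff_i / pcb))`. Transition
#' probabilities are globally-weighted observed M/I/D transition counts
#' plus fixed additive pseudocounts, normalized per group.
#'
#' @param m An [msa()] object (typically already redundancy-filtered).
#' @param name Profile name (default: first sequence name).
#' @param pca,pcb Emission pseudocount admixture parameters
#'   (defaults 1.0 and 1.5); `pca = 0` disables emission pseudocounts.
#' @param trans_pc Scale on the additive transition pseudocounts
#'   (M: 0.6/0.2/0.2, I: 0.5/0.5, D: 0.5/0.5); 0 disables them.
#' @param background Background frequencies.
#' @param maxseqs Maximum number of sequences used (the first `maxseqs`
#'   rows are kept; default 65535).
#' @param maxres Maximum profile length (default 15000).
#' @return A [profile_hmm()].
#' @export
build_profile_hmm <- function(m, name = m$names[[1L]], pca = 1.0, pcb = 1.5,
                              trans_pc = 1.0, background = aa_background(),
                              maxseqs = 65535L, maxres = 15000L) {
  if (m$length < 1L) stop("MSA has zero match columns")
  if (m$length > maxres) stop("MSA exceeds maxres = ", maxres)
  if (n_sequences(m) > maxseqs) {
    warning("MSA truncated to the first ", maxseqs, " sequences")
    m <- msa(m$names[seq_len(maxseqs)], m$rows[seq_len(maxseqs)])
  }
  X <- msa_match_matrix(m)
  L <- ncol(X)
  W <- column_sequence_weights(m)

  # weighted observed residue frequencies; 'X' spreads uniformly
  f_obs <- matrix(0, L, 20L)
  for (i in seq_len(L)) {
    x <- X[, i]
    wi <- W[, i]
    sel <- x >= 1L & x <= 20L
    if (any(sel)) {
      f_obs[i, ] <- vapply(1:20, function(a) sum(wi[sel][x[sel] == a]), 0)
    }
    wx <- sum(wi[x == 21L])
    if (wx > 0) f_obs[i, ] <- f_obs[i, ] + wx / 20
    s <- sum(f_obs[i, ])
    if (s <= 0) f_obs[i, ] <- background else f_obs[i, ] <- f_obs[i, ] / s
  }

  # per-column diversity: exponential of the Shannon entropy (nats)
  p <- pmax(f_obs, 0)
  ent <- -rowSums(ifelse(p > 0, p * log(p), 0))
  neff <- pmax(1, exp(ent))

  # substitution-matrix pseudocounts with diversity-dependent admixture
  if (pca > 0) {
    g <- f_obs %*% t(blosum62_conditional())  # row i: sum_b g(a|b) f_obs(b)
    tau <- pmin(1, pca / (1 + neff / pcb))
    em <- (1 - tau) * f_obs + tau * g
  } else {
    em <- f_obs
  }
  em <- em / rowSums(em)

  tr <- .transition_counts(m, X, henikoff_weights(X))
  tr <- .normalize_transitions(tr, trans_pc)

  profile_hmm(name, em, tr, neff, background)
}

# Weighted M/I/D transition counts per column (L x 7). Row weights are
# global position-based weights. Insertions following a deleted column
# are ignored (the model has no D->I transition).
.transition_counts <- function(m, X, gw) {
  L <- ncol(X)
  counts <- matrix(0, L, 7L)
  colnames(counts) <- transition_names()
  for (n in seq_len(nrow(X))) {
    w <- gw[[n]]
    ch <- strsplit(m$rows[[n]], "", fixed = TRUE)[[1L]]
    is_ins <- grepl("[a-z]", ch)
    pos <- cumsum(!is_ins)           # match-column index of each character
    ins_after <- tabulate(pos[is_ins], L)
    state <- ifelse(X[n, ] == 0L, "D", "M")
    if (L < 2L) next
    for (i in seq_len(L - 1L)) {
      from <- state[[i]]
      to <- state[[i + 1L]]
      ni <- ins_after[[i]]
      if (ni > 0L && from == "M") {
        counts[i, "MI"] <- counts[i, "MI"] + w
        if (ni > 1L) counts[i, "II"] <- counts[i, "II"] + w * (ni - 1L)
        counts[i, "IM"] <- counts[i, "IM"] + w
      } else {
        slot <- paste0(from, to)
        counts[i, slot] <- counts[i, slot] + w
      }
    }
  }
  counts
}

.normalize_transitions <- function(counts, trans_pc) {
  L <- nrow(counts)
  pc <- trans_pc * c(MM = 0.6, MI = 0.2, MD = 0.2, IM = 0.5, II = 0.5,
                     DM = 0.5, DD = 0.5)
  tr <- sweep(counts, 2L, pc, "+")
  groups <- list(1:3, 4:5, 6:7)
  # groups with no observations and no pseudocounts exit to M
  defaults <- list(c(1, 0, 0), c(1, 0), c(1, 0))
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    s <- rowSums(tr[, g, drop = FALSE])
    zero <- s <= 0
    if (any(zero)) {
      tr[zero, g] <- matrix(defaults[[k]], sum(zero), length(g), byrow = TRUE)
      s[zero] <- 1
    }
    tr[, g] <- tr[, g, drop = FALSE] / s
  }
  # the final column has no outgoing transitions; store the exit convention
  tr[L, ] <- c(1, 0, 0, 1, 0, 1, 0)
  tr
}
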