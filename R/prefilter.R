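# Column-state alphabet and two-stage prefilter: target profiles are
# discretized into sequences over K archetypical profile columns; the
# prefilter aligns the query profile against those sequences, first
# ungapped (best diagonal segment) then gapped (affine Smith-Waterman),
# keeping only the top-scoring targets for the full Viterbi stage.

#' Build a column-state alphabet from profile columns
#'
#' K archetypical profile columns obtained by k-means clustering of the
#' pooled emission rows under the Euclidean metric on square-root
#' transformed probabilities (an approximation of the Hellinger distance
#' between distributions). Deterministic given the seed.
#'
#' @param profiles List of [profile_hmm()] objects supplying columns.
#' @param K Alphabet size (default 219).
#' @param seed Integer seed for the k-means initialization.
#' @param iter_max k-means iteration cap.
#' @return Object of class `column_alphabet`: list with `emission`
#'   (K x 20 archetype rows, each summing to 1) and `K`.
#' @export
build_column_alphabet <- function(profiles, K = 219L, seed = 1L,
                                  iter_max = 50L) {
  stopifnot(K >= 2L)
  cols <- do.call(rbind, lapply(profiles, function(h) h$match_emission))
  X <- sqrt(cols)
  uX <- unique(round(X, 12L))
  if (nrow(uX) < K) {
    stop("K = ", K, " exceeds the number of distinct profile columns (",
         nrow(uX), ")")
  }
  centers <- if (nrow(uX) == K) {
    uX
  } else {
    with_seed(derive_seed(seed, 7L), {
      init <- uX[sample.int(nrow(uX), K), , drop = FALSE]
      suppressWarnings(kmeans(X, centers = init, iter.max = iter_max))$centers
    })
  }
  em <- centers^2
  em <- em / rowSums(em)
  structure(list(emission = unname(as.matrix(em)), K = K),
            class = "column_alphabet")
}

#' Discretize a profile into a column-state sequence
#'
#' Each match column is assigned its nearest archetype (Euclidean
#' distance on square-root probabilities). Letters are returned as raw
#' bytes with values 1..K.
#'
#' @param h A [profile_hmm()].
#' @param alphabet A `column_alphabet`.
#' @return Raw vector of length `h$L`.
#' @export
discretize_profile <- function(h, alphabet) {
  X <- sqrt(h$match_emission)
  C <- sqrt(alphabet$emission)
  # argmin_k ||x - c_k||^2 = argmax_k (x . c_k - ||c_k||^2 / 2)
  scores <- X %*% t(C) - matrix(rowSums(C^2) / 2, nrow(X), nrow(C),
                                byrow = TRUE)
  as.raw(max.col(scores, ties.method = "first"))
}

# Query-vs-archetype score table: row i holds the column similarity score
# of query column i against each of the K archetypes.
.query_alphabet_scores <- function(q, alphabet) {
  qf <- sweep(q$match_emission, 2L, q$background, "/")
  s <- qf %*% t(alphabet$emission)
  out <- matrix(.LOG0, nrow(s), ncol(s))
  pos <- s > 0
  out[pos] <- log2(s[pos])
  out
}

#' Two-stage prefilter
#'
#' Stage 1 scores the query profile against each target's column-state
#' sequence with the best ungapped diagonal segment; stage 2 rescored
#' survivors with gapped (affine) Smith-Waterman on the same per-cell
#' scores. Each stage keeps the top `keep_fraction` of targets, with an
#' absolute floor of `min_prefilter_hits`.
#'
#' @param q Query [profile_hmm()].
#' @param cs_seqs Named list of raw column-state sequences (from
#'   [discretize_profile()]).
#' @param alphabet The `column_alphabet` the sequences were built with.
#' @param keep_fraction Fraction of targets retained per stage
#'   (default 0.05).
#' @param min_prefilter_hits Absolute floor on survivors per stage
#'   (default 100).
#' @param gap_open,gap_extend Stage-2 gap costs in bits (defaults 5, 1).
#' @return Data frame `name`, `ungapped`, `gapped` (NA for stage-1
#'   casualties is not reported: only survivors of both stages are
#'   returned), sorted by decreasing gapped score.
#' @export
prefilter <- function(q, cs_seqs, alphabet, keep_fraction = 0.05,
                      min_prefilter_hits = 100L, gap_open = 5,
                      gap_extend = 1) {
  if (length(cs_seqs) == 0L) stop("empty database")
  W <- .query_alphabet_scores(q, alphabet)
  s1 <- vapply(cs_seqs, function(s) {
    .diag_ungapped_cpp(W[, as.integer(s), drop = FALSE])
  }, 0)
  n_keep <- max(min(min_prefilter_hits, length(s1)),
                ceiling(keep_fraction * length(s1)))
  surv1 <- names(s1)[order(-s1, names(s1))][seq_len(n_keep)]
  s2 <- vapply(cs_seqs[surv1], function(s) {
    .sw_affine_cpp(W[, as.integer(s), drop = FALSE], gap_open, gap_extend)
  }, 0)
  n_keep2 <- max(min(min_prefilter_hits, length(s2)),
                 ceiling(keep_fraction * length(s1)))
  n_keep2 <- min(n_keep2, length(s2))
  surv2 <- names(s2)[order(-s2, names(s2))][seq_len(n_keep2)]
  data.frame(name = surv2, ungapped = unname(s1[surv2]),
             gapped = unname(s2[surv2]), stringsAsFactors = FALSE)
}
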