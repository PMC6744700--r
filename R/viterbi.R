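# Five-pair-state local Viterbi alignment of profile HMMs: scalar path,
# batched-over-targets path, compressed backtrace, suboptimal alignments.

.LOG0 <- -100000  # log2(0) sentinel in bits; padded lanes can never win

#' Profile column similarity score
#'
#' The co-emission log-odds score of two profile columns in bits:
#' `log2 sum_a q(a) t(a) / f(a)`. Zero when both columns equal the
#' background; `-Inf` when the sum vanishes.
#'
#' @param q_col,t_col Emission probability vectors (length 20).
#' @param background Background frequencies f_a.
#' @return Score in bits.
#' @export
column_score <- function(q_col, t_col, background = aa_background()) {
  s <- sum(q_col * t_col / background)
  if (s <= 0) return(-Inf)
  log2(s)
}

# Precomputed DP inputs for one HMM: emission-over-background matrix for
# the query role, raw emissions for the target role, log2 transitions.
.hmm_arrays <- function(h) {
  tr <- h$transition
  ltr <- matrix(.LOG0, nrow(tr), ncol(tr))
  pos <- tr > 0
  ltr[pos] <- log2(tr[pos])
  list(em = h$match_emission,
       emf = sweep(h$match_emission, 2L, h$background, "/"),
       ltr = ltr)
}

.as_pair_alignment <- function(path_df, score, q_name, t_name) {
  structure(list(path = path_df, score = score,
                 query = q_name, target = t_name,
                 start_cell = if (nrow(path_df)) unlist(path_df[1L, 1:2]) else c(i = 0L, j = 0L),
                 end_cell = if (nrow(path_df)) unlist(path_df[nrow(path_df), 1:2]) else c(i = 0L, j = 0L)),
            class = "pair_alignment")
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(sprintf("Pair alignment %s vs %s: score %.3f bits, %d columns (%d aligned pairs)\n",
              x$query, x$target, x$score, nrow(x$path),
              sum(x$path$state == "MM")))
  if (nrow(x$path)) {
    cat(sprintf("  query %d-%d, target %d-%d\n", x$path$i[[1L]],
                x$path$i[[nrow(x$path)]], x$path$j[[1L]],
                x$path$j[[nrow(x$path)]]))
  }
  invisible(x)
}

#' Scalar Viterbi alignment of two profile HMMs
#'
#' Local five-pair-state Viterbi (pair states MM, MI, IM, DG, GD; II and
#' DD excluded) with a zero restart option at every cell, computed with
#' single-row score buffers and a one-byte-per-cell backtrace matrix.
#'
#' @param q,t Query and target [profile_hmm()] objects.
#' @param cell_off Optional raw matrix `(L_q+1) x (L_t+1)`; cells with the
#'   most significant bit set are forbidden (used for suboptimal
#'   alignments).
#' @param ss Optional `L_q x L_t` additive per-cell score matrix (hook for
#'   secondary-structure or other extra terms; default contributes 0).
#' @param corrected Use the transition-factor set consistent with the
#'   pair-state semantics (default `TRUE`); `FALSE` selects the literal
#'   printed variant of the MI/DG entry factors, for debugging.
#' @return List with `score` (bits, >= 0), `bt` (raw backtrace matrix) and
#'   `end_cell` (the best-scoring MM cell, `c(0, 0)` for the empty
#'   alignment).
#' @export
viterbi_scalar <- function(q, t, cell_off = NULL, ss = NULL, corrected = TRUE) {
  qa <- .hmm_arrays(q)
  ta <- .hmm_arrays(t)
  r <- .viterbi_scalar_cpp(qa$emf, qa$ltr, ta$em, ta$ltr, cell_off, ss,
                           corrected)
  list(score = max(0, r$score), bt = r$bt,
       end_cell = c(i = r$i_best, j = r$j_best))
}

#' Batched Viterbi alignment of one query against many targets
#'
#' Production path mirroring the lane-parallel formulation: targets are
#' grouped into batches of `batch_width` lanes, sorted by decreasing
#' length within each batch, padded with zero emission probabilities up to
#' the longest profile in the batch, and processed cell-by-cell with
#' branch-free compare-select maximization over lanes. Results are
#' returned in the input order and are identical to [viterbi_scalar()]
#' per target.
#'
#' @param q Query [profile_hmm()].
#' @param targets List of target [profile_hmm()] objects.
#' @param batch_width Number of lanes per batch (default 8).
#' @param cell_off Optional list (parallel to `targets`) of raw cell-off
#'   matrices, or `NULL`.
#' @param corrected See [viterbi_scalar()].
#' @return List (input order) of per-target results as in
#'   [viterbi_scalar()].
#' @export
viterbi_batch <- function(q, targets, batch_width = 8L, cell_off = NULL,
                          corrected = TRUE) {
  if (length(targets) == 0L) stop("empty target list")
  stopifnot(batch_width >= 1L)
  qa <- .hmm_arrays(q)
  Lq <- q$L
  lens_all <- vapply(targets, function(h) h$L, 0L)
  ord <- order(lens_all, decreasing = TRUE)
  out <- vector("list", length(targets))
  for (start in seq(1L, length(ord), by = batch_width)) {
    idx <- ord[start:min(start + batch_width - 1L, length(ord))]
    B <- length(idx)
    lens <- lens_all[idx]
    Ltmax <- max(lens)
    tem_b <- array(0, c(B, 20L, Ltmax))
    ttr_b <- array(.LOG0, c(B, 7L, Ltmax))
    for (l in seq_len(B)) {
      ta <- .hmm_arrays(targets[[idx[[l]]]])
      tem_b[l, , seq_len(lens[[l]])] <- t(ta$em)
      ttr_b[l, , seq_len(lens[[l]])] <- t(ta$ltr)
    }
    co <- NULL
    if (!is.null(cell_off)) {
      co <- lapply(idx, function(k) {
        m <- cell_off[[k]]
        if (is.null(m)) {
          m <- matrix(as.raw(0L), Lq + 1L, lens_all[[k]] + 1L)
        }
        m
      })
    }
    res <- .viterbi_batch_cpp(qa$emf, qa$ltr, as.numeric(tem_b),
                              as.numeric(ttr_b), B, Ltmax,
                              as.integer(lens), co, corrected)
    for (l in seq_len(B)) {
      r <- res[[l]]
      out[[idx[[l]]]] <- list(
        score = max(0, r$score),
        bt = r$bt[, seq_len(lens[[l]] + 1L), drop = FALSE],
        end_cell = c(i = r$i_best, j = r$j_best))
    }
  }
  out
}

#' Encode / decode one backtrace byte
#'
#' Bits 0-2 hold the 3-bit predecessor code of the MM state (one of
#' `STOP, MM, IM, MI, GD, DG`); bits 3-6 hold one flag each for the GD,
#' IM, DG and MI states (1 = predecessor is the same state, 0 = MM); the
#' most significant bit is the cell-off flag.
#'
#' @param mm_pred Predecessor of MM: one of `"STOP"`, `"MM"`, `"IM"`,
#'   `"MI"`, `"GD"`, `"DG"`.
#' @param gd_same,im_same,dg_same,mi_same Same-state flags (0/1 or
#'   logical).
#' @param cell_off Cell-off flag (0/1 or logical).
#' @return `encode_backtrace_byte`: integer in 0..255.
#' @export
encode_backtrace_byte <- function(mm_pred, gd_same = 0L, im_same = 0L,
                                  dg_same = 0L, mi_same = 0L, cell_off = 0L) {
  codes <- pair_state_codes()
  if (!mm_pred %in% names(codes)) stop("invalid MM predecessor: ", mm_pred)
  as.integer(codes[[mm_pred]]) +
    bitwShiftL(as.integer(as.logical(gd_same)), 3L) +
    bitwShiftL(as.integer(as.logical(im_same)), 4L) +
    bitwShiftL(as.integer(as.logical(dg_same)), 5L) +
    bitwShiftL(as.integer(as.logical(mi_same)), 6L) +
    bitwShiftL(as.integer(as.logical(cell_off)), 7L)
}

#' @rdname encode_backtrace_byte
#' @param byte Integer 0..255 or a raw value.
#' @return `decode_backtrace_byte`: list with fields `mm_pred`, `gd_same`,
#'   `im_same`, `dg_same`, `mi_same`, `cell_off`.
#' @export
decode_backtrace_byte <- function(byte) {
  b <- as.integer(byte)
  code <- bitwAnd(b, 7L)
  codes <- pair_state_codes()
  if (!code %in% codes) stop("invalid 3-bit predecessor code: ", code)
  list(mm_pred = names(codes)[match(code, codes)],
       gd_same = bitwAnd(bitwShiftR(b, 3L), 1L),
       im_same = bitwAnd(bitwShiftR(b, 4L), 1L),
       dg_same = bitwAnd(bitwShiftR(b, 5L), 1L),
       mi_same = bitwAnd(bitwShiftR(b, 6L), 1L),
       cell_off = bitwAnd(bitwShiftR(b, 7L), 1L))
}

#' Reconstruct an alignment path from a backtrace matrix
#'
#' Walks the compressed backtrace from the best-scoring MM end cell to
#' the cell whose MM predecessor is STOP. Pair states advance query
#' and/or target coordinates: MM both, MI/DG query only, IM/GD target
#' only.
#'
#' @param bt Raw backtrace matrix from [viterbi_scalar()] /
#'   [viterbi_batch()].
#' @param end_cell `c(i, j)` of the final MM cell; `c(0, 0)` yields the
#'   empty alignment.
#' @param score Optional score to attach to the result.
#' @param q_name,t_name Optional identifiers for the report.
#' @return A `pair_alignment` with a `path` data frame (`i`, `j`,
#'   `state`).
#' @export
traceback_alignment <- function(bt, end_cell, score = NA_real_,
                                q_name = "query", t_name = "target") {
  i <- as.integer(end_cell[[1L]])
  j <- as.integer(end_cell[[2L]])
  empty <- data.frame(i = integer(0), j = integer(0),
                      state = character(0), stringsAsFactors = FALSE)
  if (i == 0L && j == 0L) {
    return(.as_pair_alignment(empty, if (is.na(score)) 0 else score,
                              q_name, t_name))
  }
  max_steps <- nrow(bt) + ncol(bt) + 2L
  codes <- pair_state_codes()
  state <- "MM"
  ii <- integer(0); jj <- integer(0); ss <- character(0)
  for (step in seq_len(max_steps)) {
    if (i < 1L || j < 1L) stop("malformed backtrace matrix: ran off the grid")
    ii <- c(i, ii); jj <- c(j, jj); ss <- c(state, ss)
    b <- as.integer(bt[i + 1L, j + 1L])
    if (state == "MM") {
      pred <- names(codes)[match(bitwAnd(b, 7L), codes)]
      if (is.na(pred)) stop("invalid predecessor code in backtrace")
      if (pred == "STOP") {
        return(.as_pair_alignment(
          data.frame(i = ii, j = jj, state = ss, stringsAsFactors = FALSE),
          score, q_name, t_name))
      }
      i <- i - 1L; j <- j - 1L; state <- pred
    } else if (state == "MI") {
      same <- bitwAnd(bitwShiftR(b, 6L), 1L) == 1L
      i <- i - 1L; state <- if (same) "MI" else "MM"
    } else if (state == "DG") {
      same <- bitwAnd(bitwShiftR(b, 5L), 1L) == 1L
      i <- i - 1L; state <- if (same) "DG" else "MM"
    } else if (state == "IM") {
      same <- bitwAnd(bitwShiftR(b, 4L), 1L) == 1L
      j <- j - 1L; state <- if (same) "IM" else "MM"
    } else if (state == "GD") {
      same <- bitwAnd(bitwShiftR(b, 3L), 1L) == 1L
      j <- j - 1L; state <- if (same) "GD" else "MM"
    } else {
      stop("malformed backtrace matrix: unknown state")
    }
  }
  stop("malformed backtrace matrix: no STOP within L_q + L_t steps")
}

#' Align two profile HMMs and return the full alignment
#'
#' Convenience wrapper around [viterbi_scalar()] + [traceback_alignment()].
#'
#' @inheritParams viterbi_scalar
#' @return A `pair_alignment`.
#' @export
align_hmms <- function(q, t, cell_off = NULL, ss = NULL, corrected = TRUE) {
  v <- viterbi_scalar(q, t, cell_off = cell_off, ss = ss,
                      corrected = corrected)
  traceback_alignment(v$bt, v$end_cell, v$score, q$name, t$name)
}

#' Optimal and suboptimal Viterbi alignments
#'
#' Alignment k+1 is the Viterbi optimum among paths avoiding every cell
#' within Chebyshev distance `exclusion_radius` of any cell on alignments
#' 1..k (cell-off bit set on those cells). The first alignment runs the
#' plain code path; later ones the cell-off path. Stops early when no
#' positive-scoring alignment remains.
#'
#' @inheritParams viterbi_scalar
#' @param n_alignments Maximum number of alignments (>= 1).
#' @param exclusion_radius Chebyshev radius of the forbidden neighborhood
#'   (default 40 cells).
#' @return List of `pair_alignment` objects with non-increasing scores.
#' @export
suboptimal_alignments <- function(q, t, n_alignments, exclusion_radius = 40L,
                                  corrected = TRUE) {
  stopifnot(n_alignments >= 1L)
  out <- list()
  co <- NULL
  for (k in seq_len(n_alignments)) {
    v <- viterbi_scalar(q, t, cell_off = co, corrected = corrected)
    if (v$score <= 0 || v$end_cell[[1L]] == 0L) break
    aln <- traceback_alignment(v$bt, v$end_cell, v$score, q$name, t$name)
    out[[k]] <- aln
    if (k == n_alignments) break
    if (is.null(co)) co <- matrix(as.raw(0L), q$L + 1L, t$L + 1L)
    r <- as.integer(exclusion_radius)
    for (p in seq_len(nrow(aln$path))) {
      i <- aln$path$i[[p]]; j <- aln$path$j[[p]]
      co[max(1L, i - r):min(q$L, i + r) + 1L,
         max(1L, j - r):min(t$L, j + r) + 1L] <- as.raw(0x80)
    }
  }
  out
}
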