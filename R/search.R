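# End-to-end search driver: database container, chunked Viterbi with
# E-value-based early termination, MAC realignment, iterative search.

#' Build an in-memory profile HMM database
#'
#' Builds the column-state alphabet from the database profiles (or reuses
#' a supplied one) and discretizes every profile for the prefilter.
#'
#' @param profiles Named list of [profile_hmm()] objects (names must be
#'   unique; unnamed lists use each profile's own name).
#' @param K Column-state alphabet size; capped at the number of distinct
#'   columns available (default 219).
#' @param seed Seed for the alphabet clustering.
#' @param alphabet Optional prebuilt `column_alphabet`.
#' @return Object of class `hmm_db`: list with `profiles`, `cs` (raw
#'   column-state sequences), `alphabet`, `lengths`.
#' @export
make_hmm_db <- function(profiles, K = 219L, seed = 1L, alphabet = NULL) {
  stopifnot(length(profiles) >= 1L)
  if (is.null(names(profiles))) {
    names(profiles) <- vapply(profiles, function(h) h$name, "")
  }
  if (anyDuplicated(names(profiles))) stop("duplicate profile names")
  if (is.null(alphabet)) {
    ncols <- sum(vapply(profiles, function(h) h$L, 0L))
    K <- min(K, max(2L, ncols - 1L))
    alphabet <- build_column_alphabet(profiles, K = K, seed = seed)
  }
  cs <- lapply(profiles, discretize_profile, alphabet = alphabet)
  structure(list(profiles = profiles, cs = cs, alphabet = alphabet,
                 lengths = vapply(profiles, function(h) h$L, 0L)),
            class = "hmm_db")
}

#' @export
print.hmm_db <- function(x, ...) {
  cat(sprintf("Profile HMM database: %d targets, alphabet K = %d\n",
              length(x$profiles), x$alphabet$K))
  invisible(x)
}

# ---- FFindex-backed storage ----------------------------------------------

.serialize_alphabet <- function(alphabet) {
  paste0("K ", alphabet$K, "\n",
         paste(apply(alphabet$emission, 1L,
                     function(p) paste(.prob_to_int(p), collapse = " ")),
               collapse = "\n"), "\n")
}

.deserialize_alphabet <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- lines[nzchar(lines)]
  K <- as.integer(sub("^K ", "", lines[[1L]]))
  em <- t(vapply(lines[-1L], function(l) {
    .int_to_prob(as.integer(strsplit(l, " ", fixed = TRUE)[[1L]]))
  }, numeric(20L), USE.NAMES = FALSE))
  em <- em / rowSums(em)
  structure(list(emission = em, K = K), class = "column_alphabet")
}

#' Write / read an HMM database as FFindex file pairs
#'
#' Produces `<prefix>_hmm.ffdata/.ffindex` (profile text records) and
#' `<prefix>_cs.ffdata/.ffindex` (column-state byte sequences plus the
#' serialized alphabet under the reserved name `__ALPHABET__`).
#'
#' @param db An `hmm_db`.
#' @param prefix Path prefix for the four files.
#' @return `write_hmm_db`: the prefix, invisibly. `read_hmm_db`: an
#'   `hmm_db`.
#' @export
write_hmm_db <- function(db, prefix) {
  stopifnot(inherits(db, "hmm_db"))
  hmm_recs <- lapply(db$profiles, write_profile)
  ffindex_write(ffindex_pack(hmm_recs),
                paste0(prefix, "_hmm.ffdata"), paste0(prefix, "_hmm.ffindex"))
  cs_recs <- c(db$cs, list(`__ALPHABET__` =
                             charToRaw(.serialize_alphabet(db$alphabet))))
  ffindex_write(ffindex_pack(cs_recs),
                paste0(prefix, "_cs.ffdata"), paste0(prefix, "_cs.ffindex"))
  invisible(prefix)
}

#' @rdname write_hmm_db
#' @export
read_hmm_db <- function(prefix) {
  hdb <- ffindex_read(paste0(prefix, "_hmm.ffdata"),
                      paste0(prefix, "_hmm.ffindex"))
  cdb <- ffindex_read(paste0(prefix, "_cs.ffdata"),
                      paste0(prefix, "_cs.ffindex"))
  nms <- ffindex_names(hdb)
  profiles <- setNames(lapply(nms, function(n) {
    read_profile(rawToChar(ffindex_get(hdb, n)))
  }), nms)
  alphabet <- .deserialize_alphabet(rawToChar(ffindex_get(cdb, "__ALPHABET__")))
  cs <- setNames(lapply(nms, function(n) ffindex_get(cdb, n)), nms)
  structure(list(profiles = profiles, cs = cs, alphabet = alphabet,
                 lengths = vapply(profiles, function(h) h$L, 0L)),
            class = "hmm_db")
}

# ---- chunked Viterbi with early termination ------------------------------

#' Chunked Viterbi search with E-value early termination
#'
#' Candidates are sorted by decreasing prefilter score and split into
#' chunks; within each chunk targets are sorted by decreasing length and
#' aligned with the batched Viterbi. After each chunk the mean of
#' `1 / (1 + E-value)` over the chunk is computed; remaining chunks are
#' skipped when it drops below `term_threshold`.
#'
#' @param q Query [profile_hmm()].
#' @param db An `hmm_db`.
#' @param candidates Data frame with `name` and a prefilter score column
#'   (`gapped` or `prefilter`); default: all targets, prefilter score 0.
#' @param evd Gumbel calibration (list with `lambda`, `mu`).
#' @param n_db Database size used for E-values (default: number of
#'   targets in `db`).
#' @param chunk_size Chunk size (default 2000).
#' @param term_threshold Early-termination threshold on the chunk mean of
#'   `1/(1+E)` (default 0.01).
#' @param early_termination Disable to always process every chunk.
#' @param batch_width Lanes for [viterbi_batch()].
#' @param with_alignment Attach traceback coordinates (default `TRUE`).
#' @return List with `hits` (data frame: `target`, `prefilter`,
#'   `score_bits`, `p_value`, `e_value`, and alignment coordinates),
#'   `paths` (named list of `pair_alignment`s) and `n_processed`.
#' @export
chunked_search <- function(q, db, candidates = NULL, evd, n_db = NULL,
                           chunk_size = 2000L, term_threshold = 0.01,
                           early_termination = TRUE, batch_width = 8L,
                           with_alignment = TRUE) {
  if (is.null(candidates)) {
    candidates <- data.frame(name = names(db$profiles), prefilter = 0,
                             stringsAsFactors = FALSE)
  }
  pf_col <- intersect(c("prefilter", "gapped"), names(candidates))[[1L]]
  if (is.null(n_db)) n_db <- length(db$profiles)
  cand <- candidates[order(-candidates[[pf_col]], candidates$name), ,
                     drop = FALSE]
  hits <- list()
  paths <- list()
  n_proc <- 0L
  chunk_starts <- seq(1L, nrow(cand), by = chunk_size)
  for (cs in chunk_starts) {
    idx <- cs:min(cs + chunk_size - 1L, nrow(cand))
    chunk <- cand[idx, , drop = FALSE]
    lens <- db$lengths[chunk$name]
    chunk <- chunk[order(-lens, chunk$name), , drop = FALSE]
    targets <- db$profiles[chunk$name]
    res <- viterbi_batch(q, targets, batch_width = batch_width)
    scores <- vapply(res, `[[`, 0, "score")
    pv <- evd_pvalue(scores, evd)
    ev <- pv * n_db
    df <- data.frame(target = chunk$name, prefilter = chunk[[pf_col]],
                     score_bits = scores, p_value = pv, e_value = ev,
                     q_start = 0L, q_end = 0L, t_start = 0L, t_end = 0L,
                     n_aligned_pairs = 0L, stringsAsFactors = FALSE)
    if (with_alignment) {
      for (k in seq_along(res)) {
        aln <- traceback_alignment(res[[k]]$bt, res[[k]]$end_cell,
                                   scores[[k]], q$name, chunk$name[[k]])
        paths[[chunk$name[[k]]]] <- aln
        if (nrow(aln$path)) {
          mm <- aln$path[aln$path$state == "MM", , drop = FALSE]
          df$q_start[[k]] <- aln$path$i[[1L]]
          df$q_end[[k]] <- aln$path$i[[nrow(aln$path)]]
          df$t_start[[k]] <- aln$path$j[[1L]]
          df$t_end[[k]] <- aln$path$j[[nrow(aln$path)]]
          df$n_aligned_pairs[[k]] <- nrow(mm)
        }
      }
    }
    hits[[length(hits) + 1L]] <- df
    n_proc <- n_proc + nrow(chunk)
    if (early_termination && mean(1 / (1 + ev)) < term_threshold) break
  }
  hits <- do.call(rbind, hits)
  hits <- hits[order(hits$e_value, -hits$score_bits, hits$target), ,
               drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, paths = paths, n_processed = n_proc)
}

#' Search a query profile HMM against a database
#'
#' Full pipeline: two-stage prefilter on the discretized database,
#' per-query Gumbel calibration against column-shuffled targets, chunked
#' batched Viterbi with early termination, and MAC realignment of hits
#' below the realignment E-value threshold.
#'
#' @param q Query [profile_hmm()].
#' @param db An `hmm_db`.
#' @param seed Seed for calibration decoys.
#' @param use_prefilter Run the prefilter (default `TRUE`; `FALSE`
#'   Viterbi-aligns every target).
#' @param keep_fraction,min_prefilter_hits,gap_open,gap_extend See
#'   [prefilter()].
#' @param n_calibration Number of decoy alignments for the E-value fit.
#' @param chunk_size,term_threshold,early_termination,batch_width See
#'   [chunked_search()].
#' @param realign Realign significant hits with MAC (default `TRUE`).
#' @param realign_e_max Realign hits with E-value at most this threshold
#'   (default 10).
#' @param mact MAC penalty (default 0.35).
#' @param evd Optional precomputed calibration, skipping `calibrate_evd`.
#' @return Object of class `search_result`: list with `hits` (sorted by
#'   ascending E-value), `alignments` (MAC where realigned, else
#'   Viterbi), `evd`, `n_processed`, `n_candidates`.
#' @export
search_hmm <- function(q, db, seed = 1L, use_prefilter = TRUE,
                       keep_fraction = 0.05, min_prefilter_hits = 100L,
                       gap_open = 5, gap_extend = 1,
                       n_calibration = 1000L, chunk_size = 2000L,
                       term_threshold = 0.01, early_termination = TRUE,
                       batch_width = 8L, realign = TRUE, realign_e_max = 10,
                       mact = 0.35, evd = NULL) {
  stopifnot(inherits(db, "hmm_db"))
  candidates <- if (use_prefilter) {
    pf <- prefilter(q, db$cs, db$alphabet, keep_fraction = keep_fraction,
                    min_prefilter_hits = min_prefilter_hits,
                    gap_open = gap_open, gap_extend = gap_extend)
    data.frame(name = pf$name, prefilter = pf$gapped,
               stringsAsFactors = FALSE)
  } else {
    data.frame(name = names(db$profiles), prefilter = 0,
               stringsAsFactors = FALSE)
  }
  if (is.null(evd)) {
    evd <- calibrate_evd(q, db$profiles, n_decoys = n_calibration,
                         seed = seed, batch_width = batch_width)
  }
  res <- chunked_search(q, db, candidates, evd,
                        n_db = length(db$profiles),
                        chunk_size = chunk_size,
                        term_threshold = term_threshold,
                        early_termination = early_termination,
                        batch_width = batch_width)
  alignments <- res$paths
  if (realign) {
    to_realign <- res$hits$target[res$hits$e_value <= realign_e_max]
    for (nm in to_realign) {
      post <- forward_backward(q, db$profiles[[nm]])
      mac <- mac_align(post, mact = mact, q_name = q$name, t_name = nm)
      mac$e_value <- res$hits$e_value[[match(nm, res$hits$target)]]
      alignments[[nm]] <- mac
    }
  }
  structure(list(hits = res$hits, alignments = alignments, evd = evd,
                 n_processed = res$n_processed,
                 n_candidates = nrow(candidates), query = q$name),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("Search %s: %d candidates, %d aligned, best E-value %.3g\n",
              x$query, x$n_candidates, x$n_processed,
              if (nrow(x$hits)) x$hits$e_value[[1L]] else NA))
  print(utils::head(x$hits[, c("target", "score_bits", "p_value", "e_value",
                               "n_aligned_pairs")], 10L))
  invisible(x)
}

# ---- iterative search -----------------------------------------------------

# Merge one accepted target into the query MSA: aligned target consensus
# residues go into the query match columns; target columns between
# aligned pairs become lowercase insertions.
.merge_hit_row <- function(query_L, target_consensus, path) {
  mm <- path[path$state == "MM", , drop = FALSE]
  if (nrow(mm) == 0L) return(NULL)
  cons <- strsplit(target_consensus, "", fixed = TRUE)[[1L]]
  out <- character(query_L)
  out[] <- "-"
  aligned_j <- rep(NA_integer_, query_L)
  aligned_j[mm$i] <- mm$j
  for (k in seq_len(nrow(mm))) out[[mm$i[[k]]]] <- cons[[mm$j[[k]]]]
  # target columns skipped between consecutive aligned pairs -> insertions
  if (nrow(mm) > 1L) {
    for (k in seq_len(nrow(mm) - 1L)) {
      j0 <- mm$j[[k]]; j1 <- mm$j[[k + 1L]]
      if (j1 - j0 > 1L) {
        ins <- tolower(paste(cons[(j0 + 1L):(j1 - 1L)], collapse = ""))
        out[[mm$i[[k]]]] <- paste0(out[[mm$i[[k]]]], ins)
      }
    }
  }
  paste(out, collapse = "")
}

#' Iterative profile search from a single query sequence
#'
#' Iteration 1 builds a profile HMM from the single query sequence; each
#' subsequent iteration searches the database, adds the MAC-aligned
#' consensus sequences of hits with E-value at most `e_threshold` to the
#' query MSA (insertions relative to the query become lowercase),
#' refilters redundancy and rebuilds the HMM.
#'
#' @param query_name,query_seq Query identifier and residue string.
#' @param db An `hmm_db`.
#' @param n_iterations Number of search iterations (>= 1).
#' @param e_threshold Acceptance E-value threshold (default 1e-3).
#' @param seqid_max Redundancy-filter cutoff applied to the growing MSA.
#' @param seed Seed (calibration decoys per iteration derive from it).
#' @param ... Further arguments passed to [search_hmm()].
#' @return List with `msa` (the final query MSA), `hmm`, `search` (the
#'   last `search_result`), `accepted` (names accepted per iteration) and
#'   `neff_trace` (mean profile diversity per iteration).
#' @export
iterative_search <- function(query_name, query_seq, db, n_iterations = 2L,
                             e_threshold = 1e-3, seqid_max = 0.9, seed = 1L,
                             ...) {
  stopifnot(n_iterations >= 1L)
  m <- msa(query_name, toupper(query_seq))
  accepted <- list()
  neff_trace <- numeric(0)
  res <- NULL
  hmm <- NULL
  for (it in seq_len(n_iterations)) {
    m <- filter_redundancy(m, seqid_max = seqid_max)
    hmm <- build_profile_hmm(m, name = query_name)
    neff_trace <- c(neff_trace, mean(hmm$neff))
    res <- search_hmm(hmm, db, seed = derive_seed(seed, 20L + it), ...)
    acc <- res$hits[res$hits$e_value <= e_threshold, , drop = FALSE]
    accepted[[it]] <- acc$target
    if (it == n_iterations) break
    new_names <- setdiff(acc$target, m$names)
    rows_added <- FALSE
    for (nm in new_names) {
      aln <- res$alignments[[nm]]
      if (is.null(aln) || nrow(aln$path) == 0L) next
      row <- .merge_hit_row(hmm$L, hmm_consensus(db$profiles[[nm]]), aln$path)
      if (is.null(row)) next
      m <- msa(c(m$names, nm), c(m$rows, row))
      rows_added <- TRUE
    }
    if (!rows_added) {
      # converged: no new sequences to add
      for (k in seq(it + 1L, n_iterations)) accepted[[k]] <- acc$target
      break
    }
  }
  list(msa = m, hmm = hmm, search = res, accepted = accepted,
       neff_trace = neff_trace)
}
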