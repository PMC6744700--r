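# Independent reference implementations used as test oracles. These are
# deliberately naive (exhaustive enumeration, full matrices, per-position
# loops) and stay independent of the production code paths they check.

LOG0_T <- -100000

ltr <- function(p) if (p > 0) log2(p) else LOG0_T

saa_of <- function(q, t, i, j) {
  s <- sum(q$match_emission[i, ] * t$match_emission[j, ] / q$background)
  if (s > 0) log2(s) else LOG0_T
}

# transition factor tables (log2) for a move from `state` continuing as
# `nxt`, taken at query column i / target column j of the source cell
step_factor <- function(q, t, state, nxt, i, j) {
  qt <- function(s) ltr(q$transition[i, s])
  tt <- function(s) ltr(t$transition[j, s])
  key <- paste(state, nxt)
  switch(key,
    "MM MM" = qt(1) + tt(1),
    "MM MI" = qt(1) + tt(2),
    "MM IM" = qt(2) + tt(1),
    "MM DG" = qt(3),
    "MM GD" = tt(3),
    "MI MI" = qt(1) + tt(5),
    "MI MM" = qt(1) + tt(4),
    "IM IM" = qt(5) + tt(1),
    "IM MM" = qt(4) + tt(1),
    "DG DG" = qt(7),
    "DG MM" = qt(6) + tt(1),
    "GD GD" = tt(7),
    "GD MM" = qt(1) + tt(6),
    stop("illegal transition ", key))
}

# move of the destination pair state: how much i and j advance
state_move <- function(s) {
  switch(s, MM = c(1L, 1L), MI = c(1L, 0L), DG = c(1L, 0L),
         IM = c(0L, 1L), GD = c(0L, 1L))
}

# Exhaustive enumeration over every legal pair-state path (paths start
# and end in MM; II/DD excluded; only X->X and MM<->{MI,IM,DG,GD}
# transitions). Returns the maximum path score and, optionally, the full
# partition function and per-cell posterior numerators.
enumerate_paths <- function(q, t, collect = FALSE) {
  Lq <- q$L; Lt <- t$L
  best <- -Inf
  z <- 0
  post_num <- matrix(0, Lq, Lt)
  # walk(i, j, state, score): state holds at cell (i, j), score includes
  # everything up to and including (i, j)
  walk <- function(i, j, state, score, mm_cells) {
    if (state == "MM") {
      if (score > best) best <<- score
      if (collect) {
        z <<- z + 2^score
        for (c in mm_cells) {
          post_num[c[[1L]], c[[2L]]] <<- post_num[c[[1L]], c[[2L]]] + 2^score
        }
      }
    }
    for (nxt in c("MM", "MI", "IM", "DG", "GD")) {
      ok <- state == nxt || state == "MM" || nxt == "MM"
      if (!ok) next
      mv <- state_move(nxt)
      i2 <- i + mv[[1L]]; j2 <- j + mv[[2L]]
      if (i2 > Lq || j2 > Lt) next
      fac <- step_factor(q, t, state, nxt, i, j)
      if (fac <= LOG0_T) next
      sc <- score + fac + if (nxt == "MM") saa_of(q, t, i2, j2) else 0
      walk(i2, j2, nxt, sc,
           if (nxt == "MM") c(mm_cells, list(c(i2, j2))) else mm_cells)
    }
  }
  for (i in seq_len(Lq)) {
    for (j in seq_len(Lt)) {
      walk(i, j, "MM", saa_of(q, t, i, j), list(c(i, j)))
    }
  }
  list(best = max(best, -Inf), log_z = if (collect) log2(z) else NA_real_,
       posterior = if (collect) post_num / z else NULL)
}

# Full-matrix Viterbi reference: O(Lq * Lt) matrices for all five pair
# states, identical recursion, comparison order and byte encoding as the
# production single-row kernel.
viterbi_full_matrix <- function(q, t) {
  Lq <- q$L; Lt <- t$L
  S <- lapply(1:5, function(k) matrix(LOG0_T, Lq + 1L, Lt + 1L))
  names(S) <- c("MM", "MI", "IM", "DG", "GD")
  bt <- matrix(as.raw(0L), Lq + 1L, Lt + 1L)
  qtr <- matrix(LOG0_T, Lq, 7L); pos <- q$transition > 0
  qtr[pos] <- log2(q$transition[pos])
  ttr <- matrix(LOG0_T, Lt, 7L); pos <- t$transition > 0
  ttr[pos] <- log2(t$transition[pos])
  best <- 0; ib <- 0L; jb <- 0L
  for (i in seq_len(Lq)) {
    qMM <- if (i >= 2) qtr[i - 1L, 1L] else LOG0_T
    qIM <- if (i >= 2) qtr[i - 1L, 4L] else LOG0_T
    qDM <- if (i >= 2) qtr[i - 1L, 6L] else LOG0_T
    qMD <- if (i >= 2) qtr[i - 1L, 3L] else LOG0_T
    qDD <- if (i >= 2) qtr[i - 1L, 7L] else LOG0_T
    for (j in seq_len(Lt)) {
      tMM <- if (j >= 2) ttr[j - 1L, 1L] else LOG0_T
      tIM <- if (j >= 2) ttr[j - 1L, 4L] else LOG0_T
      tDM <- if (j >= 2) ttr[j - 1L, 6L] else LOG0_T
      tMD <- if (j >= 2) ttr[j - 1L, 3L] else LOG0_T
      tDD <- if (j >= 2) ttr[j - 1L, 7L] else LOG0_T
      dot <- 0
      for (a in 1:20) {
        dot <- dot + q$match_emission[i, a] / q$background[[a]] *
          t$match_emission[j, a]
      }
      saa <- if (dot > 0) log2(dot) else LOG0_T
      bv <- 0; pred <- 0L
      c1 <- S$MM[i, j] + qMM + tMM; if (c1 > bv) { bv <- c1; pred <- 1L }
      c1 <- S$IM[i, j] + qIM + tMM; if (c1 > bv) { bv <- c1; pred <- 2L }
      c1 <- S$MI[i, j] + qMM + tIM; if (c1 > bv) { bv <- c1; pred <- 3L }
      c1 <- S$GD[i, j] + qMM + tDM; if (c1 > bv) { bv <- c1; pred <- 4L }
      c1 <- S$DG[i, j] + qDM + tMM; if (c1 > bv) { bv <- c1; pred <- 5L }
      nMM <- saa + bv
      cm <- S$MM[i, j + 1L] + qMM + ttr[j, 2L]
      cs <- S$MI[i, j + 1L] + qMM + ttr[j, 5L]
      mi_same <- !(cm > cs); nMI <- if (mi_same) cs else cm
      cm <- S$MM[i, j + 1L] + qMD
      cs <- S$DG[i, j + 1L] + qDD
      dg_same <- !(cm > cs); nDG <- if (dg_same) cs else cm
      cm <- S$MM[i + 1L, j] + qtr[i, 2L] + tMM
      cs <- S$IM[i + 1L, j] + qtr[i, 5L] + tMM
      im_same <- !(cm > cs); nIM <- if (im_same) cs else cm
      cm <- S$MM[i + 1L, j] + tMD
      cs <- S$GD[i + 1L, j] + tDD
      gd_same <- !(cm > cs); nGD <- if (gd_same) cs else cm
      S$MM[i + 1L, j + 1L] <- nMM
      S$MI[i + 1L, j + 1L] <- nMI
      S$IM[i + 1L, j + 1L] <- nIM
      S$DG[i + 1L, j + 1L] <- nDG
      S$GD[i + 1L, j + 1L] <- nGD
      bt[i + 1L, j + 1L] <- as.raw(pred + bitwShiftL(as.integer(gd_same), 3L) +
                                     bitwShiftL(as.integer(im_same), 4L) +
                                     bitwShiftL(as.integer(dg_same), 5L) +
                                     bitwShiftL(as.integer(mi_same), 6L))
      if (nMM > best) { best <- nMM; ib <- i; jb <- j }
    }
  }
  list(score = max(0, best), bt = bt, end_cell = c(i = ib, j = jb))
}

# Recompute the score of an alignment path directly from the model
# parameters (entry contributes only the first cell's column score).
path_score <- function(q, t, path) {
  if (nrow(path) == 0L) return(0)
  stopifnot(path$state[[1L]] == "MM")
  sc <- saa_of(q, t, path$i[[1L]], path$j[[1L]])
  if (nrow(path) > 1L) {
    for (k in 2:nrow(path)) {
      prev <- path[k - 1L, ]
      cur <- path[k, ]
      src_i <- prev$i
      src_j <- prev$j
      sc <- sc + step_factor(q, t, prev$state, cur$state, src_i, src_j)
      if (cur$state == "MM") sc <- sc + saa_of(q, t, cur$i, cur$j)
    }
  }
  sc
}

# Naive per-position sequence identity (the scalar reference loop).
naive_identity <- function(x, y) {
  cx <- strsplit(x, "", fixed = TRUE)[[1L]]
  cy <- strsplit(y, "", fixed = TRUE)[[1L]]
  stopifnot(length(cx) == length(cy))
  nid <- 0L; nx <- 0L; ny <- 0L
  for (k in seq_along(cx)) {
    if (cx[[k]] != "-") nx <- nx + 1L
    if (cy[[k]] != "-") ny <- ny + 1L
    if (cx[[k]] != "-" && cx[[k]] == cy[[k]]) nid <- nid + 1L
  }
  if (min(nx, ny) == 0L) return(0)
  nid / min(nx, ny)
}

# Brute-force O(N^2 L) greedy redundancy filter on match-column strings.
naive_filter <- function(m, seqid_max) {
  rows <- gsub("[a-z]", "", m$rows)
  keep <- 1L
  for (i in seq_along(rows)[-1L]) {
    ok <- TRUE
    for (k in keep) {
      if (naive_identity(rows[[k]], rows[[i]]) > seqid_max) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  keep
}

# Brute-force MAC: maximize sum of (P - mact) over all strictly monotone
# pair sets (enumerated recursively); empty set allowed.
brute_mac_score <- function(p, mact) {
  Lq <- nrow(p); Lt <- ncol(p)
  rec <- function(i0, j0) {
    best <- 0
    for (i in i0:Lq) {
      for (j in j0:Lt) {
        if (i > Lq || j > Lt) next
        v <- (p[i, j] - mact) +
          if (i < Lq && j < Lt) rec(i + 1L, j + 1L) else 0
        if (v > best) best <- v
      }
    }
    best
  }
  if (Lq < 1L || Lt < 1L) return(0)
  rec(1L, 1L)
}

# Direct per-column Henikoff weights: rebuilds each gap-free subalignment
# explicitly and recomputes position-based weights from scratch.
naive_column_weights <- function(m) {
  rows <- gsub("[a-z]", "", m$rows)
  M <- do.call(rbind, lapply(rows, function(r) strsplit(r, "", TRUE)[[1L]]))
  N <- nrow(M); L <- ncol(M)
  W <- matrix(0, N, L)
  for (i in seq_len(L)) {
    members <- which(M[, i] != "-")
    if (length(members) == 0L) { W[, i] <- 1 / N; next }
    sub <- M[members, , drop = FALSE]
    w <- numeric(length(members))
    for (j in seq_len(L)) {
      col <- sub[, j]
      res <- col[col != "-"]
      if (length(res) == 0L) next
      types <- unique(res)
      for (n in seq_along(members)) {
        if (col[[n]] != "-") {
          w[[n]] <- w[[n]] + 1 / (length(types) * sum(res == col[[n]]))
        }
      }
    }
    if (sum(w) <= 0) w <- rep(1, length(members))
    W[members, i] <- w / sum(w)
  }
  W
}

# Small random HMM helper for alignment tests.
tiny_hmm <- function(L, seed, conservation = 0.5) {
  random_profile_hmm(L, seed, conservation = conservation)
}

# Engineered fixture: five conserved columns shared by query and target,
# one extra query column traversed as a target insertion (MI) and one as
# a query pass-through deletion (DG).
make_indel_fixture <- function() {
  delta <- function(a) { v <- rep(0.04 / 19, 20); v[[a]] <- 0.96; v }
  bg <- aa_background()
  tcols <- do.call(rbind, lapply(c(1, 5, 4, 7, 8), delta))   # A C D E G
  qcols <- do.call(rbind, lapply(c(1, 5, 18, 4, 7, 14, 8), delta)) # A C W D E F G
  base_tr <- function(L) {
    tr <- matrix(rep(c(0.9, 0.05, 0.05, 0.9, 0.1, 0.9, 0.1), each = L), L, 7L)
    tr[L, ] <- c(1, 0, 0, 1, 0, 1, 0)
    tr
  }
  ttr <- base_tr(5L)
  ttr[2L, 1:3] <- c(0.55, 0.40, 0.05)   # target opens an insertion after col 2
  qtr <- base_tr(7L)
  qtr[5L, 1:3] <- c(0.55, 0.05, 0.40)   # query opens a deletion after col 5
  list(q = profile_hmm("q_fig", qcols, qtr, rep(1, 7L), bg),
       t = profile_hmm("t_fig", tcols, ttr, rep(1, 5L), bg))
}
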