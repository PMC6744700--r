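# Pair-state Viterbi: column score, scalar/batched DP, backtrace codec,
# traceback, suboptimal alignments.

test_that("column score matches its closed forms and the explicit sum", {
  bg <- aa_background()
  expect_equal(column_score(bg, bg, bg), 0)
  delta <- c(1, rep(0, 19))
  expect_equal(column_score(delta, delta, rep(1 / 20, 20)), log2(20))
  expect_identical(column_score(delta, c(0, 1, rep(0, 18)), rep(1 / 20, 20)),
                   -Inf)
  set.seed(5)
  for (k in 1:50) {
    q <- rgamma(20, 0.5); q <- q / sum(q)
    t <- rgamma(20, 0.5); t <- t / sum(t)
    ref <- 0
    for (a in 1:20) ref <- ref + q[[a]] * t[[a]] / bg[[a]]
    expect_equal(column_score(q, t, bg), log2(ref), tolerance = 1e-12)
  }
})

test_that("two length-1 delta HMMs align in a single MM cell", {
  em <- matrix(0, 1, 20); em[1, 3] <- 1
  tr <- matrix(c(1, 0, 0, 1, 0, 1, 0), 1, 7)
  h <- profile_hmm("d", em, tr, 1, rep(1 / 20, 20))
  v <- viterbi_scalar(h, h)
  expect_equal(v$score, log2(20), tolerance = 1e-12)
  aln <- traceback_alignment(v$bt, v$end_cell, v$score)
  expect_equal(aln$path, data.frame(i = 1L, j = 1L, state = "MM"))
})

test_that("Viterbi equals the exhaustive path enumeration on small HMMs", {
  for (seed in 1:60) {
    q <- tiny_hmm(sample(1:4, 1L), seed, conservation = 0.3)
    t <- tiny_hmm(sample(1:4, 1L), seed + 500L, conservation = 0.3)
    v <- viterbi_scalar(q, t)
    ref <- enumerate_paths(q, t)
    expect_equal(v$score, max(0, ref$best), tolerance = 1e-9,
                 label = sprintf("seed %d", seed))
  }
})

test_that("self-alignment of a match-dominated HMM is the full MM diagonal", {
  for (seed in c(3, 9)) {
    h <- random_profile_hmm(12L, seed, conservation = 0.2)
    # force all q_i(M,M) >= 0.9
    h$transition[, 1:3] <- matrix(rep(c(0.9, 0.05, 0.05), each = 12L), 12L)
    h$transition[12L, ] <- c(1, 0, 0, 1, 0, 1, 0)
    aln <- align_hmms(h, h)
    expect_equal(aln$path$state, rep("MM", 12L))
    expect_equal(aln$path$i, 1:12)
    expect_equal(aln$path$j, 1:12)
  }
})

test_that("batched Viterbi reproduces the scalar loop including padding", {
  q <- tiny_hmm(18L, 77)
  targets <- lapply(1:11, function(k) {
    tiny_hmm(sample(c(1L, 3:30), 1L), 600L + k)
  })
  for (bw in c(4L, 8L)) {
    res <- viterbi_batch(q, targets, batch_width = bw)
    for (k in seq_along(targets)) {
      ref <- viterbi_scalar(q, targets[[k]])
      expect_equal(res[[k]]$score, ref$score, tolerance = 1e-6)
      expect_equal(res[[k]]$end_cell, ref$end_cell)
      expect_identical(res[[k]]$bt, ref$bt)
    }
  }
  # batch of identical targets gives identical scores
  res8 <- viterbi_batch(q, rep(list(targets[[1L]]), 8L))
  expect_equal(length(unique(vapply(res8, `[[`, 0, "score"))), 1L)
  expect_error(viterbi_batch(q, list()), "empty")
})

test_that("padding never places path cells beyond a short target's length", {
  q <- tiny_hmm(10L, 31)
  targets <- list(tiny_hmm(25L, 32), tiny_hmm(1L, 33), tiny_hmm(12L, 34))
  res <- viterbi_batch(q, targets, batch_width = 4L)
  for (k in seq_along(targets)) {
    aln <- traceback_alignment(res[[k]]$bt, res[[k]]$end_cell)
    if (nrow(aln$path)) expect_lte(max(aln$path$j), targets[[k]]$L)
    expect_equal(ncol(res[[k]]$bt), targets[[k]]$L + 1L)
  }
})

test_that("single-row kernel equals the full-matrix reference", {
  for (seed in 1:30) {
    q <- tiny_hmm(sample(2:16, 1L), seed + 40L)
    t <- tiny_hmm(sample(2:16, 1L), seed + 900L)
    v <- viterbi_scalar(q, t)
    ref <- viterbi_full_matrix(q, t)
    expect_equal(v$score, ref$score, tolerance = 1e-12)
    expect_equal(v$end_cell, ref$end_cell)
    expect_identical(v$bt, ref$bt)
  }
})

test_that("backtrace byte codec round-trips all 192 valid tuples", {
  expect_equal(encode_backtrace_byte("STOP", 0, 0, 0, 0, 0), 0L)
  expect_equal(bitwAnd(encode_backtrace_byte("MM", 0, 0, 0, 0, 1), 128L), 128L)
  n <- 0L
  for (pred in c("STOP", "MM", "IM", "MI", "GD", "DG")) {
    for (gd in 0:1) for (im in 0:1) for (dg in 0:1) for (mi in 0:1) {
      for (co in 0:1) {
        b <- encode_backtrace_byte(pred, gd, im, dg, mi, co)
        d <- decode_backtrace_byte(b)
        expect_identical(d, list(mm_pred = pred, gd_same = gd, im_same = im,
                                 dg_same = dg, mi_same = mi, cell_off = co))
        n <- n + 1L
      }
    }
  }
  expect_equal(n, 192L)
  expect_error(decode_backtrace_byte(6L), "invalid")
  expect_error(encode_backtrace_byte("XX"), "invalid")
})

test_that("an engineered insertion/deletion fixture yields the canonical path", {
  fx <- make_indel_fixture()
  aln <- align_hmms(fx$q, fx$t)
  expect_equal(aln$path$state, c("MM", "MM", "MI", "MM", "MM", "DG", "MM"))
  expect_equal(aln$path$i, 1:7)
  expect_equal(aln$path$j, c(1L, 2L, 2L, 3L, 4L, 4L, 5L))
})

test_that("traceback path score re-accumulates to the DP score", {
  for (seed in 1:25) {
    q <- tiny_hmm(sample(2:20, 1L), seed + 70L)
    t <- tiny_hmm(sample(2:20, 1L), seed + 1100L)
    aln <- align_hmms(q, t)
    if (nrow(aln$path) == 0L) next
    expect_equal(path_score(q, t, aln$path), aln$score, tolerance = 1e-6)
  }
})

test_that("score is symmetric under swapping query and target", {
  for (seed in 1:10) {
    q <- tiny_hmm(sample(2:15, 1L), seed + 130L)
    t <- tiny_hmm(sample(2:15, 1L), seed + 1300L)
    a <- align_hmms(q, t)
    b <- align_hmms(t, q)
    expect_equal(a$score, b$score, tolerance = 1e-9)
    # paths agree with IM<->MI and DG<->GD exchanged
    swap <- c(MM = "MM", MI = "IM", IM = "MI", DG = "GD", GD = "DG")
    expect_equal(data.frame(i = b$path$j, j = b$path$i,
                            state = unname(swap[b$path$state])),
                 a$path)
  }
})

test_that("appending an identical match column never lowers the self score", {
  h <- random_profile_hmm(8L, 55, conservation = 0.2)
  s0 <- viterbi_scalar(h, h)$score
  em <- rbind(h$match_emission, h$match_emission[8L, ])
  tr <- rbind(h$transition, h$transition[8L, ])
  tr[8L, ] <- c(0.9, 0.05, 0.05, 0.9, 0.1, 0.9, 0.1)
  h2 <- profile_hmm(h$name, em, tr, c(h$neff, h$neff[[8L]]))
  s1 <- viterbi_scalar(h2, h2)$score
  expect_gte(s1, s0)
})

test_that("local score is never negative", {
  # two HMMs concentrated on disjoint residues: nothing aligns
  em1 <- matrix(0, 3, 20); em1[, 1] <- 1
  em2 <- matrix(0, 3, 20); em2[, 2] <- 1
  tr <- matrix(rep(c(0.9, 0.05, 0.05, 0.9, 0.1, 0.9, 0.1), each = 3), 3, 7)
  tr[3, ] <- c(1, 0, 0, 1, 0, 1, 0)
  h1 <- profile_hmm("a", em1, tr, rep(1, 3))
  h2 <- profile_hmm("b", em2, tr, rep(1, 3))
  v <- viterbi_scalar(h1, h2)
  expect_identical(v$score, 0)
  expect_equal(unname(v$end_cell), c(0L, 0L))
  expect_equal(nrow(traceback_alignment(v$bt, v$end_cell)$path), 0L)
})

test_that("suboptimal alignments respect the exclusion zone", {
  # two well-separated homologous blocks
  delta <- function(a) { v <- rep(0.02 / 19, 20); v[[a]] <- 0.98; v }
  block <- do.call(rbind, lapply(c(1, 5, 4, 7, 8, 10), delta))
  spacer <- matrix(1 / 20, 90, 20)
  # the repeated block makes the off-diagonal block1-vs-block2 alignment
  # the best path outside the 40-cell zone around the self diagonal
  em <- rbind(block, spacer, block)
  L <- nrow(em)
  tr <- matrix(rep(c(0.9, 0.05, 0.05, 0.9, 0.1, 0.9, 0.1), each = L), L, 7)
  tr[L, ] <- c(1, 0, 0, 1, 0, 1, 0)
  h <- profile_hmm("blocks", em, tr, rep(1, L))
  alns <- suboptimal_alignments(h, h, n_alignments = 2L,
                                exclusion_radius = 40L)
  expect_equal(length(alns), 2L)
  expect_gte(alns[[1L]]$score, alns[[2L]]$score)
  # no cell of alignment 2 within Chebyshev distance 40 of alignment 1
  d <- outer(alns[[2L]]$path$i, alns[[1L]]$path$i, function(a, b) abs(a - b))
  dj <- outer(alns[[2L]]$path$j, alns[[1L]]$path$j, function(a, b) abs(a - b))
  expect_true(all(pmax(d, dj) > 40L))
})

test_that("suboptimal alignment scores are non-increasing", {
  for (seed in c(2, 12, 22)) {
    q <- tiny_hmm(30L, seed + 2000L, conservation = 0.15)
    t <- tiny_hmm(30L, seed + 2100L, conservation = 0.15)
    alns <- suboptimal_alignments(q, t, n_alignments = 4L,
                                  exclusion_radius = 3L)
    sc <- vapply(alns, `[[`, 0, "score")
    if (length(sc) > 1L) expect_true(all(diff(sc) <= 1e-9))
    expect_identical(alns[[1L]]$score, viterbi_scalar(q, t)$score)
  }
})

test_that("printed-variant transition factors are selectable", {
  q <- tiny_hmm(8L, 71)
  t <- tiny_hmm(9L, 72)
  a <- viterbi_scalar(q, t, corrected = TRUE)
  b <- viterbi_scalar(q, t, corrected = FALSE)
  expect_true(is.finite(b$score) && b$score >= 0)
  # when the swapped slots hold identical probabilities the variants agree
  qe <- q; te <- t
  qe$transition[, 3L] <- qe$transition[, 6L] <-
    (qe$transition[, 3L] + qe$transition[, 6L]) / 2
  qe$transition[, 1L] <- 1 - qe$transition[, 2L] - qe$transition[, 3L]
  qe$transition[, 7L] <- 1 - qe$transition[, 6L]
  te$transition[, 2L] <- te$transition[, 7L] <-
    (te$transition[, 2L] + te$transition[, 7L]) / 2
  te$transition[, 1L] <- 1 - te$transition[, 2L] - te$transition[, 3L]
  te$transition[, 6L] <- 1 - te$transition[, 7L]
  expect_equal(viterbi_scalar(qe, te, corrected = FALSE)$score,
               viterbi_scalar(qe, te, corrected = TRUE)$score,
               tolerance = 1e-12)
})
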