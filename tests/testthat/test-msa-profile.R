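# MSA -> profile HMM: match columns, identity filter, weights, estimation.

test_that("match columns follow the gap-fraction rule", {
  rows <- c("AC", "AC", "A-", "-C", "--")
  m <- msa(sprintf("s%d", 1:5), rows)
  # column 1: 2/5 gaps (40%) -> match; column 2: built below
  mask <- assign_match_columns(m)
  expect_true(mask[[1L]])
  m2 <- msa(sprintf("s%d", 1:5), c("A", "-", "-", "-", "A"))  # 60% gaps
  expect_false(assign_match_columns(m2)[[1L]])
  m3 <- msa(c("a", "b"), c("AC", "GC"))  # gapless
  expect_true(all(assign_match_columns(m3)))
})

test_that("remaster_msa demotes columns to insertions", {
  m <- msa(c("a", "b"), c("ACD", "A-D"))
  out <- remaster_msa(m, c(TRUE, FALSE, TRUE))
  expect_equal(out$length, 2L)
  expect_equal(out$rows, c("AcD", "AD"))
})

test_that("pairwise identity matches the naive per-position loop", {
  expect_equal(pairwise_identity("ACDE", "ACDE"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAV"), 0.75)
  set.seed(7)
  aa <- c(aa_alphabet(), "-")
  for (k in 1:200) {
    L <- sample(1:60, 1L)
    x <- paste(sample(aa, L, replace = TRUE, prob = c(rep(1, 20), 5)), collapse = "")
    y <- paste(sample(aa, L, replace = TRUE, prob = c(rep(1, 20), 5)), collapse = "")
    expect_identical(pairwise_identity(x, y), naive_identity(x, y))
    expect_identical(pairwise_identity(x, y), pairwise_identity(y, x))
  }
  expect_error(pairwise_identity("AC", "A"), "equal length")
})

test_that("redundancy filter equals the brute-force reference and is idempotent", {
  m <- msa(c("a", "b"), c("ACDE", "ACDE"))
  expect_equal(n_sequences(filter_redundancy(m, 0.9)), 1L)

  m2 <- random_msa(6L, 30L, seed = 11, gap_rate = 0.3, conservation = 5)
  f2 <- filter_redundancy(m2, 0.9)
  expect_gte(n_sequences(f2), 1L)

  for (seed in 1:40) {
    m <- random_msa(n_seq = sample(2:25, 1L), L = sample(5:60, 1L),
                    seed = seed, gap_rate = 0.25,
                    conservation = sample(c(0.05, 0.3, 2), 1L))
    cutoff <- sample(c(0.5, 0.7, 0.9), 1L)
    f <- filter_redundancy(m, cutoff)
    expect_identical(f$names, m$names[naive_filter(m, cutoff)])
    # query always kept, order preserved, idempotent
    expect_identical(f$names[[1L]], m$names[[1L]])
    expect_identical(filter_redundancy(f, cutoff), f)
  }
})

test_that("column weights match the direct subalignment recomputation", {
  # N identical gapless sequences: every weight 1/N in every column
  m <- msa(sprintf("s%d", 1:5), rep("ACDEF", 5L))
  W <- column_sequence_weights(m)
  expect_equal(unname(W), matrix(0.2, 5L, 5L), ignore_attr = TRUE)

  m1 <- msa("only", "ACD")
  expect_equal(unname(column_sequence_weights(m1)), matrix(1, 1L, 3L),
               ignore_attr = TRUE)

  for (seed in 1:20) {
    m <- random_msa(n_seq = sample(2:10, 1L), L = sample(2:15, 1L),
                    seed = seed + 100L, gap_rate = 0.3)
    W <- column_sequence_weights(m)
    expect_equal(unname(W), naive_column_weights(m), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(colSums(W), rep(1, ncol(W)))
  }
})

test_that("all-gap match columns fall back to uniform weights", {
  m <- msa(c("a", "b"), c("A-C", "A-C"))
  # middle column has gaps in every row yet stays a match column
  W <- column_sequence_weights(m)
  expect_equal(W[, 2L], c(0.5, 0.5))
  expect_true(attr(W, "uniform_fallback")[[2L]])
})

test_that("single sequence with no pseudocounts gives delta emissions", {
  m <- msa("q", "ACD")
  h <- build_profile_hmm(m, pca = 0, trans_pc = 0)
  expect_equal(h$L, 3L)
  idx <- match(c("A", "C", "D"), aa_alphabet())
  for (i in 1:3) {
    expect_equal(h$match_emission[i, idx[[i]]], 1)
    expect_equal(sum(h$match_emission[i, ]), 1)
  }
  expect_equal(h$transition[, 1L], rep(1, 3L))  # all q_i(M,M) = 1
  expect_equal(h$neff, rep(1, 3L))
})

test_that("gapless MSA has zero delete/insert opening before pseudocounts", {
  m <- msa(c("a", "b", "c"), c("ACDE", "AGDE", "ACDF"))
  h <- build_profile_hmm(m, trans_pc = 0)
  expect_equal(h$transition[1:3, 2L], rep(0, 3L))  # M->I
  expect_equal(h$transition[1:3, 3L], rep(0, 3L))  # M->D
})

test_that("profile invariants hold on random fixtures", {
  for (seed in 1:50) {
    m <- random_msa(n_seq = sample(1:15, 1L), L = sample(1:40, 1L),
                    seed = seed + 300L, gap_rate = 0.2, insert_rate = 0.1)
    h <- build_profile_hmm(m)
    expect_silent(validate_profile_hmm(h, tol = 1e-9))
  }
})

test_that("emissions are invariant to row order after weighting", {
  m <- random_msa(8L, 20L, seed = 17, gap_rate = 0.2)
  h <- build_profile_hmm(m)
  perm <- c(3L, 1L, 8L, 5L, 2L, 7L, 4L, 6L)
  mp <- msa(m$names[perm], m$rows[perm])
  hp <- build_profile_hmm(mp, name = h$name)
  expect_equal(hp$match_emission, h$match_emission, tolerance = 1e-9)
  expect_equal(hp$transition, h$transition, tolerance = 1e-9)
})

test_that("stronger pseudocount admixture moves emissions toward the prior", {
  m <- random_msa(5L, 15L, seed = 23)
  h0 <- build_profile_hmm(m, pca = 0)
  g <- h0$match_emission %*% t(blosum62_conditional())
  prev <- NULL
  for (pca in c(0, 0.25, 0.5, 0.75, 1.0)) {
    h <- build_profile_hmm(m, pca = pca)
    d <- sum(abs(h$match_emission - g))
    if (!is.null(prev)) expect_lte(d, prev + 1e-12)
    prev <- d
  }
})

test_that("degenerate MSAs are rejected", {
  m <- msa("a", "acd")  # all insertions, no match columns
  expect_error(build_profile_hmm(m), "zero match columns")
})
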