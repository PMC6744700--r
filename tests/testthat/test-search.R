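# End-to-end search: chunked early termination, planted-homolog recovery,
# database round trips, iterative search.

make_small_db <- function(n_hom = 4L, n_dec = 40L, seed = 1L, La = 40L) {
  pd <- planted_database(n_hom, n_dec,
                         family_spec(ancestor_length = La, seed = seed))
  db <- make_hmm_db(pd$records, K = 40L, seed = seed)
  list(pd = pd, db = db)
}

test_that("a chunk of hopeless E-values triggers early termination", {
  x <- make_small_db(0L, 24L, seed = 3L)
  # calibration forced so that every E-value is large
  evd <- list(lambda = 5, mu = -50)   # all scores >> mu -> p ~ 0... inverted
  evd <- list(lambda = 5, mu = 1e6)   # p ~ 1 -> E ~ n_db
  res <- chunked_search(x$pd$query, x$db, evd = evd, n_db = 24000L,
                        chunk_size = 8L)
  # every E-value ~ 24000: mean 1/(1+E) << 0.01 -> stop after chunk 1
  expect_equal(res$n_processed, 8L)
  expect_equal(nrow(res$hits), 8L)

  # all E-values ~ 0: never terminate
  evd0 <- list(lambda = 5, mu = -1e6)
  res0 <- chunked_search(x$pd$query, x$db, evd = evd0, n_db = 24L,
                         chunk_size = 8L)
  expect_equal(res0$n_processed, 24L)
})

test_that("the termination statistic follows the stated arithmetic", {
  # mean of 1/(1+E) for E = 1000 is ~0.000999 < 0.01; for E = 0 it is 1
  expect_lt(mean(1 / (1 + rep(1000, 2000))), 0.01)
  expect_equal(mean(1 / (1 + rep(0, 2000))), 1)
})

test_that("early termination preserves the processed prefix of the hit list", {
  x <- make_small_db(4L, 36L, seed = 5L)
  cal <- calibrate_evd(x$pd$query, x$db$profiles, n_decoys = 150L, seed = 2L)
  pf <- prefilter(x$pd$query, x$db$cs, x$db$alphabet, keep_fraction = 1,
                  min_prefilter_hits = 40L)
  cand <- data.frame(name = pf$name, prefilter = pf$gapped,
                     stringsAsFactors = FALSE)
  full <- chunked_search(x$pd$query, x$db, cand, cal, chunk_size = 10L,
                         early_termination = FALSE)
  part <- chunked_search(x$pd$query, x$db, cand, cal, chunk_size = 10L,
                         early_termination = TRUE)
  expect_lte(part$n_processed, full$n_processed)
  done <- part$hits$target
  sub <- full$hits[full$hits$target %in% done, ]
  expect_equal(part$hits[order(part$hits$target), ],
               sub[order(sub$target), ], ignore_attr = TRUE)
})

test_that("disabling prefilter and termination yields a superset of hits", {
  x <- make_small_db(3L, 30L, seed = 7L)
  cal <- calibrate_evd(x$pd$query, x$db$profiles, n_decoys = 150L, seed = 3L)
  res_def <- search_hmm(x$pd$query, x$db, evd = cal, realign = FALSE,
                        min_prefilter_hits = 10L, keep_fraction = 0.2)
  res_all <- search_hmm(x$pd$query, x$db, evd = cal, realign = FALSE,
                        use_prefilter = FALSE, early_termination = FALSE)
  expect_true(all(res_def$hits$target %in% res_all$hits$target))
  merged <- merge(res_def$hits, res_all$hits, by = "target")
  expect_equal(merged$score_bits.x, merged$score_bits.y, tolerance = 1e-9)
})

test_that("planted homologs rank above decoys", {
  ranks_ok <- vapply(1:3, function(seed) {
    x <- make_small_db(5L, 60L, seed = seed, La = 50L)
    res <- search_hmm(x$pd$query, x$db, seed = seed, realign = FALSE,
                      n_calibration = 200L, use_prefilter = FALSE,
                      early_termination = FALSE)
    hits <- res$hits
    is_hom <- startsWith(hits$target, "HOM")
    worst_hom <- max(which(is_hom))
    all(seq_len(worst_hom) %in% which(is_hom))
  }, NA)
  expect_true(all(ranks_ok))
})

test_that("hits are sorted by ascending E-value and E = p * N", {
  x <- make_small_db(2L, 20L, seed = 11L)
  res <- search_hmm(x$pd$query, x$db, seed = 4L, n_calibration = 150L,
                    realign = FALSE, use_prefilter = FALSE)
  expect_true(all(diff(res$hits$e_value) >= 0))
  expect_equal(res$hits$e_value, res$hits$p_value * length(x$db$profiles))
})

test_that("MAC realignment attaches alignments for significant hits", {
  x <- make_small_db(3L, 20L, seed = 13L)
  res <- search_hmm(x$pd$query, x$db, seed = 5L, n_calibration = 150L,
                    realign = TRUE, realign_e_max = 1, mact = 0.35,
                    use_prefilter = FALSE)
  sig <- res$hits$target[res$hits$e_value <= 1]
  expect_gt(length(sig), 0L)
  for (nm in sig) {
    aln <- res$alignments[[nm]]
    expect_s3_class(aln, "pair_alignment")
    expect_true(all(aln$path$state %in% c("MM", "DG", "GD")))
  }
})

test_that("hmm database round-trips through FFindex files", {
  x <- make_small_db(2L, 10L, seed = 17L)
  prefix <- file.path(tempdir(), "testdb")
  write_hmm_db(x$db, prefix)
  db2 <- read_hmm_db(prefix)
  expect_equal(names(db2$profiles), sort(names(x$db$profiles)))
  expect_equal(db2$alphabet$K, x$db$alphabet$K)
  nm <- names(x$db$profiles)[[1L]]
  expect_identical(db2$cs[[nm]], x$db$cs[[nm]])
  expect_equal(db2$profiles[[nm]]$L, x$db$profiles[[nm]]$L)
  # labels survive the makedb + search report join
  res <- search_hmm(x$pd$query, db2, seed = 1L, n_calibration = 120L,
                    realign = FALSE, use_prefilter = FALSE)
  joined <- merge(res$hits, x$pd$truth, by.x = "target", by.y = "name")
  expect_equal(nrow(joined), nrow(res$hits))
})

test_that("iterative search on a decoy-only database keeps the single query", {
  x <- make_small_db(0L, 25L, seed = 19L)
  qseq <- hmm_consensus(x$pd$query)
  res <- iterative_search("q0", qseq, x$db, n_iterations = 2L, seed = 3L,
                          n_calibration = 120L, use_prefilter = FALSE)
  expect_equal(n_sequences(res$msa), 1L)
  expect_equal(res$msa$rows[[1L]], qseq)
})

test_that("iterative search accepts only significant hits and grows diversity", {
  x <- make_small_db(5L, 30L, seed = 23L, La = 50L)
  qseq <- hmm_consensus(x$pd$query)
  res <- iterative_search("q0", qseq, x$db, n_iterations = 2L, seed = 4L,
                          n_calibration = 200L, use_prefilter = FALSE)
  acc <- unlist(res$accepted)
  if (length(acc)) {
    hits <- res$search$hits
    expect_true(all(startsWith(acc, "HOM")))
  }
  expect_true(all(diff(res$neff_trace) >= -1e-9))
  # added rows are real database members aligned to the query columns
  if (n_sequences(res$msa) > 1L) {
    expect_true(all(res$msa$names[-1L] %in% names(x$db$profiles)))
  }
})
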