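# Extreme-value (Gumbel) statistics for Viterbi scores: maximum-likelihood
# fit on decoy scores, p-values and E-values, and per-query calibration
# against column-shuffled database HMMs.

#' Maximum-likelihood Gumbel fit to decoy scores
#'
#' Fits the extreme-value distribution with survival function
#' `P(S >= s) = 1 - exp(-exp(-lambda (s - mu)))` by maximizing the
#' log-likelihood over `(lambda, mu)`, starting from the method-of-moments
#' estimate.
#'
#' @param decoy_scores Numeric vector of scores from unrelated (decoy)
#'   targets; at least 100 values recommended.
#' @param min_scores Minimum number of scores required (default 10).
#' @return List with `lambda` and `mu`.
#' @export
fit_evd <- function(decoy_scores, min_scores = 10L) {
  s <- decoy_scores[is.finite(decoy_scores)]
  if (length(s) < min_scores) {
    stop("need at least ", min_scores, " finite decoy scores")
  }
  if (sd(s) < 1e-12) stop("degenerate (constant) decoy scores")
  lambda0 <- pi / (sd(s) * sqrt(6))
  mu0 <- mean(s) - 0.57721566490153286 / lambda0
  nll <- function(par) {
    lambda <- exp(par[[1L]])
    z <- lambda * (s - par[[2L]])
    -(length(s) * log(lambda) - sum(z) - sum(exp(-z)))
  }
  fit <- optim(c(log(lambda0), mu0), nll, method = "BFGS",
               control = list(maxit = 500L))
  list(lambda = exp(fit$par[[1L]]), mu = fit$par[[2L]])
}

#' Gumbel tail probability and E-value
#'
#' @param score Score(s) in bits.
#' @param evd List with `lambda`, `mu` from [fit_evd()].
#' @param n_db Database size (number of targets) for the E-value.
#' @return `evd_pvalue`: P(S >= score); `evd_evalue`: p-value times
#'   database size.
#' @export
evd_pvalue <- function(score, evd) {
  -expm1(-exp(-evd$lambda * (score - evd$mu)))
}

#' @rdname evd_pvalue
#' @export
evd_evalue <- function(score, evd, n_db) {
  evd_pvalue(score, evd) * n_db
}

#' Sample from a Gumbel distribution
#'
#' @param n Number of draws.
#' @param lambda,mu Gumbel parameters.
#' @return Numeric vector.
#' @export
r_gumbel <- function(n, lambda, mu) {
  mu - log(-log(runif(n))) / lambda
}

# Column-shuffled copy of a profile HMM: permutes the order of match
# columns (emissions, transitions and neff together), destroying homology
# while preserving column composition.
shuffle_profile_columns <- function(h) {
  perm <- sample.int(h$L)
  profile_hmm(paste0(h$name, "_shuf"), h$match_emission[perm, , drop = FALSE],
              h$transition[perm, , drop = FALSE], h$neff[perm],
              h$background, validate = FALSE)
}

#' Calibrate the E-value distribution for one query
#'
#' Aligns the query against column-shuffled versions of database HMMs
#' (sampled with replacement) and fits a Gumbel distribution to the decoy
#' Viterbi scores.
#'
#' @param q Query [profile_hmm()].
#' @param targets List of database [profile_hmm()] objects to shuffle.
#' @param n_decoys Number of decoy alignments (default 1000).
#' @param seed Integer seed.
#' @param batch_width Lanes for the batched Viterbi.
#' @return List with `lambda`, `mu` and the decoy `scores`.
#' @export
calibrate_evd <- function(q, targets, n_decoys = 1000L, seed = 1L,
                          batch_width = 8L) {
  stopifnot(length(targets) >= 1L)
  decoys <- with_seed(derive_seed(seed, 6L), {
    idx <- sample.int(length(targets), n_decoys, replace = TRUE)
    lapply(idx, function(k) shuffle_profile_columns(targets[[k]]))
  })
  res <- viterbi_batch(q, decoys, batch_width = batch_width)
  scores <- vapply(res, `[[`, 0, "score")
  c(fit_evd(scores), list(scores = scores))
}
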