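# Forward-Backward posteriors and Maximum Accuracy (MAC) alignment.

#' Forward-Backward posterior alignment probabilities
#'
#' Log-space Forward-Backward over the same five-pair-state local model
#' as the Viterbi alignment (max replaced by log-sum-exp, the zero entry
#' option retained at every cell). The posterior probability that query
#' column i aligns to target column j in the MM pair state is
#' `2^(F_MM(i,j) + B_MM(i,j) - log Z)`.
#'
#' @param q,t Query and target [profile_hmm()] objects.
#' @param corrected See [viterbi_scalar()].
#' @return Object of class `posterior_matrix`: list with `log_post`
#'   (`L_q x L_t` matrix of log2 posteriors), `log_total` (log2 of the
#'   partition function Z, bits, from the Forward pass) and
#'   `log_total_backward` (same from the Backward pass).
#' @export
forward_backward <- function(q, t, corrected = TRUE) {
  qa <- .hmm_arrays(q)
  ta <- .hmm_arrays(t)
  r <- .forward_backward_cpp(qa$emf, qa$ltr, ta$em, ta$ltr, corrected)
  structure(list(log_post = r$log_post,
                 log_total = r$log_total_f,
                 log_total_backward = r$log_total_b,
                 query = q$name, target = t$name),
            class = "posterior_matrix")
}

#' @export
print.posterior_matrix <- function(x, ...) {
  cat(sprintf("Posterior matrix %s vs %s: %d x %d, log2 Z = %.3f bits\n",
              x$query, x$target, nrow(x$log_post), ncol(x$log_post),
              x$log_total))
  invisible(x)
}

#' Extract linear posterior probabilities
#' @param post A `posterior_matrix` or a numeric matrix of probabilities.
#' @return `L_q x L_t` matrix of probabilities in `[0, 1]`.
#' @export
posterior_probs <- function(post) {
  if (inherits(post, "posterior_matrix")) {
    p <- 2^post$log_post
    p[p > 1] <- 1
    return(p)
  }
  as.matrix(post)
}

#' Maximum Accuracy (MAC) alignment
#'
#' Local dynamic program maximizing the expected number of correctly
#' aligned column pairs minus the per-pair penalty `mact`: the sum over
#' aligned pairs of `P(i,j) - mact`, with gap moves carrying zero gain
#' and an empty alignment allowed. `mact` near 0 gives long, nearly
#' global alignments; larger values give shorter, local ones.
#'
#' @param post A `posterior_matrix` from [forward_backward()], or a
#'   numeric matrix of per-pair posterior probabilities.
#' @param mact Per-pair penalty in `[0, 1]` (default 0.35).
#' @param q_name,t_name Optional identifiers.
#' @return A `pair_alignment`; `score` is the expected-accuracy objective.
#'   Gap moves appear in the path as DG (query advances) / GD (target
#'   advances) steps; the path starts and ends with an aligned (MM) pair.
#' @export
mac_align <- function(post, mact = 0.35, q_name = NULL, t_name = NULL) {
  stopifnot(mact >= 0, mact <= 1)
  if (is.null(q_name)) {
    q_name <- if (inherits(post, "posterior_matrix")) post$query else "query"
  }
  if (is.null(t_name)) {
    t_name <- if (inherits(post, "posterior_matrix")) post$target else "target"
  }
  p <- posterior_probs(post)
  r <- .mac_cpp(p, mact)
  path <- r$path
  states <- names(pair_state_codes())
  df <- data.frame(i = as.integer(path[, 1L]), j = as.integer(path[, 2L]),
                   state = states[match(path[, 3L], pair_state_codes())],
                   stringsAsFactors = FALSE)
  .as_pair_alignment(df, r$score, q_name, t_name)
}
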