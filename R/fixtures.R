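# Deterministic synthetic-data generators: random profile HMMs, random
# MSAs, homologous HMM pairs with known true alignments, and planted
# databases with decoys. Every generator is a pure function of its seed.

#' Derive a stream seed from a master seed
#'
#' One global RNG protocol: every generator derives its own stream from
#' `(seed, stream id)` so that independent draws never share state and
#' any fixture can be cited as "seed s, stream k". Derived seeds stay
#' below 2^31.
#'
#' @param seed Master integer seed.
#' @param stream Integer stream identifier.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stream = 0L) {
  as.integer((as.numeric(seed) %% 2147483629 * 7919 + stream * 104729) %%
               2147483629)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, keeping generators pure
#' functions of their seeds.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Dirichlet draw via normalized gammas; tiny floor keeps rows normalizable
# when the concentration is very small (near-delta columns).
.rdirichlet_rows <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  x <- x + 1e-300
  x / rowSums(x)
}

.random_transitions <- function(L) {
  m <- .rdirichlet_rows(L, c(18, 1, 1))
  i <- .rdirichlet_rows(L, c(6, 4))
  d <- .rdirichlet_rows(L, c(6, 4))
  cbind(m, i, d)
}

#' Random profile HMM
#'
#' Emission columns are symmetric Dirichlet draws with concentration
#' `conservation` (smaller values give peakier, more conserved columns);
#' transitions are Dirichlet draws centered on match-heavy values.
#' Deterministic per seed.
#'
#' @param L Number of match columns (>= 1).
#' @param seed Integer seed.
#' @param conservation Dirichlet concentration of emission columns
#'   (default 0.3).
#' @param name Profile name.
#' @param maxres Maximum length.
#' @return A [profile_hmm()].
#' @export
random_profile_hmm <- function(L, seed, conservation = 0.3,
                               name = sprintf("rand_L%d_s%d", L, seed),
                               maxres = 15000L) {
  stopifnot(L >= 1L)
  if (L > maxres) stop("L exceeds maxres = ", maxres)
  with_seed(derive_seed(seed, 1L), {
    em <- .rdirichlet_rows(L, rep(conservation, 20L))
    tr <- .random_transitions(L)
    neff <- 1 + rgamma(L, shape = 2, rate = 1)
    profile_hmm(name, em, tr, neff)
  })
}

#' Random MSA in A3M convention
#'
#' Rows are sampled from a random column profile; the first row is the
#' gapless query. Later rows carry gaps at rate `gap_rate` and short
#' lowercase insertions at rate `insert_rate`.
#'
#' @param n_seq,L Numbers of sequences and match columns.
#' @param seed Integer seed.
#' @param gap_rate,insert_rate Per-position event rates.
#' @param conservation Dirichlet concentration of the generating columns.
#' @return An [msa()].
#' @export
random_msa <- function(n_seq, L, seed, gap_rate = 0.1, insert_rate = 0.05,
                       conservation = 0.2) {
  stopifnot(n_seq >= 1L, L >= 1L)
  aa <- aa_alphabet()
  with_seed(derive_seed(seed, 2L), {
    cols <- .rdirichlet_rows(L, rep(conservation, 20L))
    rows <- vapply(seq_len(n_seq), function(n) {
      ch <- vapply(seq_len(L), function(i) sample(aa, 1L, prob = cols[i, ]), "")
      if (n > 1L) {
        gap <- runif(L) < gap_rate
        ch[gap] <- "-"
        ins <- which(runif(L) < insert_rate)
        for (k in ins) {
          len <- sample(1:3, 1L)
          ch[[k]] <- paste0(ch[[k]], paste(tolower(sample(aa, len,
                                                          replace = TRUE)),
                                           collapse = ""))
        }
      }
      paste(ch, collapse = "")
    }, "")
    msa(sprintf("seq%03d", seq_len(n_seq)), rows)
  })
}

#' Family specification for homologous fixtures
#'
#' @param ancestor_length Number of ancestral columns.
#' @param conservation Dirichlet concentration of ancestral columns
#'   (smaller = more conserved).
#' @param indel_rate Per-column probability of a deletion / insertion
#'   event in each descendant.
#' @param precision Concentration of the per-column resampling of
#'   descendants around the ancestral column (larger = closer).
#' @param n_members Number of descendant HMMs.
#' @param seed Integer seed; the spec is fully determined by it.
#' @return A `family_spec` list.
#' @export
family_spec <- function(ancestor_length = 60L, conservation = 0.1,
                        indel_rate = 0.05, precision = 100,
                        n_members = 2L, seed = 1L) {
  stopifnot(ancestor_length >= 1L, indel_rate >= 0, indel_rate <= 1,
            n_members >= 1L)
  structure(list(ancestor_length = as.integer(ancestor_length),
                 conservation = conservation, indel_rate = indel_rate,
                 precision = precision, n_members = as.integer(n_members),
                 seed = as.integer(seed)),
            class = "family_spec")
}

# Sample one descendant of the ancestral column set. Returns the HMM and
# the map from surviving ancestral column -> descendant column.
.sample_descendant <- function(anc, spec, name) {
  La <- nrow(anc)
  deleted <- runif(La) < spec$indel_rate
  if (all(deleted)) deleted[sample(La, 1L)] <- FALSE
  cols <- list()
  map <- rep(NA_integer_, La)
  for (i in seq_len(La)) {
    if (runif(1L) < spec$indel_rate) {
      cols[[length(cols) + 1L]] <- .rdirichlet_rows(1L, rep(0.5, 20L))[1L, ]
    }
    if (!deleted[[i]]) {
      child <- rgamma(20L, shape = anc[i, ] * spec$precision + 1e-4) + 1e-300
      cols[[length(cols) + 1L]] <- child / sum(child)
      map[[i]] <- length(cols)
    }
  }
  em <- do.call(rbind, cols)
  L <- nrow(em)
  hmm <- profile_hmm(name, em, .random_transitions(L),
                     1 + rgamma(L, shape = 2, rate = 1))
  list(hmm = hmm, map = map)
}

#' Homologous profile HMM pair with known true alignment
#'
#' Two HMMs derived from one sampled ancestor by per-column Dirichlet
#' resampling plus seeded deletion and insertion events. The true
#' alignment pairs the descendant columns of ancestral columns surviving
#' in both.
#'
#' @param spec A [family_spec()].
#' @return List with `hmm1`, `hmm2`, `true_alignment` (data frame `i`,
#'   `j`) and `ancestor` (matrix of ancestral columns).
#' @export
homologous_pair <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(derive_seed(spec$seed, 3L), {
    anc <- .rdirichlet_rows(spec$ancestor_length, rep(spec$conservation, 20L))
    d1 <- .sample_descendant(anc, spec, "member1")
    d2 <- .sample_descendant(anc, spec, "member2")
    both <- !is.na(d1$map) & !is.na(d2$map)
    list(hmm1 = d1$hmm, hmm2 = d2$hmm,
         true_alignment = data.frame(i = d1$map[both], j = d2$map[both]),
         ancestor = anc)
  })
}

#' Family of homologous profile HMMs
#'
#' @param spec A [family_spec()]; `n_members` descendants are drawn.
#' @return List with `members` (list of HMMs), `maps` (list of
#'   ancestor-to-member column maps) and `ancestor`.
#' @export
homologous_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(derive_seed(spec$seed, 4L), {
    anc <- .rdirichlet_rows(spec$ancestor_length, rep(spec$conservation, 20L))
    ds <- lapply(seq_len(spec$n_members), function(k) {
      .sample_descendant(anc, spec, sprintf("member%03d", k))
    })
    list(members = lapply(ds, `[[`, "hmm"),
         maps = lapply(ds, `[[`, "map"),
         ancestor = anc)
  })
}

#' Planted-homolog database with decoys
#'
#' A query HMM plus `n_homologs` members of the same synthetic family and
#' `n_decoys` unrelated random HMMs, with a truth table of labels.
#'
#' @param n_homologs,n_decoys Record counts (>= 0).
#' @param spec A [family_spec()] for the planted family.
#' @param seed Integer seed for the decoys (the family uses `spec$seed`).
#' @param decoy_length_range Range of decoy lengths (default: ancestor
#'   length +/- 20%).
#' @return List with `query` (a [profile_hmm()]), `records` (named list
#'   of target HMMs) and `truth` (data frame `name`, `is_homolog`).
#' @export
planted_database <- function(n_homologs, n_decoys, spec, seed = spec$seed,
                             decoy_length_range = NULL) {
  stopifnot(n_homologs >= 0L, n_decoys >= 0L)
  fam_spec <- family_spec(spec$ancestor_length, spec$conservation,
                          spec$indel_rate, spec$precision,
                          n_members = n_homologs + 1L, seed = spec$seed)
  fam <- homologous_family(fam_spec)
  query <- fam$members[[1L]]
  query$name <- "query"
  records <- list()
  if (n_homologs > 0L) {
    homs <- fam$members[-1L]
    names(homs) <- sprintf("HOM%04d", seq_len(n_homologs))
    for (k in seq_along(homs)) homs[[k]]$name <- names(homs)[[k]]
    records <- homs
  }
  if (n_decoys > 0L) {
    if (is.null(decoy_length_range)) {
      La <- spec$ancestor_length
      decoy_length_range <- c(max(5L, round(0.8 * La)), round(1.2 * La))
    }
    lens <- with_seed(derive_seed(seed, 5L), {
      sample(decoy_length_range[[1L]]:decoy_length_range[[2L]], n_decoys,
             replace = TRUE)
    })
    decoys <- lapply(seq_len(n_decoys), function(k) {
      h <- random_profile_hmm(lens[[k]], derive_seed(seed, 100L + k),
                              conservation = 0.3,
                              name = sprintf("DEC%04d", k))
      h
    })
    names(decoys) <- vapply(decoys, function(h) h$name, "")
    records <- c(records, decoys)
  }
  truth <- data.frame(name = names(records),
                      is_homolog = startsWith(names(records), "HOM"),
                      stringsAsFactors = FALSE)
  list(query = query, records = records, truth = truth)
}

#' Consensus sequence of a profile HMM
#'
#' The most probable residue of each match column.
#'
#' @param h A [profile_hmm()].
#' @return Character string of length `h$L`.
#' @export
hmm_consensus <- function(h) {
  aa <- aa_alphabet()
  paste(aa[max.col(h$match_emission, ties.method = "first")], collapse = "")
}
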