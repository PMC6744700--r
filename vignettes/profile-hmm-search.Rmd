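---
title: "Profile HMM-HMM alignment and homology search with hmmpair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile HMM-HMM alignment and homology search with hmmpair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmmpair)
```

## The model

Remote protein homology is most reliably detected by comparing *profiles*
of related sequences rather than single sequences. A profile hidden Markov
model (HMM) summarizes a multiple sequence alignment (MSA) by one match
state per retained alignment column. A match state M emits amino acids
with column-specific probabilities estimated from the (weighted) residue
frequencies of that column; insert states I emit from the background
distribution $f_a$; delete states D are silent. Position-specific
transition probabilities $q_i(X,Y)$ between M, I and D replace the uniform
gap penalties of plain sequence alignment.

`hmmpair` aligns two profile HMMs $q$ (length $L_q$) and $t$ (length
$L_t$) by a local Viterbi dynamic program over *pair states*: the joint
state of the two models in one alignment column. Because M and I states
emit and D states do not, only five pair states are needed once the
uninformative II and DD combinations are excluded: MM, MI, IM, DG and GD.
MM advances both models, MI and DG advance only the query, IM and GD only
the target. Allowed transitions are within a pair state and between MM
and each of the four others.

The emission term of an MM cell is the column similarity score

$$S_{aa}(q_i, t_j) \;=\; \log_2 \sum_{a=1}^{20}
  \frac{q_i(a)\, t_j(a)}{f_a},$$

the log-odds of the two columns co-emitting a residue relative to the
background. It is zero when both columns equal the background, positive
for similar informative columns, and symmetric in $q$ and $t$. Pair-state
moves contribute the logarithms of the corresponding transition
probabilities; a zero option at every cell makes the alignment local, so
the reported score is always non-negative. All scores are in bits.

Two of the recursion's transition factors are implemented as the
pair-state semantics require — the MI entry uses the target's
insert-opening probability $t_j(M,I)$ and the DG entry the query's
delete-opening probability $q_{i-1}(M,D)$ — and the third diagonal
predecessor of MM is the IM state. A debug flag (`corrected = FALSE`)
selects the alternative factor set ($t_j(D,D)$, $q_{i-1}(D,M)$) so that
both variants can be compared; the corrected set is the default and the
one all tests pin down, via an exhaustive path-enumeration oracle that is
independent of the DP.

## Batched alignment and the memory layout

The production path aligns one query against batches of `batch_width`
targets (default 8) simultaneously. Targets are sorted by decreasing
length within a batch and padded with zero emission probabilities up to
the longest member; emission and transition values of the batch are laid
out lane-interleaved so one "column" of values for all lanes is
contiguous. Each DP cell is processed for all lanes with branch-free
compare-select updates: the six-way MM maximization is a sequence of five
strictly-greater compare-selects (comparison order STOP, MM, IM, MI, GD,
DG, so the earliest state wins ties) and the four two-way maximizations
keep the same-state extension on ties. Padded columns carry the score
sentinel −100000 bits so they can never win a maximization, and a lane
validity mask is consulted before a cell may become a lane's best score.
The scalar and batched kernels are verified against each other
cell-for-cell: identical backtrace bytes, not just equal scores.

Memory follows the two standard reductions. The five score matrices are
kept as single rows: one vector per pair state holds the current row up
to column $j-1$ and the previous row from $j$ on, turning
$O(L_q L_t)$ score storage into $O(L_t)$ (a full-matrix reference
implementation is kept in the test suite as the oracle). The backtrace
needs one byte per cell: bits 0–2 encode the MM predecessor (STOP, MM,
IM, MI, GD, DG — STOP marks the local start), bits 3–6 hold one flag per
GD/IM/DG/MI state (1 = predecessor is the same state, 0 = MM), and the
most significant bit is the cell-off flag. Profile length is capped at
`maxres = 15000` columns by default.

Suboptimal alignments exclude, for alignment $k+1$, every cell within
Chebyshev distance `exclusion_radius = 40` of any cell on alignments
$1..k$ by setting the cell-off bit; the first alignment runs the plain
code path, later ones the cell-off path. The Chebyshev (square)
neighborhood is a design choice — the radius is configurable.

## Posteriors and Maximum Accuracy alignment

`forward_backward()` replaces the Viterbi maximization with log-sum-exp
over the same pair-state model, keeping the local zero-entry option at
every cell symmetrically with the Viterbi recursion (a design decision:
the partition function then sums over exactly the same path set the
Viterbi maximizes over, which the tests exploit by comparing both against
one path enumeration). The posterior that query column $i$ aligns to
target column $j$ is $2^{F_{MM}(i,j) + B_{MM}(i,j) - \log_2 Z}$; the
matrix is stored as logarithms. Row and column sums of the posterior
matrix cannot exceed 1 because each path aligns $i$ to at most one $j$.

`mac_align()` maximizes the expected number of correctly aligned pairs
minus a penalty: the sum over aligned pairs of $P(i,j) - \texttt{mact}$,
by a local three-move DP in which gap moves carry zero gain (the penalty
applies only to aligned pairs). `mact` trades alignment greed against
precision: near 0 the alignment is long and nearly global, above 0.3 it
becomes short and local; the default is 0.35. Ties are broken in the
fixed order stop, diagonal, up, left with strictly-greater updates, so
the decoded path always starts and ends on an aligned pair. In the search
pipeline, hits that reach significance are realigned with MAC and
reported with their Viterbi E-value.

## From MSA to profile

* **Match columns.** Columns with a gap fraction below 0.5 (default)
  become match states, the rest insertions. The fraction is unweighted; a
  weighted variant would require weights before the columns exist, and
  the choice is configurable.
* **Redundancy filter.** Pairwise identity is the number of identical
  non-gap residues divided by the smaller non-gap count of the two
  sequences (symmetric, robust to fragments). The greedy filter keeps the
  first sequence (the query) and scans the rest in input order,
  discarding anything above `seqid_max = 0.9` identity to a kept
  sequence; it is deterministic and idempotent, and is checked verbatim
  against a naive double-loop reference.
* **Weights.** For each match column $i$, position-based
  (Henikoff-style) weights are computed on the subalignment of sequences
  without a gap in $i$ — each column contributes $1/(r \cdot n_{x})$ to a
  sequence carrying residue $x$, where $r$ is the number of residue types
  in the column and $n_x$ the multiplicity. Columns where every sequence
  has a gap fall back to uniform weights and are flagged. This is the
  $O(NL)$-per-column scheme; transition counts use the global weights.
* **Pseudocounts.** Emissions mix observed frequencies with
  substitution-matrix pseudocounts
  $g_i(a) = \sum_b g(a\,|\,b)\, f_{obs,i}(b)$, where $g(a|b)$ is derived
  from the BLOSUM62 score matrix by inverting its log-odds construction
  against the Robinson–Robinson background. The admixture is
  diversity-dependent, $\tau_i = \min(1,\ pca/(1 + n_{eff,i}/pcb))$ with
  defaults $pca = 1.0$, $pcb = 1.5$; per-column diversity $n_{eff,i}$ is
  the exponential of the Shannon entropy of the weighted residue
  frequencies. Transition pseudocounts are fixed additive counts
  (M: 0.6/0.2/0.2, I: 0.5/0.5, D: 0.5/0.5, scalable via `trans_pc`).
  Context-specific pseudocounts are out of scope.

## Search pipeline

A database search runs four stages:

1. **Prefilter.** Target profiles are discretized into sequences over a
   column-state alphabet of K = 219 archetypical profile columns obtained
   by k-means on square-root-transformed emission rows (Euclidean
   distance on $\sqrt{p}$ approximates the Hellinger distance between
   distributions). Stage 1 scores the query profile against each
   column-state sequence by the best ungapped diagonal segment; stage 2
   rescored survivors with affine-gap Smith–Waterman (open 5 bits, extend
   1 bit) on the same per-cell scores. Each stage keeps the top 5% with
   an absolute floor of `min_prefilter_hits = 100`; retention-based
   thresholds were chosen because only the removal behavior, not absolute
   cutoffs, is specified for this architecture.
2. **E-values.** The Viterbi score null distribution is calibrated per
   query by aligning against column-shuffled versions of database HMMs
   (1000 by default, seeded) and fitting a Gumbel distribution by maximum
   likelihood; $P(S \ge s) = 1 - \exp(-e^{-\lambda (s - \mu)})$ and
   E-value = p-value × database size. This self-contained calibration is
   a substitute for the original tool's published E-value machinery, not
   a reproduction of it; since it is per query, no separate
   length-bucket refit is needed.
3. **Chunked Viterbi with early termination.** Candidates are sorted by
   decreasing prefilter score, split into chunks (default 2000), each
   chunk re-sorted by decreasing length for the batched kernel. After a
   chunk, the mean of $1/(1+E)$ over the chunk is computed and the search
   stops when it falls below 0.01 — a chunk whose E-values all exceed
   ~100 contributes essentially nothing. The per-chunk statistic (rather
   than a 200-alignment running average) is the default.
4. **MAC realignment** of hits with E-value at most `realign_e_max`
   (default 10), reported with the Viterbi E-value.

Iterative search (`iterative_search()`, CLI `blits`) starts from a single
sequence, builds a single-row profile, searches, and merges the
MAC-aligned consensus sequences of hits with E ≤ 10⁻³ into the query MSA
— aligned target columns land in query match columns, skipped target
columns become lowercase insertions — then refilters redundancy and
rebuilds the profile. Profile diversity (mean Neff) grows monotonically
on planted-family fixtures.

Multi-query runs parallelize over queries with a process pool
(`-cpu`); every query derives its own seed from the master seed, so
reports are byte-identical regardless of worker count.

## Synthetic data: what it emulates and what it does not

The generators produce all test inputs. `random_profile_hmm()` draws
emission columns from a symmetric Dirichlet whose concentration tunes
column conservation and match-heavy Dirichlet transitions.
`homologous_pair()`/`homologous_family()` sample an ancestor column set
and derive members by per-column Dirichlet resampling (concentration
`precision = 100` around the ancestral column) with seeded deletion and
insertion events at `indel_rate = 0.05` per column, recording the true
column correspondence. `planted_database()` combines 20 family members
with 500 unrelated decoys of comparable length (defaults used by the
recovery analyses; ancestor length 100, conservation 0.1 — values chosen
as realistic for a conserved domain family of moderate length).

These fixtures capture per-column composition, diversity and indel
structure, but not phylogenetic correlation between database entries,
repeat/coiled-coil composition biases, length extremes, or alignment
errors in real MSAs. Passing the recovery tests therefore demonstrates
correctness of the machinery and sensible behavior under the generative
model — not benchmark sensitivity on real protein families.

## Numerical choices

* All DP scores in bits (log2); probability zero maps to the finite
  sentinel −100000 bits in Viterbi kernels and −10³⁰ in Forward–Backward
  (where magnitudes add across log-sum-exp chains).
* Tie-breaking is fully specified (see above) so scalar, batched and
  full-matrix paths agree byte-for-byte.
* The profile text dialect stores every probability as
  `round(-1000 * log2 p)` with sentinel 99999 for zero: integers
  round-trip exactly, recovered probabilities are accurate to ~0.07%
  relative, and a re-read profile re-serializes identically.
* Gumbel fitting optimizes over $(\log \lambda, \mu)$ from the
  method-of-moments start; constant score vectors are rejected.
* k-means initialization samples K distinct column vectors under the
  given seed; if exactly K distinct columns exist they are used directly,
  making the degenerate case exact.
* Problem sizes in tests and in `scripts/acceptance.R` (e.g. 200
  enumeration pairs at $L \le 4$, 10 planted-database replicates of
  20 + 500 targets at ancestor length 100, 2000-decoy calibrations) were
  chosen so the full analysis reruns in a few minutes on one core while
  keeping the statistics stable.

## Known limitations

* No secondary-structure scoring: the $S_{ss}$ term is compiled out; an
  additive per-cell hook (`ss =`) accepts an external score matrix.
* No context-specific pseudocounts; the substitution-matrix fallback is
  simpler and slightly less sensitive at fold level.
* The E-value calibration is internal and per query; absolute E-values
  are not comparable with other tools' reports.
* The prefilter stage 2 operates on the discretized column-state
  sequence (profile-to-sequence alignment), not on the full target
  profile.
* The file dialects are self-describing but deliberately not byte
  compatible with other tools' profile or MSA database formats.
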