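---
title: "Aligning fragmentary sequences with a merged ensemble of profile HMMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning fragmentary sequences with a merged ensemble of profile HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Datasets with strong sequence length heterogeneity — short reads, partial
genes, sequences truncated by large deletions — are poorly served by
standard multiple sequence aligners. A robust alternative is the two-stage
approach: align only the full-length sequences (the *backbone*), then place
each remaining *query* sequence into that fixed backbone. `ehmmalign`
implements the placement stage. The backbone alignment and its tree are
inputs; estimating them is a job for dedicated aligners and tree builders
and is deliberately out of scope.

## The model

A single profile HMM built on the whole backbone blurs distinct
subfamilies: a query that resembles one clade is scored against the average
of all of them. The remedy is an *ensemble* of profile HMMs on subsets of
the backbone, obtained by repeatedly deleting *centroid edges* of the
backbone tree (the edge whose removal splits the leaves most evenly,
`find_centroid_edge()`), until every subset has at most `max_subset_size`
sequences (default 50, a runtime/accuracy compromise). Three ensembles are
supported (`select_ensemble()`): the pairwise-disjoint minimal subsets
(`"disjoint"`, the default), those plus the full backbone
(`"disjoint+bb"`), and the entire hierarchical family of subsets recorded
during the decomposition (`"upp"`).

Each subset induces a sub-alignment of the backbone (all columns retained,
so local columns keep backbone coordinates), and a profile HMM is built on
it (`build_profile_hmm()`):

* a column is a **match column** iff its fraction of non-gap letters in the
  subset is at least `symfrac` (default 0.5, the customary occupancy
  threshold of profile HMM builders);
* per-sequence state paths are read directly off the sub-alignment, and
  transition probabilities are pseudocount-smoothed path counts (default
  0.1 per allowed edge) normalized over each state's allowed edges; the
  topology allows all nine M/I/D to M/I/D moves, since counted paths can
  contain for instance delete-to-insert steps;
* match emissions are letter counts with additive smoothing (default 1.0);
  insert emissions are the uniform background; ambiguity codes (N and
  friends) add no counts and emit the background at scoring time.

Because a subset can be entirely gapped across a stretch of backbone
columns, its HMM simply has no match states there — and therefore contains
a transition that *skips* those columns.

### The merged HMM

The method's core is to fuse the ensemble, per query, into one **merged
HMM** over backbone coordinates. Every ensemble state maps to the merged
state at its backbone column (match and delete states to their column,
insert states to their anchor column, with anchor 0 before the first
column). The merged topology (`build_merged_topology()`) is the exact union
of the mapped per-HMM edge sets — including the column-skipping edges, so
it is not a standard profile HMM. We use the union of the ensembles' match
states rather than only the backbone HMM's: the default disjoint ensemble
need not contain the backbone HMM at all, and the union is the only choice
that is well defined for every ensemble mode.

For a given query, each HMM `i` receives an adjusted-bitscore weight
(`compute_adjusted_weights()`):

$$w_i = \frac{2^{b_i}\, s_i}{\sum_j 2^{b_j}\, s_j}$$

where `b_i` is the HMM's bit score for the query and the prior is
proportional to the subset size `s_i` — a posterior-style estimate of the
probability that HMM `i` generated the query, valid when the subsets
partition the backbone. For the hierarchical `"upp"` ensemble the same
formula is applied with each subset's own size; since the correct prior for
nested subsets is genuinely unclear, `weight_prior = "uniform"` switches
the size factor off. The computation is done in the log2 domain and is
stable at arbitrary score magnitudes.

Merged numeric parameters (`parameterize_merged()`) are weighted sums:
every edge's raw value is $\sum_i w_i t_i(\text{edge})$ over the HMMs
supporting that edge, and likewise for match/insert emissions over the HMMs
having that state; weights are used as-is (no re-normalization over
supporters), and each state's outgoing distribution and each emission
distribution is then renormalized to sum to one. Insert emissions are
merged by the same rule as match emissions — the least surprising
completion, given that all component insert emissions are the background
anyway.

### Glocal alignment

Viterbi through this model is global: a 30-letter fragment of a 1000-column
backbone would pay for hundreds of delete transitions. To align the whole
query to a *contiguous region* of the backbone (`add_glocal()`), entry
edges from Start to every match state and exit edges from every match and
delete state to End are added, then all outgoing distributions are
renormalized. The total pre-normalization entry mass is `entry_total = 0.1`
divided equally over the `S` match states, and the exit mass is a constant
`pexit = 0.1` per state. We read the entry constant as *total* mass 0.1
(0.1/S per edge): the per-edge alternative 0.1·S exceeds 1 whenever S > 10,
and equal entry/exit edges are the stated intent. Mass added to an edge
that already exists (e.g. Start to the first match state) accumulates
before the renormalization.

`align_query()` runs Viterbi over the glocal merged HMM and reads the
optimal path off as placements: match states place query letters into
backbone columns; insert states place letters between columns.

### Bit scores for the weighting

The exported `bit_score()` is the classical global log-odds score,
`(forward − null)/ln 2`, against an i.i.d. uniform background with a
geometric length correction (extension probability `n/(n+1)` at query
length `n`); only score *differences* matter for the weights, so the
background is kept uniform. However, `predict()` deliberately scores each
ensemble HMM through its **glocal view** — the HMM with the same entry/exit
edges the merged model uses (`glocal_bit_score()`). With plain global
scores, a fragment's score against every HMM is dominated by the delete
chain through the columns the fragment does not cover, so larger subsets
(more match states) lose regardless of fit; in development this misranked
the ensemble for about a fifth of fragments and multiplied the placement
error several-fold. The glocal score asks the right question — how well
does the best region of this model explain the whole fragment — and the
ranking it induces is what the weighting needs.

### Transitivity merge

After all queries are aligned, `merge_extended()` assembles the final MSA.
Backbone columns are preserved in order; each query's run of inserted
letters becomes a block of fresh columns right after its anchor column.
Insertion letters are written in lowercase and are never placed in a shared
column: they are not homologous to anything, and any layout that keeps them
unshared is equivalent under sum-of-pairs scoring. Blocks of different
queries at the same anchor are ordered by query input order.

## Scoring

`sp_error()` computes sum-of-pairs false negative and false positive rates
over pairwise homologies: two *uppercase* letters in the same column,
identified by (sequence, residue index). SPFN is the fraction of reference
homologies missing from the estimate; SPFP the fraction of estimated
homologies absent from the reference; the average of the two is the usual
summary. Lowercase (insertion) letters generate no pairs. In *query-only*
mode each counted pair must touch at least one query — the right comparison
when methods share a backbone. When one side has no homologies at all the
corresponding rate is defined as 0. The two rates are dual:
`spfn(est, ref) == spfp(ref, est)`, which the tests exploit.

## Synthetic data

`simulate_true_msa()` evolves a uniform random DNA sequence down a random
bifurcating tree with per-branch per-site substitutions, and geometric
indels (insertion/deletion each at half the indel rate). Every site carries
a permanent identity, so the emitted alignment *is* the truth about
homology, with inserted sites spliced next to their anchors in a global
column order. `make_fragments()` implements the fragmentation protocol:
draw a target length from Normal(mean, sd) — by convention mean 25% of the
median input length with sd 60 for the high-fragmentary condition, half
that mean for the ultra-high-fragmentary one — round, clamp to
`[1, length]` (the protocol leaves out-of-range draws unspecified; clamping
is the documented choice here), and cut a uniformly positioned substring.

The simulator is intentionally plain: uniform substitutions, no rate
variation across sites, no selection, geometric indel lengths. Passing
placement tests on it shows the machinery recovers structure a profile HMM
can represent; it says nothing about biological realism, secondary
structure constraints, or the difficulty of real rRNA datasets.

## Numerical choices

All dynamic programming is in natural-log space; normalizations use
log-sum-exp where sums of probabilities are needed. Viterbi ties are broken
deterministically: match over delete over insert predecessors, then lower
backbone column. Every ordering that could depend on the session locale
(centroid tie-breaks between equally balanced edges, predecessor ordering,
homology pair canonicalization) uses C-locale byte order, so results are
identical across locales. Probability invariants (outgoing and emission
distributions summing to 1) are enforced to 1e-9 in the tests.

Degenerate inputs are handled explicitly: a subset with no match column at
the chosen `symfrac` is an error; single-sequence subsets are allowed with
a warning (their HMMs are point-mass but well defined); an empty query set
returns the backbone with a warning; RNA input (U) is mapped to T
internally and restored on output.

## Problem sizes in the test suite

The suite verifies the dynamic programming against exhaustive path
enumeration on models with up to 4 match states and queries up to length 4
(a seeded battery of over 100 parameterizations), checks centroid
decomposition exhaustively on trees of up to 12 leaves, and runs the
end-to-end placement study on a 20-taxon backbone of about 120 ancestral
sites with 10 fragments at 25% of the median length — sizes chosen so the
whole suite runs in well under a minute per file while still exercising
multi-subset ensembles, skip edges, and glocal entry/exit behaviour. The
regression threshold for the end-to-end fixture (query-only average error
at most 0.12) was pinned from the first verified run of the final
implementation (0.089) and is frozen.

## Limitations

* Parity with HMMER's `hmmbuild`/`hmmsearch` is not attempted: priors are
  simple additive pseudocounts, the null model is uniform, and no E-values
  are computed.
* The merged HMM is rebuilt per query; for large backbones this is
  memory-hungry (the union topology carries every ensemble edge), which is
  inherent to the method.
* Backbone alignment and tree estimation are inputs, not outputs: garbage
  backbones yield garbage placements.
* Posterior-decoding alignment and consensus-of-extended-alignments
  strategies are intentionally not implemented.
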