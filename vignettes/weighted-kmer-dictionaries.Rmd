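---
title: "Run-length weighted k-mer dictionaries: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Run-length weighted k-mer dictionaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wkdict)
```

## The problem

k-mer counting tools emit tables mapping every distinct k-mer of a DNA
database to its abundance count (weight). These tables are large — tens
of bits per k-mer — yet downstream tools often need only two operations:
*is this k-mer present?* and *if so, what is its count?* `wkdict`
answers both from a compressed representation in which the weights cost
a small fraction of a bit per k-mer on realistic inputs, while keeping
membership exact: a k-mer that was never indexed returns code 0, never a
fabricated count. That exactness is what separates a *dictionary* from a
minimal perfect hash or a compressed static function, which cannot
reject out-of-set keys.

## Model and assumptions

The indexed object is a weighted spectrum-preserving string set (SPSS):
strings over {A,C,G,T} in which each k-mer of the underlying set occurs
exactly once, counting a k-mer and its reverse complement as the same
object (the canonical form used throughout is the lexicographic minimum
of the two orientations). Producing the SPSS itself (e.g. with
BCALM2 + UST) is upstream of this package; `wkdict` consumes it, one
weight per k-mer, through the `ab:Z:` or plain-counts FASTA dialects.

Assumptions the code enforces rather than trusts:

* every weight is a positive integer and every record carries exactly
  `nchar(seq) - k + 1` of them;
* canonical k-mers are globally distinct (violations are an error; a
  flag downgrades them to a warning on read, but an index can never be
  built over duplicates, as the weight-per-k-mer alignment would be
  ambiguous);
* the alphabet is uppercase ACGT only. Lowercase and IUPAC ambiguity
  codes are rejected, not normalised — for SPSS input they indicate a
  malformed file, and silent upcasing could mask duplicated content.

## The representation

Scanning strings in order assigns consecutive hash codes to consecutive
k-mers, so the weight sequence `W[1..n]` decomposes into `r` maximal
runs. The encoding stores the sorted distinct run values `D`, one
`ceiling(log2(|D|))`-bit code per run, and the Elias-Fano-coded prefix
sums `L` of the run lengths. A weight lookup is a predecessor query on
`L` followed by a table access.

Numerical/accounting choices:

* `D` entries are stored in `max(1, ceiling(log2(max + 1)))` bits; the
  common `ceiling(log2(max))` accounting under-counts by one bit exactly
  when the largest weight is a power of two, so `space_bits()` reports
  both.
* `code_width` may be 0 when `|D| = 1`; lookups short-circuit.
* Elias-Fano uses `low_width = max(0, floor(log2(universe / r)))`, the
  standard choice, giving a payload of at most
  `r*ceiling(log2(universe/r)) + 2r + O(1)` bits; the test suite asserts
  this bound with a declared constant slack of 64 bits rather than
  chasing the exact `o(r)` term. Predecessor search is a binary search
  over `access` (O(log r)); the contract tested is agreement with a
  linear scan, not the constant factor.
* Hash codes are 1-based and 0 means "absent", so the two outcomes of a
  lookup cannot collide.
* Degenerate inputs: an empty weight sequence has no encoding (error);
  a single run encodes with `L = [0]`; an empty collection is valid for
  I/O and permutation (both are identities) but yields an empty
  dictionary.

## Minimising the number of runs

Strings are atomic — splitting them would enlarge the k-mer text and
defeat the purpose — so only their order and orientation may change.
Reordering affects the run count only through the *end-point weights*
(first and last weight of each string): a junction glues one run when
the previous string's last weight equals the next one's first. The
collection is therefore modelled as a graph with one node per string
labelled `(front, back)`, and an ordering/orientation corresponds to a
node-disjoint cover by oriented paths, giving the identity
`r = R - m + |C|`. Minimum-cardinality path cover is NP-hard on general
directed graphs but solvable in linear time here, because any two nodes
sharing a weight can be glued:

1. **preprocess** — all nodes with equal end-points `(x,x)` are chained
   into one node and attached to a partner `(x,y)` when one exists; each
   duplicate class `E_{x,y}` collapses to one node (odd size) or two
   (even size). Afterwards every pair occurs at most twice and no
   `(x,x)` node remains except single-node components.
2. **merge-even** — while some weight has a nonzero even frequency,
   merge two nodes incident to the weight `w*` of *minimum* even
   frequency. Minimality is what makes the argument go through: the
   incidence set of an even-frequency weight can never be left with a
   single node. After this phase each component is either one node or
   free of even-frequency weights.
3. **greedy-cover** — grow maximal oriented paths; with only
   odd-frequency weights left, each maximal path retires exactly two
   odd weights, so the phase produces `|W_odd|/2` paths.

The result has size `|C_even| + |W_odd|/2`, which is optimal: each
all-even component necessarily contributes one path, and each pair of
odd weights one path end. The test suite re-derives this quantity
independently (frequency tables plus igraph components) and also checks
the cover size against exhaustive search over all `m!·2^m` signed
orderings for m ≤ 7, and the final run count against the analogous
exhaustive minimum for whole collections.

### Determinism and tie-breaks

The algorithm's output (not just its size) is deterministic:

* containers are insertion-ordered everywhere; "take a node from
  `I_w`" always takes the earliest-inserted alive node;
* duplicate-pair groups are processed in sorted `(x, y)` order; an
  `(x,x)` chain attaches to the lexicographically smallest available
  partner pair; an even-sized class splits as "chain of all but one,
  plus the untouched last node";
* ties among equal minimum even frequencies resolve by the tracker's
  array order (numeric key order at build). Ties never affect `|C|` —
  only which optimal cover is returned;
* greedy paths extend their back end before their front end.

### The min-even tracker

Phase 2 needs "report a key of minimum positive value" in O(1) under
"decrease a key's value by 2". The structure is an array `A` of
(key, value) pairs sorted by value, a map `R` from each present value to
the half-open index range of its block in `A`, and a map `P` from key to
position. `R[0]` starts as `[1, 1)`, so `A[R[0].end]` is always the
minimum-positive entry. A decrease swaps the touched entry to the head
of its block and shifts two range boundaries — O(1) touched entries,
which the property tests verify operation by operation along with the
three structural invariants (sorted `A`, tiling `R`, consistent `P`).

### Engine representation

Merged nodes form binary trees over the original strings; orientation
changes are O(1) (swap end-points, negate the sign) with the reversal
of children deferred to expansion time. The production engine keeps all
node fields in flat arrays inside a closure — in R, element writes on
closure variables are in-place, whereas the equivalent writes through an
environment copy the whole vector — and the incidence sets are
intrusive linked lists with lazy deletion. A recursive list-of-lists
node implementation (`endpoint_node`, `merge_nodes`, `expand_node`) is
exported as the readable reference; the tests drive both through random
merge/flip sequences and require identical expansions. Timing checks in
the suite use a deliberately generous two-point ratio (4k vs 16k nodes)
because wall-clock slopes are noisy; development measurements were
near-linear up to 10^5 nodes.

## The synthetic generator

`gen_spss()` emulates the two features of real weighted SPSS data that
matter here: globally distinct canonical k-mers (enforced by rejection
sampling against a global set) and runny weights (a Markov model that
keeps the previous k-mer's weight with probability `1 - p_change`,
otherwise redraws a different value uniformly from `1..max_weight`).
The acceptance script uses 300 strings of length 40–120 at k = 21 with
`p_change = 0.1` and weights up to 8 — unitig-like sizes with long runs,
picked once as a realistic desk-scale stand-in.

What the generator does *not* emulate: the skewed weight distribution of
real genomes (most k-mers occur once), overlap structure between strings
(generated strings share no k-mers at all, while unitigs tile a genome),
and the string-length distribution of real unitig sets. Consequently,
passing tests demonstrate correctness of the data structures and
optimality of the cover on arbitrary end-point configurations — which is
the mathematical claim — but the *compression ratios* printed by the
acceptance script are illustrative, not predictions for genomic data,
where entropy is lower and runs are far longer.

## Parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| `k` | everywhere | none (explicit) | headers do not carry k unambiguously; forcing it avoids silent misparses |
| `p_change` | `gen_spss` | 0.2 (0.1 in the acceptance run) | run-change probability per k-mer; 0 gives one run per string, 1 gives one run per weight |
| `max_weight` | `gen_spss` | 6 | weight alphabet `1..max`; controls `|D|` and the code width |
| `max_retries` | `gen_spss` | 200 | rejection-sampling budget per string before declaring the spec infeasible |
| `max_m` | oracles | 7 / 8 | exhaustive-search guards; beyond this the memoised enumeration stops being instant |
| slack | space tests | 64 bits | constant absorbing the `o(r)` terms the analysis leaves unpinned |

## Known limitations

* The associative map is an R hash environment over canonical k-mer
  strings: exact and order-preserving, but not the compressed
  minimizer-bucketed storage a production C++ dictionary would use, so
  the *k-mer* side of the index is not small — only the weight side is.
  All correctness properties of the weight encoding and the cover
  optimisation are independent of this choice.
* Queries are random-access only; no streaming (sliding-window)
  amortisation across neighbouring queries.
* Single-document weights only: one count per k-mer, no per-sample
  count vectors.
* Weights are exact; no lossy/approximate mode.
* The index file stores the SPSS sequences and rebuilds the map on
  load; load time is linear in n.
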