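---
title: "Binary interpretation of mtDNA mixtures with variation graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary interpretation of mtDNA mixtures with variation graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitograph)
library(dplyr)
```

## The problem

Forensic mitochondrial DNA profiles are reported as *sequence differences*
against a reference (in practice the rCRS): `73G` for a substitution,
`4.1T` for an insertion after position 4, `5 del` for a deletion. Unlike the
haplotypes they encode, difference sets are not directly comparable: the
string AACAGT can be written against the reference AACAAGT as a deletion of
either the 4th or the 5th A, so two call sets may differ while describing
the same molecule. Single-source casework therefore compares *decoded
strings*, never call sets. For **mixtures** — where a profile like
`73G 154W 178M` superimposes two contributors, with IUPAC codes (W = A/T,
M = A/C) marking sites where they disagree — no string can be decoded
directly, and the same convention problem applies.

`mitograph` solves this by compiling the mixture's calls into a **variation
graph**: a DAG whose source-to-sink paths spell exactly the haplotypes
compatible with the mixture. All comparisons are then string-to-graph, so
verdicts are invariant to how the variation was encoded (the two deletion
encodings above yield graphs generating identical sequence sets). The
method is *binary*: allele calls are taken as error-free presences, and
read counts / signal intensities are deliberately ignored.

## The graph construction

The reference backbone alternates base nodes with *epsilon nodes* —
sequence-free nodes that consume no characters on a path — plus terminal
sentinels:

```
source -> e0 -> b1 -> e1 -> b2 -> ... -> bL -> eL -> sink
```

Variants are applied in turn:

* **Substitution** — the reference base node is removed and one node per
  observed allele is added in its place (the reference base is re-added
  only when the IUPAC expansion contains it). Nothing the mixture does not
  assert ever enters the graph.
* **Insertion** — a chain of inserted bases plus a new closing epsilon is
  attached after the anchor's epsilon; the closing epsilon inherits the
  anchor epsilon's outgoing edges. A skip edge (epsilon to epsilon)
  preserves the insertion-free spelling unless the insertion is *fixed* in
  all contributors.
* **Deletion** — a bypass edge runs from the epsilon before the first
  deleted base to the epsilon after the last. A fixed deletion removes the
  spanned bases outright.

The epsilon nodes are the load-bearing device. Without them, two adjacent
ambiguous sites would need base-to-base edges for every allele combination,
most of which no contributor may carry; with the epsilon bottleneck, *every
node and every edge is certainly present in the mixture*. That is what
licenses the explanation test below. Two design points were genuinely open
and settled as follows:

* The "node before the deleted bases" from which a bypass departs is read
  as the epsilon currently preceding the first deleted base (which, after
  an insertion at that boundary, is the insertion's closing epsilon), not
  the base node(s). This keeps the edge count independent of allele
  multiplicity, preserves the bottleneck, and makes an insertion and an
  abutting deletion independent choices on a path — a path may take the
  insertion, the bypass, both, or neither.
* The insertion skip is an epsilon-to-epsilon edge. A path may therefore
  traverse two consecutive epsilons; the skip edge is a first-class
  coverable element, which is exactly why two insertion carriers fail to
  explain a reference + insertion mixture (nobody covers the skip).

Node identifiers are deterministic functions of the profile
(`b:154:T`, `e:154`, `bi:4.1:T`, `ei:4`), so equal profiles give identical
graphs and fixtures diff cleanly.

## Matching and explanation

```{r fig2}
ref <- reference_sequence("AACCT")
g <- build_mixture_graph(parse_variants("3Y 4Y", ref))
enumerate_generated(g)$sequences
```

A haplotype is **consistent** (not excluded) when some path spells it —
decided by NFA-style dynamic programming over node sets with epsilon
closure, in time linear in haplotype length, never by enumerating the up to
2^k generated sequences. A haplotype multiset **explains** the mixture when
every member is consistent and some choice of one accepting path per member
jointly covers every node and edge:

```{r explain}
is_consistent(g, c("AATCT", "AACCT"))
explains(g, c("AATCT", "AACCT"))$explained  # 4T is never covered
explains(g, c("AATTT", "AACCT"))$explained  # complementary pair
```

One string can trace several paths (homopolymer deletion placements), so
the explanation test quantifies over accepting paths, enumerated by
deterministic backtracking on the forward/backward-pruned product of graph
nodes and prefix lengths. The search over path assignments is exhaustive
with pruning; caps (1000 paths per haplotype, 10^6 assignments, both
configurable) flag a verdict `approximate` if ever hit — real mixtures sit
far below them because few haplotypes are consistent at all.

For a two-person mixture of k biallelic substitution sites the feasible
unordered pairs are the complementary allele assignments, 2^(k-1) of them —
with ~30 ambiguous sites, beyond a billion — which is why the statistics
below filter through consistency first and why `n_feasible_pairs()` counts
by dynamic programming instead of enumerating.

## Match statistics

**RMNE.** A random person is "not excluded" if their haplotype traces a
path. `rmne()` reports the proportion of database records consistent with
the graph and an exact Clopper–Pearson upper bound (the 1 − α/2 quantile of
Beta(x+1, n−x); 1 − (α/2)^(1/n) at x = 0) to correct for finite database
size. The default confidence level is 0.95, two-sided, so the bound is a
97.5% one-sided limit.

**Likelihoods.** The naive likelihood of a set U of unknowns is
|U|!·∏Pr(H_j) with Pr taken as database relative frequency; the total
likelihood sums this over every unknown set that (with any knowns) explains
the mixture. Because most mitochondrial genomes are unique in a database,
that sum is usually empty — likelihood 0, flagged `empty_T`. The **GBC
likelihood** stays well defined there: the proportion of u-combinations of
database haplotypes that explain the mixture out of choose(n, u)
(n(n−1)/2 pairs for u = 2), again with a Clopper–Pearson upper bound.
Combination scans are restricted to non-excluded haplotypes, which provably
cannot change the count (tested against unrestricted scans).

Two readings of "adding the knowns to the database implicitly" are
defensible, so both are implemented behind documented switches with the
conservative defaults: unknowns are drawn *without* replacement
(denominator choose(n, u), matching the printed formula; sampling with
replacement is available via `with_replacement`) and knowns are conditioned
on rather than drawable (`include_knowns` appends them to the records and
enlarges n). Haplotype frequencies are plain relative frequencies;
theta-corrected (Balding–Nichols) likelihoods are out of scope.

**Masking** removes calls whose reference footprint intersects the given
intervals, identically for the mixture and for database haplotypes, so
masked comparisons stay like-with-like. It is safest away from ambiguous
indel placements, since an indel's footprint depends on its encoding even
though decoded strings do not.

## The synthetic study

`simulate_database()` generates single-source haplotypes by independent
per-site mutation on a (by default random) reference: no phylogeny, no
linkage. The defaults — 1000 bp reference, per-site substitution rate
0.015, per-site indel rate 10^-4 with geometric lengths up to 3 — give ~30
mean pairwise differences, matching European-level mitogenome diversity on
a scaled-down sequence; r = 0.0275 mimics African-level diversity (~55).
`run_study()` samples two records with replacement, rejects pairs with
identical haplotypes (as decoded strings, so equivalent encodings count as
identical) or with partially overlapping / abutting non-identical indels —
whose merged encoding would be ambiguous — and redraws, tallying
rejections. Per accepted mixture it records the number of explaining
haplotype pairs, the number of distinct non-excluded haplotypes, p(RMNE)
with its upper bound, and the GBC likelihood treating the first-sampled
contributor as known (u = 1).

What the simulator does *not* emulate matters for interpretation: real
populations are phylogenetically structured, so near-identical haplotypes
(maternal relatives, shared lineages) lift the non-excluded counts well
above their floor, whereas independent mutation at these rates makes
almost every synthetic haplotype unique and pins the count at the minimum
of two contributors. Passing tests therefore demonstrate the
guarantees of the method (the generating pair always explains its own
mixture; contributors are never excluded, so p(RMNE) ≥ 2/n; bounds dominate
estimates; the modal explaining-pair count is 1), not the population-level
distributions of real databases, which depend on a 40k-genome external
snapshot and are deliberately not reproduced.

The acceptance suite runs this study at n = 2000 haplotypes and 2000
mixtures with fixed seeds; the unit suite uses smaller sizes. All
randomness flows through a single integer seed per generator or study call,
making every table byte-reproducible.

## Numerical and degenerate-input choices

* Enumeration (`enumerate_generated()`) caps at 10^5 paths and flags
  truncation; it is an oracle for tests, not a production path.
* `count_generated()` counts paths in doubles (exact to 2^53, far beyond
  any graph of interest here).
* A substitution whose allele set is exactly the reference base is a no-op
  and is dropped; a second substitution at the same position is a
  construction error.
* A deletion fixed in all contributors that spans another insertion's
  anchor is rejected as contradictory (the insertion would hang off a
  removed epsilon).
* Adjacent single-base deletions merge into one span; partially overlapping
  non-identical indels are rejected at profile level. The `!` token suffix
  (fixed indel) is this package's extension of EMPOP notation — the
  standard single-string encoding cannot say whether an indel is carried by
  all contributors, and plain tokens default to the mixture reading (some
  contributor retains the reference state).
* The mitochondrial genome's circularity is ignored (linear reference),
  heteroplasmy codes are not allowed in single-source database records, and
  fuzzy (near-match) search is not implemented.
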