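---
title: "Classifying reads by the lowest taxonomic unit of their maximal exact match"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying reads by the lowest taxonomic unit of their maximal exact match}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtax)
```

## The problem

Microbial reference databases are full of sequences that are distinct but
highly similar, so a short sequencing read frequently matches many
reference records equally well. When the records are annotated with nodes
of a hierarchy — here a functional taxonomy such as four-level enzyme
codes under an artificial root — the natural resolution of this
multi-matching is not to enumerate all matching records but to assign the
read directly to the deepest hierarchy node that covers all of them: the
lowest taxonomic unit (LTU), which is the lowest common ancestor (LCA) of
the matching records' labels.

`memtax` implements this as a *labeled* generalized suffix index. The
classification unit is the maximal exact match (MEM): a read substring
that occurs in the database and cannot be extended within the read in
either direction and still occur. A read is assigned to the LTU of its
longest MEM.

## The index

All database records are concatenated, each terminated by a sentinel
`$` that sorts before every residue and can never match a query symbol,
and the suffix array of the concatenation is built. Every suffix is
annotated with the taxonomy node of its source record, giving a label
array in suffix order. Because all suffixes sharing a prefix `p` form a
contiguous suffix-array interval, the LTU of `p` is the LCA of a
*contiguous range* of that label array.

To answer that range query in constant time we precompute a sparse table
over the label array using pairwise tree LCA as the combining operator.
LCA is idempotent and associative, so a range of width `w` is answered by
combining two overlapping blocks of width `2^floor(log2 w)`: one pairwise
LCA per query, regardless of `w` and of the pattern length. Pairwise LCA
itself is parent-pointer climbing with depth equalization, which costs at
most the tree height — a small constant (4 in the enzyme-code
application) that does not depend on the interval. Preprocessing is
O(n log n) in time and memory; queries do no per-element work. Any
structure with the same O(1) contract (e.g. a labeled bidirectional BWT)
could be substituted; the MEM and LTU semantics are defined purely in
terms of suffix-array intervals and are agnostic to the backend.

Suffix arrays are built by prefix doubling (O(n log² n)), which is simple,
allocation-light, and more than fast enough at the scales this reference
implementation targets; construction is single-threaded by design.

## MEM enumeration and tie-breaking

For each query start `i` (0-based) the index returns the longest prefix
`l_i` of `query[i..]` that occurs anywhere in the database, with its
interval. The match at start `i` is a MEM iff `l_i >= min_mem` and
`l_i >= l_{i-1}` (otherwise it is the trailing remainder of the previous
start's match, hence not left-maximal). Maximality is judged against the
whole database, not per record — per-record MEMs would recreate exactly
the multi-matching the labeling scheme exists to avoid.

The read is assigned to the LTU of a maximal-length MEM. When several
MEMs tie for the maximal length, one is selected uniformly at random;
the tie-break stream is derived from one root seed and the read's ordinal,
so a run is reproducible and independent of processing order. An optional
strict mode instead takes the LCA across the tied MEMs' LTU nodes (a
conservative sensitivity analysis; it can only move assignments rootward,
so it is not the default).

The default `min_mem` is 5 amino acids (15 nucleotides for nucleotide
indexes). Shorter thresholds admit spurious hits: a specific 5-mer has
20^-5 per-position probability under a uniform residue model, so random
hits are rare even in megaresidue databases, while 4-mers start to produce
them. Raising the threshold trades sensitivity for specificity; both are
exposed everywhere.

## Alphabets, wildcards and translation

Residues are uppercased on input. Symbols outside the canonical alphabet
(20 amino acids, or `ACGT`) are replaced by a wildcard that never matches:
`*` in database text and `#` in queries. Using two distinct bytes makes
"wildcard matches nothing" a plain byte comparison — an ambiguous position
on either side simply terminates an exact match, which is the only honest
treatment when the classification unit is an exact match.

Nucleotide reads searched against an amino-acid index are translated in
all six frames under the standard genetic code and split at stop codons
into maximal stop-free fragments; codons containing an ambiguous base
translate to the query wildcard rather than being dropped, so fragment
offsets stay exact. Fragment-local MEMs from all frames are pooled before
the best-hit selection, and cross-frame ties are resolved by the same
uniform draw as within-frame ties. Reported MEM lengths for translated
searches are in amino acids. Mates of a read pair are classified as
independent reads; no mate-reconciliation rule is imposed.

## Hierarchy conventions

Levels are numbered from the root: root = 0, and the leaves of a full
enzyme-code tree sit at level 4; "level 3" is the rank immediately above
the leaves. Node names are opaque; incomplete codes (such as `1.1.1.-`)
are simply internal nodes at whatever level the edge table places them.
Multi-parent structures (code transfers/aliases) are rejected — the
hierarchy must be a tree for the LCA to be well defined.

A read with no qualifying MEM is *unassigned*, which is informationally
distinct from being assigned to the root (matched, but by records spread
over the whole tree). The classifier output always separates the two;
profiles and evaluation summaries merge unassigned reads into the root by
default (`merge_unassigned_into_root`), which reproduces the common
accounting in which every read receives a node.

## The simulator and what passing tests mean

`make_fixture` emulates an annotated reference database: a complete tree
with configurable per-level branching (default four levels), records of
uniform-random residues, and labels drawn uniformly over the leaves
(optionally a small fraction at internal nodes, as real databases place
some sequences above the leaf rank). `simulate_reads` draws fragments
with probability proportional to record length at uniform offsets and
applies independent per-position substitutions to a uniformly chosen
*different* symbol. Substitution-only is the minimal error model
consistent with "x% difference from the reference"; it keeps truth offsets
exact. Indels, quality scores, platform error profiles and abundance
skew are deliberately out of scope.

Evaluation assigns each read one of five categories — correct (the truth
node), ancestor (a non-root proper ancestor of the truth), root,
incorrect (anything else, including siblings and descendants of the
truth), unassigned — plus the mean MEM length, the mean count of tied
MEMs, and per-level assignment histograms against the database's own
level composition.

What the synthetic conditions do *not* emulate matters for reading the
numbers: uniform-random records share essentially no sequence between
taxonomy nodes, so classification of low-error reads is near-perfect and
almost no read is tied or driven to the root. Real protein databases are
heavily redundant within and across subtrees, which is precisely why the
direct LTU labeling exists; on such data far more reads have multiple
equally good matches and land on internal nodes or the root. The
simulation therefore validates the *machinery* (exactness of the index,
monotone degradation with divergence, conservation of counts,
reproducibility), not field accuracy rates. The shared-content effect
itself is tested constructively, by planting an identical block across
all leaves of one level-3 subtree and checking that reads from the block
land exactly on that internal node.

## Problem sizes and numerical choices

The packaged checks run at desk scale, chosen as the smallest sizes at
which the properties are sharp: oracle equivalence on 1,000 random
fixtures of up to 20 records × 200 residues against brute-force
dynamic-programming string scans; 10,000 nested-pattern LTU-descent
pairs; the error-degradation grid on a 50-record × 300-AA database with
5,000 reads of 60 AA per rate in {0, 5, 10, 30}% (60 AA being roughly the
translated span of a ~180 nt read); tie-break uniformity over 10,000
seeds. All coordinates are 0-based and half-open; empty intervals encode
pattern absence (never an error); the empty pattern matches the full
suffix range. Ties between equal suffixes cannot arise because sentinels
make all suffixes distinct; a single sentinel symbol with record-boundary
bookkeeping suffices since no query can contain it.

## Limitations

Exact matching only: no mismatch-tolerant seeds, no alignment extension,
no compressed or sampled index, no multithreaded construction. Reads more
divergent than ~30% from any reference mostly fall to short MEMs and the
root — downstream of this package, a slower aligner can revisit those.
The on-disk index format is plain text plus a JSON manifest, versioned via
`format_version`; it favors transparency over compactness.
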