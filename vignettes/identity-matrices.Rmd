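---
title: "Pairwise identity matrices for sequence classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise identity matrices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairid)
```

## The statistic and why it is computed this way

`pairid` scores the relatedness of two sequences as the fraction of
identical residues among the columns of their *pairwise* global alignment
at which neither sequence has a gap:

$$\mathrm{identity} = 1 - \frac{M}{N}$$

with $N$ the number of gap-free columns and $M$ the number of mismatching
gap-free columns. Two decisions are baked into this definition.

**Independent pairwise alignments, not a multiple alignment.** In a multiple
sequence alignment the gap pattern imposed on a pair depends on every other
sequence present, so the apparent identity of a fixed pair drifts — usually
downwards — as the dataset grows. Aligning each pair on its own makes every
score a function of the two sequences and the scoring parameters alone.
This is the package's load-bearing invariant: embedding the same family in
supersets of any size must reproduce every pair's $M$, $N$ and identity
bit-for-bit, and the test suite asserts exactly that.

**Gap columns are ignored entirely.** Counting conventions for indel
columns (fifth character state, match, mismatch) are the other major source
of disagreement between identity calculators. A pairwise global alignment
never produces a column with gaps in both rows, and dropping the remaining
gap-containing columns from both $M$ and $N$ removes the convention
dependence — the same choice routinely made when computing evolutionary
distances for tree building.

One consequence is worth stating plainly: identities computed this way are
*generous*. Even completely unrelated random nucleotide sequences receive a
substantial score once optimally aligned, because the aligner concentrates
the disagreement into gap columns which are then excluded. With this
package's default scoring, 50 seeded pairs of uniform-random 1000-nt
sequences average in the seventies of percent identity (recomputed by
`scripts/acceptance.R`; the classical expectation is merely that such pairs
exceed 40%). For classification work this bias is tolerable and even
conservative — it makes a novel isolate look *more* like known taxa, so it
discourages the spurious erection of new species — but absolute values
should never be compared across different scoring parameter sets.

## Alignment model and parameters

Alignment is global Needleman–Wunsch with affine gap costs, computed by a
three-state (Gotoh) dynamic programme in compiled code. A gap run of length
$L$ costs $\mathrm{open} + \mathrm{extend}\,(L-1)$; terminal gaps are
penalised like internal ones.

Defaults (all overridable through `align_params()` or the command line):

| parameter | default | notes |
|---|---|---|
| nucleotide match / mismatch | +5 / −4 | EDNAFULL (EMBOSS-needle) convention |
| protein scoring | BLOSUM62 | any matrix shipped by Biostrings by name |
| gap open / extend | 10 / 0.5 | EMBOSS-needle convention |

These are one widely used, fully documented convention, not a claim of
uniqueness: published identity-based demarcation pipelines delegate their
alignments to general-purpose aligners whose gap parameters are rarely
reported, so numeric identity with any particular historical output is not
promised — only the method's properties are.

Determinism is treated as part of the contract, not an accident:

* the pair is ordered lexicographically (C locale) before alignment, so
  `global_align(a, b)` and `global_align(b, a)` differ only by a row swap;
* DP ties are broken in the fixed order *aligned column ≻ gap in the second
  row ≻ gap in the first row*, both while filling and at the final cell;
* all default scores are exactly representable doubles, so tie comparisons
  are exact.

Ambiguity codes (IUPAC nucleotide codes, `X` etc. for protein) are accepted
and scored as ordinary characters: in nucleotide mode any two identical
characters score `match` and any two different characters `mismatch`; in
protein mode characters present in the substitution table use its entries,
and the rare letters absent from it (`O`, `U` for BLOSUM62) score +4 when
identical — the table's modal diagonal — and −4 (its minimum) otherwise.
This trades biochemical subtlety for determinism; datasets dense in
ambiguity codes deserve cleaning rather than clever scoring. On input,
residues are upper-cased and `U` is mapped to `T` for nucleotide data so
that scoring operates over one canonical alphabet.

The alignment engine is validated two independent ways: against an
exhaustive enumeration of every global alignment (all pairs of short
two-letter strings, plus random short pairs), and against a second,
unrelated DP implementation (Biostrings) after mapping its gap convention
($\mathrm{gapOpening} = \mathrm{open} - \mathrm{extend}$).

## Tree ordering

The identity matrix is displayed in the leaf order of a neighbour-joining
tree built on $1 - \mathrm{identity}$ distances, so that related sequences
form contiguous blocks. NJ is the classical Saitou–Nei algorithm; it is
implemented inside the package because the *order*, not just the topology,
feeds downstream output, and that requires pinning down conventions that
tree libraries leave unspecified:

* input rows are canonicalised to lexicographic id order before the NJ
  loop, making permutation invariance of the result exact rather than
  dependent on floating-point summation order;
* ties in the Q-criterion are broken by scan order over that canonical
  ordering;
* the tree is rooted at the final join, with the last remaining distance
  split evenly between the two subtrees (for two leaves this is the
  familiar $d/2, d/2$ split);
* children are ladderised by decreasing subtree leaf count, then by
  ascending smallest contained leaf id — which reduces to plain
  lexicographic leaf order for degenerate all-zero distances;
* negative branch-length estimates, which NJ can produce on non-additive
  input, are clamped to zero for display only; they feed no further
  computation.

On additive matrices the implementation reproduces the generating tree's
topology and recovers all patristic distances to within $10^{-9}$
(`patristic_distances()` computes them at full precision; the Newick export
rounds to six decimals, which is why re-parsed trees agree to about
$10^{-5}$ instead).

## Figures and the identity distribution

The matrix heat map labels sequences horizontally on the left and
vertically along the bottom, prints cell values for up to 30 sequences, and
offers two colour modes: a continuous ramp spanning only the observed
identity range (maximising contrast — a full 0–100% ramp wastes most of its
dynamic range on empty space), or discrete bands between user thresholds,
e.g. a single species-demarcation cut-off giving a two-colour
conspecific/heterospecific matrix.

The identity-frequency distribution bins percent identities into half-open
bins $[lo, hi)$ of 1 percentage point by default (the width is
configurable; the last bin includes 100 so that identical pairs are
counted). Each unique pair is counted once. Peaks mark threshold values
that would cut through many pairs — maximally ambiguous classification
cut-offs — while troughs mark values that separate the data cleanly.

Rendering is deliberately deterministic: SVG output contains no timestamps
and avoids rasterised legend artwork (whose embedded ids carry a
process-global counter), so re-rendering the same data reproduces the file
byte-for-byte. PNG and PDF are also supported.

## Sessions and incremental growth

A completed analysis is saved as a plain uncompressed tar archive (written
by R's built-in tar implementation, so no external tools are involved)
with three inspectable members: `manifest.json` (format version, alphabet,
alignment parameters, md5 checksums), `sequences.fasta`, and `pairs.csv`
holding the exact integer $M$ and $N$ per pair. Identities are
reconstructed from $M/N$ on load, so a round trip is exact; checksums catch
truncated or edited archives. Because pairs are independent, adding $k$
sequences to a saved session of $S$ requires exactly
$kS + k(k-1)/2$ new alignments and is guaranteed — and tested — to be
byte-identical in its exports to a from-scratch run on the union.

The same independence underlies the parallel contract: pairs are
embarrassingly parallel tasks assembled in a fixed order, so any worker
count (forked processes; serial fallback for one) produces identical
output bytes.

## Partitioning by identity range

"Give me files of sequences that are between 90 and 100% identical" is
ambiguous: pairwise in-rangeness is not transitive. The package resolves it
as single-linkage — connected components of the graph whose edges are the
in-range pairs — because that is the only reading that yields
non-overlapping files whose union is the dataset. Members of one file are
therefore connected by a chain of in-range pairs but not guaranteed all
pairwise in-range; a complete-linkage variant would be the natural
extension point for callers who need the stronger guarantee. Both bounds
are inclusive, compared with a $10^{-9}$ tolerance so that exact rational
identities landing on a bound are not lost to floating-point
representation. Singletons (no in-range partner) are collected into an
`unassigned.fasta`, written only when non-empty, and a CSV manifest maps
every id to its file.

## The synthetic-data generator

`make_synthetic_family()` emulates the one regime this package is about: a
family of sequences descending independently from a common ancestor. One
seeded uniform-random ancestor is mutated per descendant with per-site
substitutions (probability `divergence`, default 0.1, replacement uniform
over the other three bases) and per-site indel events (probability
`indel_rate`, default 0.005; geometric lengths of mean 3; insertion or
deletion with equal probability). Two descendants then differ at roughly
$2d(1 - \tfrac{3}{4} \cdot 2d)$-ish of sites — divergence 0.1 yields
pairwise identities in the low 0.8s. `make_random_dataset()` provides the
opposite extreme: i.i.d.-uniform, completely unrelated sequences.

What this does *not* emulate — and hence what passing tests do not show
about real data: rate heterogeneity across sites, transition/transversion
bias, selection, recombination, shared indel history (indels here are
private to each descendant), and the rotated starting coordinates of
circular genomes (deliberately out of scope; sequences are compared as
given). The generator's role is to provide data whose true structure is
known exactly, so that invariance, equivalence and separability claims can
be asserted bit-for-bit — not to simulate realistic viral evolution.

Test and validation problem sizes were chosen once: families of 25–100
sequences of 300–1000 nt for the invariance, session and worker checks
(comfortably inside the regime where all-pairs alignment runs in seconds),
1000-nt pairs for the random-identity floor, strings of length ≤ 7 for
exhaustive alignment enumeration, and trees of up to 12 leaves for NJ
recovery.

## Degenerate inputs and edge rules

* An alignment whose gap-free column count $N$ is zero (possible only for
  pathological inputs) raises an explicit "no comparable columns" error
  rather than returning 0/0.
* Datasets need at least two sequences for all-pairs work; duplicate ids,
  empty records, gaps in input and characters outside the IUPAC sets are
  load-time errors naming the offender.
* Alphabet detection calls a dataset nucleotide when ≥ 90% of pooled
  residues are in `A,C,G,T,U,N`; the threshold is arbitrary but every
  entry point accepts an explicit override.
* `num_pairs()` and the extension arithmetic are plain integer-valued
  formulas, kept exact in doubles.

## Known limitations

* All-pairs cost grows quadratically; at ~2,800 nt and thousands of
  sequences the alignment count (499,500 pairs for 1,000 sequences) calls
  for many workers and patience. The per-pair DP is $O(mn)$ time and
  $O(mn)$ traceback memory.
* No correction for multiple substitutions: $1-M/N$ is an identity, not an
  evolutionary distance, and saturates for deep divergences. The NJ
  ordering built on it is a display device, not a phylogeny.
* Circular-genome rotation is not normalised; sequences deposited with
  different origins will score artificially low.
* Protein mode scores ambiguity characters crudely (see above) and no
  local or semi-global alignment variant is offered by design.
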