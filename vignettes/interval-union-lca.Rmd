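---
title: "Interval-union LCA binning of long reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval-union LCA binning of long reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LongReadLCA)
```

## The problem and the model

Alignment-based taxonomic binning of short reads uses the naive LCA rule: a
read is placed on the lowest common ancestor of the taxa behind its
near-best-scoring alignments. The rule implicitly assumes all alignments of a
read compete for the *same* gene. A long read or assembled contig overlaps
many genes, each conserved differently across taxa, so pooling all near-best
hits drives the LCA toward unspecific high-rank nodes, while segmenting the
read into "genes" first is fragile because protein alignments at one locus
vary widely in extent.

The interval-union LCA algorithm avoids both problems by working with
measure, not gene identity. For one read:

1. every alignment start/end becomes a boundary, cutting the covered part of
   the read into atomic pieces, so that each alignment is an exact union of
   pieces (`buildPartition()`);
2. per piece, alignments within `topPercent` of the best bit score covering
   that piece are *significant* (`significantOnPiece()`) — an alignment may
   be significant on some of its pieces and not others;
3. each taxon's interval set $I(t)$ is the union of pieces with a significant
   alignment to $t$; interval sets propagate to ancestors by union with
   overlap merging, so $I(s) \supseteq I(c)$ for every child $c$ of $s$ and
   coverage is monotone non-decreasing toward the root;
4. with $D$ the measure of the union of **all** alignment intervals of the
   read (its covered portion), the read is placed on the lowest node $s$ with
   $|I(s)| \ge \texttt{percentToCover} \cdot D$ while **no child of $s$
   reaches that threshold**; when several nodes qualify, the read goes to
   their LCA (`intervalUnionAssign()`).

Because coverage is monotone, the set of nodes reaching the threshold is
ancestor-closed and the qualifying nodes are exactly its minimal elements.
We state the child condition in terms of the child's *coverage* (not the
child's own qualifying status): on a chain of covering nodes the recursive
reading would re-admit ancestors above a qualifying node, which contradicts
both the worked example and the intent of "lowest".

The classical short-read rule is retained as `naiveLCAAssign()`; when all of
a read's alignments span one identical interval the two rules coincide (a
property the test suite checks across `topPercent` settings).

## Parameters

All percent parameters are on the 0–100 scale; defaults are the established
ones for this algorithm family.

| parameter | default | role |
|---|---|---|
| `topPercent` | 10 | score band (percent below the local best bit score) within which an alignment is significant on a piece. Smaller values chase chance score differences; larger ones push reads to higher ranks. |
| `percentToCover` | 80 | fraction of the covered portion a node's interval union must reach. Higher values are more specific but raise false positives. |
| `minSupport` | 0.05 | minimum percent of total *assigned* weight a taxon needs to be reported; deficits are pushed up the taxonomy. |
| `weightMode` | `aligned_bases` | per-read weight: `read_count`, `total_length`, `aligned_bases`, `contig_reads`. Aligned bases down-weight long unaligned stretches, which read counts and lengths do not. |
| `minPercentCoverToDominate` | 50 | functional dominance: overlap (strictly more than this percent of the dominated alignment) required, together with a strictly higher score and the same strand. |
| `minPercentCoverToStronglyDominate` | 90 | strong domination overlap threshold (inclusive). |
| `topPercentScoreToStronglyDominate` | 90 | strong domination score factor: `0.9 * bitscore(a) > bitscore(b)` (strict). |

## Numerical and boundary conventions

* **Coordinates.** Read coordinates are 0-based half-open everywhere
  internally; GFF3 conversion to 1-based inclusive happens only at the
  boundary. Reverse-strand alignments are stored on forward-read coordinates
  with a strand flag. Interval unions and measures delegate to IRanges
  (`reduce` merges overlapping *and* abutting ranges, which is the required
  union-with-merge).
* **Thresholds.** The `topPercent` band is inclusive
  (`score >= (1 - topPercent/100) * best`: scores "within 10%" count), as is
  the `percentToCover` comparison. Dominance and strong-domination score
  conditions are strict, so ties never dominate, self-domination is
  impossible, and the per-read best alignment always survives filtering.
* **Strand.** Taxonomic interval unions ignore strand (the binning rule is
  strand-free); functional dominance requires equal strands; strong
  domination is strand-blind by default with an opt-in same-strand flag,
  since its standard definition states no strand condition.
* **Strong-domination semantics.** An alignment is removed when it is
  strongly dominated by *some alignment of the original set*, not of the
  survivor set. Judged this way the filter is order-independent and
  idempotent; the tests confirm it equals the fixed point of
  simultaneous-removal rounds. (One-at-a-time removal would be order
  dependent, because domination coverage is not transitive.)
* **Denominator.** The covered portion $D$ includes alignments whose
  accessions have no taxon mapping: they cannot vote for a taxon but they do
  count toward what the read aligns to. Consequently a read can end
  unassigned when unmapped alignments keep every node below threshold.
* **minSupport push-up.** Each node's *directly assigned* weight is tested
  leaves-first; an under-threshold node transfers its entire weight to its
  parent, and the parent is re-tested after receiving pushed weight, so
  deficits cascade until a node meets the threshold (the root retains any
  residual). Total assigned weight is conserved exactly. The alternative —
  testing subtree-summarized weights — is defensible; the cascading
  direct-weight rule was chosen because it treats pushed-up weight the same
  as directly assigned weight at every level. Unassigned reads are excluded
  from the total, so the threshold depends only on binned weight.
* **Degenerate inputs.** Reads with no alignments or no taxon-mapped
  alignments yield an unassigned record, not an error; an empty dataset
  yields empty assignments and zero weights; `lca` of an empty set and
  unknown taxon ids are errors.
* **Bit scores.** MAF raw scores are converted to bits as
  $(\lambda S - \ln K)/\ln 2$ when the header carries `lambda=` and `K=`;
  otherwise raw scores pass through with a warning. All thresholds here are
  score *ratios*, so any monotone score keeps them meaningful.

## Functional binning and export

A read is binned to every functional class attached to its non-dominated
alignments (`assignFunctions()`); classes are not mutually exclusive, and a
read contributes its full weight to each of its classes. The short-read
best-hit baseline (`bestHitAssign()`) takes the single highest-scoring
*classified* alignment. Taxon compatibility — optionally required for a
reference to dominate or to be exported — accepts the read's bin itself, its
descendants, and its ancestors; a strict flag restricts it to
descendants-or-self, since the direction is a genuine open choice.

GFF3 export writes one CDS feature per (by default, representative)
alignment with a fixed attribute order (ID, Target, taxon, then namespaces
alphabetically) and percent-encoded values, so output is byte-reproducible;
round-trips are verified against an independent GFF3 parser (rtracklayer).
The visualization color rule is exposed as `colorClass()`: a reference at
the read's own taxon keeps that taxon's color; a reference below it takes
the color of the unique child on the path down; anything else (less specific
or incompatible) is gray. Only the class resolution is implemented — palette
generation is a presentation concern.

## What the synthetic data emulate — and what they do not

`makeFig1Fixture()` reconstructs the algorithm's defining worked example:
eight species A–H in two genera P, Q under family R; one read of length 120
with equal-score alignments covering 80% (A) down to 20% (H); P and R each
cover 100% of the aligned read. The caption constraints, not any drawing,
define the fixture; the intervals used (A [0,80), B [30,100), C [10,70),
D [40,90), E [50,90), F [45,80), G [55,85), H [50,70)) satisfy all of them
simultaneously, and the tests assert every stated coverage.

`simulateDataset()` generates a random root/family/genus/species taxonomy
and reads that tile 3–8 gene intervals each. Per gene it emits a top-score
alignment to the true species (about half a bit per aligned base), hits to
up to three sister species at 88% of the top score plus Gaussian noise
(`scoreNoiseSD`, default 5 bits — at zero noise sisters sit just below the
default 10% significance band, so species-level recovery is exact by
construction), and off-target hits to distant species at `offtargetRate`
(default 0.02). Chimeric reads (`chimeraRate`) splice two species from
different genera at a uniform 30–70% breakpoint; their truth label is the
LCA of the two sources, a reporting convention kept separate from the
per-species metrics. `leaveOut` suppresses every alignment to the listed
taxa while keeping their reads — the leave-one-out emulation of database
incompleteness. Everything is reproducible from the seed.

The generator emulates alignment *geometry and scores*, not sequences: no
base-level errors, no frame-shift structure (frame-shift counts are carried
through parsing but never interpreted), no varying gene density, no
shared-gene homology across genera, and scores are idealized rather than
drawn from an empirical aligner distribution. Passing tests therefore
demonstrate algorithmic correctness on controlled geometry — not
classification accuracy on real mock communities, which depends on the
aligner and reference database.

Evaluation follows the standard leave-one-out metrics: *sensitivity* is the
percent of all reads assigned to the correct taxon or one of its
descendants; *precision* is the percent assigned correctly out of all reads
binned to a node that is not a strict ancestor of the correct taxon
(ancestor assignments are cautious, not wrong; unassigned reads count in
neither numerator nor the precision denominator). The descendant clause is
applied to both metrics symmetrically.

## Problem sizes in the test suite

The property tests run at sizes chosen to finish in seconds while exercising
every code path: 200 random reads (coordinates ≤ 200, up to 12 alignments,
random 3-level taxonomies) against a per-base brute-force oracle; 100 random
single-interval score configurations for the naive-LCA reduction; 100 random
instances for strong-domination fixed-point equivalence; 150-read simulations
for noise-free recovery and leave-one-out. The simulation defaults (24
species, 100 reads of 1–5 kb) were fixed once as a realistic desk-scale
community and are not tuned.

## Known limitations

* The tabular alignment dialect replaces binary aligner archives; there is
  no streaming or chunked two-pass conversion, so datasets must fit in
  memory.
* Taxonomy handling reads the standard dump dialect but ignores merged or
  deleted node files; the package is taxonomy-version-agnostic.
* No functional hierarchy traversal (pathway or category rollups) — classes
  are opaque identifiers per namespace.
* Whether the minimum-support test should use direct or subtree-summarized
  weights, and whether taxon "compatibility" should include ancestors, are
  not settled by the algorithm's published description; both choices here
  are explicit, documented above, and flagged by flags where sensible.
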