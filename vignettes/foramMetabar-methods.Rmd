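---
title: "Methods: OTU curation and phylogenetic community analysis for rare-protist metabarcoding"
author: "foramMetabar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OTU curation and phylogenetic community analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foramMetabar)
```

## The problem this package addresses

Freshwater foraminifera are rare, phylogenetically scattered protists: a
typical amplicon survey of *Sphagnum* bogs or greenhouse pools recovers a
few dozen OTUs, one of which may carry a third of all reads, alongside
failed libraries, index-switched reads bleeding across samples, and marine
contaminants carried over from concurrent lab work. Off-the-shelf
microbiome pipelines assume richer, better-behaved communities; surveys of
rare lineages instead rely on aggressive, hand-tuned curation whose steps
are rarely reusable or auditable. This package turns that curation into a
deterministic, fully logged algorithm, pairs it with the phylogeny-aware
community analysis such surveys report, and ships a synthetic-community
generator with ground truth so every stage can be scored.

## OTU calling

The caller is a deliberately simplified, transparent re-implementation of
a swarm-style pipeline operating on merged, sample-labelled reads:

1. **Dereplication** collapses identical sequences, accumulating
   per-sample counts. Output order is total count descending with
   lexicographic tie-breaks, which makes everything downstream
   deterministic.
2. **Clustering** (`swarmCluster`, radius `d = 1`) grows each cluster from
   the most abundant unassigned sequence by repeatedly attaching any
   unassigned sequence within edit distance 1 of any member. Greedy
   frontier expansion makes the partition equal to the connected
   components of the distance-1 graph with abundance-maximal seeds; the
   test suite asserts that equivalence against an independent graph
   oracle.
3. **Singleton removal** drops clusters totalling one read.
4. **Chimera flagging** uses an explicit two-parent breakpoint test: a
   seed is chimeric if its prefix matches one at-least-twice-as-abundant
   cluster seed and its suffix another, each segment at 99% positionwise
   identity and covering at least 20% of the sequence, while neither
   parent alone explains the full sequence at 99%. The published tools
   this replaces (uchime-style detectors) are heuristic and
   version-sensitive; a fixed, documented rule is testable and behaves
   deterministically. Segments are compared in amplicon coordinates
   (left- and right-anchored), which is appropriate for the fixed-length
   amplicons this package targets and is the main simplification relative
   to alignment-based detectors.
5. **Divergence filtering** removes clusters whose seed aligns to the most
   abundant seed below 65% identity. Identity is computed from a global
   alignment (match 1, mismatch 0, linear gap −1) as matches divided by
   *all* alignment columns, gap columns included — the conservative
   denominator; ties among optimal alignments are broken toward more
   matches, then fewer columns, so the value is unique. The removal is
   strict (`< 0.65`), keeping a seed at exactly 65%.

## The curation cascade

`runCuration` composes six stages in a fixed order, each returning an
audit trail:

| stage | rule | default |
|---|---|---|
| unrarefied filter | drop samples with `< minSampleReads` reads; drop OTUs with `< minOtuReads` reads or `< minOtuOccurrence` occurrences; iterate to fixpoint | 500 / 100 / 2 |
| flagged removal | drop externally identified contaminant OTUs and samples | — |
| re-check | the unrarefied filter again, to fixpoint | as above |
| rarefaction | subsample each deeper-than-depth sample to exactly `rarefactionDepth` reads without replacement | 10,000 |
| index-switch correction | rule 1: rows with total `> bigOtuTotal` lose cells `< bigOtuCellFloor`; rule 2: all other rows lose single-read cells | 1000 / 20 / 1 |
| final filter | keep OTUs with total `> finalMinOtuReads` rarefied reads | 20 |

Numerical and boundary choices worth knowing:

* **Fixpoint semantics.** Removing OTUs can drag a sample below the read
  floor (and vice versa), so both sweeps repeat until nothing changes;
  each pass is logged separately. The filter is idempotent, which the
  suite asserts on random tables.
* **The 1000-read boundary.** Rule 1 is strict (`> 1000`) and rule 2
  covers everything else, so a row totalling exactly 1000 falls under
  rule 2 — the conservative side, since rule 2 zeroes fewer cells. The
  boundary is a `CurationParams` field, not a constant.
* **Row totals are computed once** on the correction's input; zeroing
  never re-classifies a row mid-pass.
* **The read floor applies to unrarefied data only.** A sample whose
  total falls below 500 merely through rarefaction or zeroing is
  retained.
* **Rarefaction** is a multivariate hypergeometric draw (without
  replacement), one draw per sample. Each draw is seeded from the master
  seed and a hash of the sample *id*, so results do not depend on column
  order. Samples at or below the target depth are kept whole. The suite
  checks the per-cell distribution against the hypergeometric law at 500
  replicates.
* **Replayability.** The `CurationReport` logs every removal and every
  cell change (including the realised rarefaction draws);
  `applyCurationReport` replays it on the input and must reproduce the
  output bit-exactly. This is the package's audit guarantee.
* Degenerate inputs are legal: an empty table is a valid (and reported)
  outcome, flagged ids that are absent are logged no-ops.

## Community analysis

**Weighted UniFrac.** For samples $A,B$ the raw distance is
$d(A,B)=\sum_i b_i\,\lvert p_i(A)-p_i(B)\rvert$ over branches $i$ with
length $b_i$, where $p_i(X)$ is the fraction of $X$'s reads descending
from branch $i$; the normalised variant divides by
$\sum_i b_i\,(p_i(A)+p_i(B))$ and is bounded in $[0,1]$. Normalised is
the default, since it is the bounded, depth-robust choice; the raw form
is a flag. Branch proportions are accumulated in one postorder pass; the
tests compare against an independent per-tip path-enumeration oracle
(to $10^{-10}$) and against `phyloseq::UniFrac`. Tree leaves absent from
the table are pruned automatically; table OTUs absent from the tree are
an error listing the missing ids — never silently dropped. Zero-length
branches are legal and contribute nothing.

**PCoA.** Classical scaling: Gower double-centering of $-d^2/2$, a
symmetric eigendecomposition, coordinates scaled by the square root of
each positive eigenvalue. Negative eigenvalues (normalised UniFrac is not
Euclidean in general) are reported but excluded from the percent-variance
denominator, the standard convention; no Cailliez/Lingoes correction is
applied. Axis signs are fixed by making the largest-magnitude loading
positive, so embeddings are deterministic. Isometry on Euclidean inputs
is asserted to $10^{-8}$ against the original point configurations and
cross-checked against `stats::cmdscale`.

**Abundance classes.** Per-sample presences are `rare` below 25% relative
abundance, `intermediate` from 25% to 75% inclusive, and `dominant` above
75%. The interior interval is closed on both ends because the outer
classes are defined strictly ("less than", "more than"); the three
classes partition $(0,1]$ and zero-read cells are absences, not
presences.

**Occupancy.** Detection is at least one read *after* full curation —
the correction rules have already zeroed the cells attributable to index
switching, so a separate detection threshold would double-count that
correction. An OTU detected in exactly one location is `specific`,
otherwise `shared`.

## The synthetic-community generator

`simulateDataset` emulates the structure of a small freshwater
foraminifera survey; its defaults are the package's study conditions:

* **30 samples** across **4 locations** with a few site types each.
* **60 freshwater OTUs + 6 marine contaminants**, with a phylogeny from a
  random rooted binary tree and sequences evolved under a single-rate,
  equal-frequency (Jukes–Cantor) model — the simplest model adequate for
  exercising identity- and distance-based filters.
* **Log-normal base abundances**, `abundanceSigma = 2.5`. Surveys of this
  kind report only the outcome (one OTU holding roughly a third of all
  reads), not an abundance law; the log-normal is the standard
  species-abundance choice, and σ = 2.5 puts the median top-OTU share at
  ≈ 0.35 with the large majority of seeds between 10% and 60% — the
  dominance regime the analysis must cope with.
* **Sample depths log-uniform between 10^2.85 and 10^5.48** (≈ 700 to
  300,000 reads), spanning the depth discrepancy rarefaction exists to
  fix without fitting a depth model. **20% of samples are failed
  libraries** drawn uniformly on [50, 499] reads so the 500-read floor is
  genuinely exercised on both sides.
* **Index switching** moves each read independently to a uniformly chosen
  other sample with probability `switchRate = 0.002`, the order of
  magnitude reported for multiplexed Illumina runs. Every moved packet is
  ledgered. The switch rate is a free parameter of the run, not an
  estimate for any particular instrument.
* **Habitat specificity:** half the freshwater OTUs are restricted to one
  location (zero reads elsewhere in the clean table).
* A sample is recorded as **failed in the truth ledger if its observed
  (post-switching) depth is below 500 reads**: bleed-in can push a
  borderline library over the floor, and a library observed at ≥ 500
  reads is not a failed library in any sense a downstream filter could
  recover.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: PCR amplification bias and polymerase error
(only breakpoint chimeras are modelled), quality-score structure (no
fastq level), taxonomic identity (contaminants are labels, not real
marine sequences), spatial autocorrelation within locations, and
compositional correlations between OTUs beyond the shared multinomial
draw.

### Known limitation: residual switching in dominant OTUs

The two correction rules are the survey's own: they cannot remove a
switched-in cell of ≥ 20 reads in a high-abundance row, nor cells of
2–19 reads in low-abundance rows. For the one or two most dominant OTUs,
expected bleed per wrong sample is `rowTotal × switchRate / (nSamples−1)`,
which at the default conditions exceeds the 20-read floor. Consequently a
habitat-specific *dominant* OTU can appear weakly present elsewhere and
be labelled `shared`; the test suite quantifies this (roughly nine of ten
specific OTUs surviving curation are labelled correctly at the default
switch rate, with the misses concentrated in the dominant tail). This is
a property of the correction rules, not of their implementation.

## Problem sizes and determinism

The test suite runs the clustering oracle on 200 random instances of up
to 50 sequences, the UniFrac oracle on 100 instances of up to 10 leaves
and 6 samples, replay/fixpoint checks on 100 random tables, the
hypergeometric fit at 500 rarefaction replicates, and the end-to-end
recovery checks on 10 generator seeds at the default configuration —
sizes chosen so each suite finishes in minutes while keeping the
statistical assertions well-powered. Every stochastic step takes an
explicit seed; one master seed reproduces an entire pipeline run,
including the manifest checksums.

```{r example, eval = FALSE}
sim <- simulateDataset(simConfig(seed = 1))
cur <- runCuration(sim$table,
                   flaggedOtus = contaminantOtuIds(sim$truth), seed = 1)
D   <- weightedUnifrac(cur$table, sim$truth@tree)
ord <- pcoaOrdination(D)
percentVariance(ord)[1:2]
```
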