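---
title: "FCGR phylogenetics: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FCGR phylogenetics: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgrphylo)
```

## The method in one paragraph

`cgrphylo` infers phylogenies without alignment by comparing oligonucleotide
composition. Each taxon's sequences are concatenated, cleaned to the
{A,C,G,T} alphabet, and the reverse complement appended; the k-mer spectrum
of that string, arranged on the Chaos Game Representation grid as a
2^k × 2^k matrix (the FCGR), is the taxon's signature. Pairwise distances
between signatures (Euclidean on standardized matrices, or weighted Pearson
on raw counts) feed Neighbor-Joining. Branch support comes from resampling
the 4^k FCGR cells with replacement — the cells act as the characters of the
classical bootstrap — followed by majority-rule consensus; branch lengths
are then fitted on the fixed consensus topology by non-negative weighted
least squares with the Fitch–Margoliash weighting 1/d².

The central assumption is the genomic-signature property: k-mer composition
is approximately stationary along a genome and diverges with evolutionary
distance. The method sees only composition — rearrangements, duplications
and indels that preserve composition are invisible to it, which is exactly
why it can compare unalignable whole-genome, EST and organellar datasets.

## Preprocessing rules and their rationale

* **Concatenation then one global reverse complement.** The reverse
  complement of the whole concatenation is appended (not per record), which
  makes count(w) ≈ count(revcomp(w)) for every word, removing strand
  asymmetry of assembly orientation. The property is exact up to a single
  junction word per k and is asserted in the tests.
* **Non-ACGT characters are deleted, the walk is not reset.** Ambiguity
  codes and Ns are removed and counting continues across the gap. This
  creates at most a handful of artificial junction k-mers per deletion and
  per record boundary; at the sequence lengths the method needs (see below)
  their contribution is negligible. Resetting the walk at every boundary
  would discard k−1 genuine windows per contig for the same benefit; for
  EST-scale record counts neither choice is detectable in the trees.
* **Case-insensitive input.** Soft-masked (lowercase) bases are kept: the
  signature should describe the whole sequence, and masking conventions
  differ between assemblies.
* **EST homopolymer masking.** cDNA libraries leave variable-length poly-A
  tails; the FCGR cells of A^k and T^k then hold mass that reflects library
  construction, not phylogeny. For EST-type inputs the two cells are set to
  zero in the *raw* counts — before standardization — so that both distance
  paths (Euclidean standardizes afterwards, Pearson reads raw counts) see
  masked values. Masking is applied at every k for EST data; the bias is
  only decisive at k > 5, but a consistent rule is simpler to reason about
  and the masked cells are 2 of 4^k.

## Tunable parameters

| parameter | default | meaning and guidance |
|---|---|---|
| `k` | 6 | word length; grid is 2^k × 2^k, 4^k cells (64 at k=3, 65,536 at k=8; capped at 8). Signal grows with k as long as the sequence is long enough to populate the cells; as a rule of thumb the sequence should be several times 4^k nucleotides. |
| `metric` | `"euclidean"` | `"euclidean"` is the root-mean-square cell difference on standardized FCGRs; `"pearson"` is 1 minus a product-weighted correlation on raw counts, range [0,2]. Euclidean is the more reliable choice on heterogeneous data. |
| `replicates` | 500 | bootstrap replicates B. 100 is enough for stable percentages in small studies. |
| `consensus_threshold` | 0.5 | a split enters the consensus when its replicate frequency strictly exceeds this; 0.5 is strict majority rule. Below 0.5 conflicting splits are possible and are resolved greedily by frequency. |
| `append_revcomp` | `TRUE` | strand symmetrization; disable only to inspect strand asymmetry itself. |
| `seed` | 1 | master seed; every replicate draws its own substream seed, so runs are byte-identical end to end and any single replicate can be reproduced in isolation. |

## Numerical choices

* **Exact counting instead of point binning.** The FCGR is computed by
  integer k-mer counting; it equals binning the floating-point CGR trail at
  points i ≥ k (asserted cell-for-cell in the tests) but cannot drift. The
  first k−1 trail points, whose history is shorter than k, are excluded;
  their contribution would be at most k−1 counts.
* **The Euclidean prefactor.** The constant in front of the Euclidean sum is
  taken as 2^k/4^k = 2^−k, turning the sum into a root-mean-square cell
  difference — dimensionally sensible and bounded. Any positive constant
  yields identical NJ and consensus topologies (rescaling a distance matrix
  never changes NJ's selection order); the suite asserts this invariance, so
  the choice is inert for trees.
* **Standardization tolerance.** Standardized matrices sum to 4^k to within
  1e−9 relative tolerance (floating-point rounding only).
* **Degenerate Pearson inputs.** A replicate whose resampled profile has
  zero weighted variance (e.g. all drawn cells equal) raises an error; the
  pipeline redraws such replicates from the next seed substream, counts
  them, and aborts after 10 consecutive failures rather than silently
  biasing supports.
* **Negative NJ branch lengths** are clamped to zero (they can arise on
  non-additive input); least-squares branch lengths are constrained
  non-negative from the start (`pracma::lsqnonneg` on the weighted
  incidence system).
* **Zero distances in the least-squares weights.** Fitch–Margoliash weights
  1/d² are undefined at d = 0 (identical profiles); such pairs get unit
  weight with a warning.
* **Ties in consensus building.** Retained splits are ordered by descending
  frequency, then lexicographically by their canonical label set, making
  consensus construction deterministic.

## The simulator: what it emulates, what it does not

`random_sequence` draws i.i.d. bases with a chosen GC content;
`random_additive_tree` pairs a random topology with its exact path-length
matrix (the Neighbor-Joining oracle: NJ must reconstruct it perfectly, and
does, to 1e−9); `evolve_sequences` evolves a root sequence down a known tree
with per-site substitution probability 1 − exp(−rate·branch length) to a
uniformly chosen different base, a Jukes–Cantor-like process.

This is deliberately minimal. The method under test consumes only k-mer
composition, so indels, rate heterogeneity, repeats and GC isochores are not
needed to exercise its code paths — but their absence matters for
interpretation: passing recovery tests on simulated data shows the pipeline
is correct and well-calibrated under its own model, not that real genomes
satisfy the genomic-signature assumption. The simulator's EST mode
(`polya_mean`) appends Poisson-length poly-A tails per record, with per-taxon
mean tail lengths drawn independently of the phylogeny — the situation in
which unmasked high-resolution trees demonstrably follow library artifacts
instead of ancestry.

Validation problem sizes were chosen to be desk-scale while leaving the
phenomena clearly visible: the headline two-clade scenario uses 8 taxa with
50 kb root sequences (leaf edges 0.05, within-clade internal edges 0.05,
central edge 0.20 substitutions/site); the 20-seed method-comparison sweeps
use 20 kb roots and 50-replicate bootstraps; EST masking sweeps use 40
records per taxon with mean tails of 100–300 nt. With 50 kb (100 kb after
reverse complement) and k = 6 (4,096 cells) each cell holds ≈ 24 counts on
average — comfortably populated; at k = 8 the same sequences are sparse
(≈ 1.5 per cell), which the bootstrap comparisons show is still sufficient,
whereas 1 kb sequences at k = 8 are not (most cells empty), reproducing the
familiar degradation of high-resolution signatures on short inputs.

## Open design points and how they were settled

* **Bootstrap semantics.** "Resampling an FCGR with replacement" is
  implemented as drawing 4^k cell indices with replacement once per
  replicate and applying the same index vector to every taxon, by direct
  analogy with the taxon-by-character bootstrap. Resampling each taxon
  independently would compare different character sets across taxa within a
  replicate and was rejected.
* **Standardize before or after resampling?** Each Euclidean replicate is
  re-standardized after resampling, so the Euclidean distance's precondition
  (cells sum to 4^k) holds inside every replicate. The configuration echo in
  the pipeline MANIFEST records this, so the alternative (resampling
  standardized values without renormalizing) can be compared externally.
* **Consensus flavor.** Strict majority (> 50%) without greedy completion,
  the common default; the threshold is configurable.
* **Supports on the point tree.** The NJ point-estimate tree is annotated
  with per-split bootstrap percentages; if its topology differs from the
  consensus, both trees are reported rather than choosing one.
* **Masking order.** Masking operates on raw counts and precedes
  standardization — necessarily, since the Pearson distance is defined on
  non-standardized FCGRs. Masked cells stay in the cell count n of the
  Euclidean mean (they are zeros, not missing values).

## Known limitations

* Composition-based distances are not additive in expectation, so NJ on
  FCGR distances is a heuristic, not a consistent estimator of the
  substitution tree; the bootstrap quantifies stability, not correctness.
* Branch lengths are in units of signature distance, not substitutions per
  site; compare them only within one tree.
* Very unbalanced sequence lengths leave short taxa with sparse
  high-resolution FCGRs; choose k so the shortest taxon still populates the
  grid, or the sparse taxa will attract one another.
* The Pearson path requires non-degenerate profiles; datasets engineered to
  a single dominant cell (or aggressive masking at k = 1) can make it
  unusable, which the pipeline reports rather than papering over.
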