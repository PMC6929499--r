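---
title: "Local perfect phylogenies and association scans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local perfect phylogenies and association scans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendroscan)
```

## The model and its assumptions

`dendroscan` works on phased binary haplotypes under the infinite-sites
model: every marker is strictly diallelic, allele 0 is ancestral, allele 1
derived, and each site is assumed to have mutated at most once in the
history of the sample. Under these assumptions and in the absence of
recombination, the derived-allele carrier sets of any two SNVs are nested or
disjoint, and the sample admits a perfect phylogeny: a rooted binary tree in
which each SNV changes state exactly once, so each carrier set is a clade.

Real genomic regions recombine, so a single perfect phylogeny rarely spans a
whole region. The method therefore reconstructs a *local* perfect phylogeny
around each focal SNV, using pairwise four-gamete compatibility to decide
how far the local tree may reach. Two SNVs fail the Four-Gamete Test when
all four haplotype patterns 00, 01, 10, 11 occur across sequences; a failure
implies recurrent mutation or recombination between the sites, and marks the
boundary of the locally tree-like neighborhood.

The reconstruction is a recursive partition rather than an estimate of the
coalescent tree: no branch lengths are defined, and nodes deeper than the
available splitting information remain unresolved as multi-sequence tips.
Sequences that are identical across the neighborhood are indistinguishable
by construction; they share a tip whose label joins their names with the
`sep` string (default `"-"`).

## Reconstruction at a focal SNV

1. **Neighborhood.** The window grows outward from the focal column, one
   adjacent SNV at a time on each side, while the candidate passes the
   four-gamete test *against the focal SNV*; each side stops just before its
   first incompatible SNV. Compatibility during expansion is tested only
   against the focal column, not mutually among window members: mutual
   incompatibility among non-focal SNVs is tolerated and resolved by the
   split order, which keeps the window a contiguous range (a requirement for
   interpreting its limits as base-pair bounds).
2. **Minimum window.** If the compatible neighborhood holds fewer than
   `min_window` SNVs, the physically nearest not-yet-included SNV adjacent
   to the window is appended until the minimum is reached (ties between the
   two sides go to the lower position, for determinism). Padding SNVs are
   classified as incompatible for ordering purposes even when they
   individually pass the test against the focal column: they lie beyond the
   first incompatibility boundary, so they are appended to the split order
   by proximity rather than admitted into the age-ordered block. The default
   `min_window` is `max(1, ceiling(0.02 * nSNV))` — with 2747 SNVs this
   gives 55 — chosen so windows scale with marker density while never
   vanishing; the ceiling is the only rounding consistent with that pair of
   numbers.
3. **Ordering.** Compatible SNVs are ordered most-ancient-first; padding
   SNVs follow, by increasing distance to the focal SNV. Age is ranked by
   the frequency of the derived allele, largest first (see *Design choices*
   below). Ties in frequency break by proximity to the focal SNV, then by
   column index; ties in distance by column index. All frequencies are
   computed over all sequences, since every row participates in every
   window.
4. **Partition.** One pass over the ordered SNVs maintains the active
   clusters (initially one cluster of all sequences). Each SNV splits every
   active cluster that is polymorphic at it into the allele-0 and allele-1
   subclusters; an SNV monomorphic within a cluster is skipped for that
   cluster, so every internal node is strictly binary. Each internal node
   records its splitting SNV and a creation rank (1 = first split). The
   allele-0 child is written first in Newick output; this affects the text,
   not the topology.

A region scan (`reconstruct_region()`) repeats this at every focal SNV, or
at every focal SNV inside inclusive base-pair bounds; windows may extend
beyond the bounds, which restrict focal SNVs only.

## Rank distances and cluster cuts

`rank_distance_matrix()` converts a tree to pairwise distances using only
the ranking of its nested partitions: with `L` the number of internal nodes
on the deepest root-to-tip path, a pair first separated at an internal node
at depth `r` (root split `r = 1`) receives `(L - r + 1)/L`; sequences
sharing a tip receive 0. Root-separated pairs are thus at distance 1 and
deeper separations are closer. The exact functional form is a convention —
any strictly decreasing function of `r` induces the same Mantel, dCor, HHG
and RV permutation tests, because the same form is used on both sides of
every comparison — so only the monotone structure is load-bearing, and the
normalized range `(0, 1]` was chosen for readability.

`cut_clusters(tree, k)` replays the recorded splits in creation-rank order
and stops after `k - 1` of them, the analogue of cutting a dendrogram at
successively lower heights; `k` equal to the tip count returns the tip
partition. Trees with fewer than `k` tips fall back to their tip partition
with a warning, since the requested splits do not exist.

## Association profiles and the omnibus test

Five statistics are implemented in-package:

* **Rand index** between two partitions: the proportion of sequence pairs
  on which the partitions agree (together in both or apart in both).
* **Mantel**: Pearson correlation of the strict upper triangles.
* **RV**: `tr(S1 S2) / sqrt(tr(S1^2) tr(S2^2))` on the Gower-centered
  cross-product matrices `S = -1/2 J D^2 J`.
* **dCor**: sample distance correlation computed directly from the two
  matrices by double-centering; when either distance variance is zero the
  statistic is defined as 0, and a (numerically) negative `dCov^2` — which
  can arise for matrices that are not exact Euclidean distances — is clamped
  at zero.
* **HHG**: for every ordered pair (i, j) the remaining points are
  cross-classified by `d(i,k) <= d(i,j)` in each matrix (ties inclusive;
  `k = i, j` excluded) and the 2x2 Pearson chi-square statistics are summed;
  zero-margin tables contribute 0.

All five align their inputs by sequence name and are invariant to a
simultaneous reordering of both sides. Each is verified in the test suite
against an independent brute-force implementation (direct formulas, explicit
centering projectors, a literal triple loop for HHG) to 12 decimal places,
with the Rand index exact.

With `nperm > 0` the region-wide omnibus null hypothesis — no association
anywhere in the region — is tested by permutation. The summary functional is
the **maximum** of the per-SNV profile, the standard scan statistic for
"any association across the region"; the mean was rejected because it
dilutes localized signals, which are the signals this method exists to find.
The permutation unit is the comparator's sequence labelling (equivalently a
joint row/column permutation of the comparator matrix): the reconstructed
trees are fixed, so the dependence among the per-SNV statistics induced by
overlapping windows is preserved exactly under the null. The p-value uses
the add-one estimator `(1 + #{perm max >= obs max}) / (nperm + 1)`, which
never returns 0 and is never smaller than `1/(nperm + 1)`. Degenerate focal
SNVs (a fully collapsed tree gives an all-zero distance matrix) yield `NA`
under Mantel and are excluded from profile maxima; dCor and RV return 0
there by the zero-variance convention.

## Design choices where the design was open

**Age ordering by derived-allele frequency.** "Most ancient first" needs an
observable proxy for allele age. Under the infinite-sites model the age of a
mutation is reflected in its derived-allele frequency, and with 0/1-coded
data the derived allele is known by construction. The minor allele frequency
is the common field proxy (it is identical whenever the derived frequency is
below one half) but *inverts* the ranking for old variants that have drifted
above 0.5: a derived allele at frequency 0.9 is old, yet its MAF of 0.1
would sort it youngest. Ordering by decreasing derived-allele frequency
keeps carrier sets processed largest-first, which yields a provable
guarantee on recombination-free data: every split's derived-carrier set is
exactly a clade of the generating genealogy (processed largest-first,
carrier sets of a laminar family can never straddle an active cluster). The
test suite checks this recovery property on 200 simulated datasets. Under
MAF ordering the guarantee fails precisely in the drifted-above-half corner
case.

**What recovery does and does not mean.** Even with correct ordering, the
reconstructed tree's node set is not a subset of the genealogy's clades:
when no mutation fell on an intermediate branch, the residual (allele-0)
side of a split can be a clade minus a subclade, which is no branch of the
true tree. The guarantee above — each *carrier-side* bipartition is a true
branch bipartition — is the sharpest property the data can support, and is
the one asserted in the tests.

**Omnibus summary and permutation scheme** are described above; both are
deliberate choices among defensible alternatives, and are documented rather
than configurable, to keep reported p-values comparable across analyses.

**Coded-allele semantics.** "Derived" means allele 1 as coded (ALT in VCF
input). No frequency-based recoding is performed; with misspecified
ancestral states the method remains well-defined, but the age ordering
becomes the MAF-style approximation for the affected columns.

**Strictly increasing positions** are required at construction. The
windowing logic orders candidates by physical distance, which is ill-defined
under duplicated positions, so duplicates are rejected rather than ties
broken silently. Monomorphic columns are accepted (they can never split a
cluster) and are not filtered at load.

**VCF conventions.** Each diploid sample contributes rows `<sample>_1` and
`<sample>_2` from the phased GT field; multi-allelic records, missing
genotypes, unphased separators, and multi-chromosome files are rejected with
errors naming the offending record, because each would silently corrupt the
0/1 coding or the windowing.

## The synthetic-data generator

`simulate_genealogy()` builds a random topology by iterative uniform
pairwise joins (a Yule process); `drop_mutations()` places each SNV on a
uniformly chosen branch, making the derived carriers exactly the leaves
below it; `simulate_region()` draws SNV positions uniformly over a 2-Mbp
region (the scale of a population fine-mapping region) and, given
recombination breakpoints, assigns an independent genealogy per segment,
redrawing (up to a cap) until every adjacent segment pair exhibits at least
one incompatible cross-boundary SNV pair, so the windowing always has a
boundary to detect. `simulate_phenotype()` assigns binary phenotypes by a
logistic model on the count of derived alleles at SNVs inside a causal
window (default 950-1050 kbp), with the intercept centered at the sample
mean count so phenotypes are roughly balanced; the phenotypic distance is
the 0/1 mismatch indicator.

The generator emulates the *structure* that the method consumes — nested
clades, infinite-sites coding, recombination boundaries, causal subregions —
not the full coalescent: there are no branch lengths or waiting times
(reconstruction uses none), mutation placement is uniform over branches
rather than proportional to branch duration, there is no selection or
mutation-rate heterogeneity, and recombination is a fixed set of breakpoints
rather than a Poisson process. Passing tests therefore demonstrate
correctness of the algorithmic contracts on infinite-sites-like data; they
do not certify behavior under gene conversion, genotyping error, phase
switch errors, or recurrent mutation, all of which violate the model's
assumptions.

## Numerical choices and degenerate inputs

* Statistic implementations are deterministic linear algebra; tests compare
  them with independent oracles at `1e-12`.
* `dcor_stat` clamps negative `dCov^2` at zero; Mantel raises an error on a
  constant upper triangle when called directly, and propagates `NA` inside
  profiles; RV errors on an all-zero configuration.
* A single-tip tree yields an all-zero rank-distance matrix (not an error),
  so null scans over monomorphic stretches degrade gracefully.
* All simulation and permutation randomness flows through explicit seeds;
  the generators restore the caller's RNG state, and identical seeds give
  byte-identical outputs (asserted in the tests).
* Permutation p-values are add-one, so the attainable minimum with
  `nperm = 999` is 0.001.

## Problem sizes in the test suite

The suite exercises the method at sizes chosen to make the statistical
checks sharp yet quick on a single CPU: exhaustive four-gamete verification
over all pairs of 6-sequence columns; 200 recovery replicates at 12
sequences by 30 SNVs; omnibus size at 20 sequences by 40 SNVs with 199
permutations and 500 null replicates (rejection rate compared with the 99%
binomial band around the nominal 5%); and localization power at 30 sequences
by 100 SNVs with a strong (4 log-odds per allele) causal effect in the
950-1050 kbp window, 100 replicates, requiring the dCor profile maximum to
fall inside the causal window in a majority. The full suite runs in under
two minutes; `scripts/acceptance.R` re-runs the headline analyses in about
one minute.

## Known limitations

* Phasing and imputation are out of scope: the method requires complete,
  phased, strictly diallelic input and rejects anything else.
* Windows are contiguous and grown by focal-SNV compatibility only;
  linkage-disequilibrium- or recombination-map-guided windows are not
  implemented.
* The region scan reconstructs each focal window from scratch; successive
  windows share most of their SNVs, so scan time grows linearly in SNVs and
  roughly quadratically in sequences. Caching shared partitions would speed
  this up and is future work.
* Per-SNV pointwise p-values (with multiple-testing control) are not
  provided; the omnibus test answers only the region-wide question.
* Rank distances carry no branch-length information; cophenetic distances
  are undefined here.
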