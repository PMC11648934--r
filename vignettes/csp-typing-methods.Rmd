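---
title: "Residue-anchor typing of cold-shock proteins: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-anchor typing of cold-shock proteins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csptyper)
```

## The problem

Bacterial cold-shock proteins (Csps) are small (~70 aa) nucleic-acid-binding
proteins built on the cold-shock domain (CSD), an OB-fold carrying the RNP1
and RNP2 RNA-binding motifs. Members of one genome's Csp repertoire are
nearly identical in composition yet act on different RNA targets. Two
sequence features are diagnostic of that target specificity:

* the **loop pair** — the two residues at the positions homologous to
  CspD 43–44 (equivalently CspA 46–47). Lysine–alanine (`K-A`) marks
  CspD-like proteins, aspartate–glutamate (`D-E`) CspA-like proteins, and
  lysine–glutamate (`K-E`) a separate cluster with its own specificity;
* the **N-terminal K4** — a lysine at the position homologous to CspA
  residue 4, inside the unstructured N-terminal extension that CspD-type
  proteins lack.

`csptyper` projects these *anchors* through a multiple sequence alignment
to type whole families, asks whether the resulting types are monophyletic
on a phylogeny, relates per-genome Csp counts to genome size and GC
content, and implements the band-quantitation arithmetic used to measure
specificity experimentally.

## Anchors and coordinate mapping

An anchor is `(ref_id, ref_pos)`: a 1-based residue position in the
*ungapped* reference sequence (the convention of names like "K43").
`column_of()` locates the alignment column holding the `ref_pos`-th
non-gap character of the reference row; `residues_at()` then reads the
homologous residue in every row. All columns are 1-based, matching R
indexing; the 0/1 ambiguity that plagues coordinate code is avoided by
having a single convention everywhere.

Gap-rich columns can be removed with `trim_columns(aln, max_gap_frac)`,
which keeps exactly the columns whose gap fraction is at most the
threshold and records a **provenance map** (current column → original
column). Provenance composes across repeated trimming, so any trimmed
coordinate can be traced back. Two policy decisions matter here:

* **anchors are resolved on the untrimmed alignment.** Trimming exists to
  stabilise distance computation, not typing; resolving anchors before
  trimming guarantees a diagnostic column can never be silently lost. If a
  trimmed alignment is supplied to `resolve_anchors()`, anchors are mapped
  through provenance and any anchor whose column was removed is explicitly
  marked `trimmed` (never remapped to a neighbouring column);
* **default `max_gap_frac = 0.8`**: columns missing in more than 80% of
  rows carry little distance signal and mostly reflect rare insertions.
  The threshold is a tunable fraction in [0, 1], not a fitted value.

## Residue typing

`classify_loop(first, second)` is a total function on residue pairs:

| pair | label |
|------|-------|
| K, A | `K-A` |
| K, E | `K-E` |
| K, other | `K-other` |
| D, E | `D-E` |
| gap at either | `unaligned` |
| anything else | `other` |

The ambiguity code `X` at either position yields `other` rather than an
error or a `K-*` call — real protein sets contain ambiguity codes, and an
unknown residue should not assert a type. `tally_types()` reports counts
and percentages per label (one decimal place), the share of lysine-first
records whose second residue is A or E (denominator: labels `K-A`, `K-E`,
`K-other` only, mirroring the "K-X proteins" convention; gapped records
are excluded), and the dual-lysine count (loop-first K *and* K4 — the
combination that is rare in nature because the two signatures belong to
different subfamilies). The per-protein table always carries the raw
anchor residues next to the label so alternative typings can be derived
without re-resolving the alignment.

## Variant construction

`fuse()` and `point_mutate()` build the chimeric and point-mutant
sequences used to validate anchor residues experimentally (e.g. swapping
a K-A loop to D-E and observing the classification flip). Junctions are
explicit `(left_end, right_skip)` pairs: the N-terminal cross-mapping
between two parents is figure-derived information, so the shipped
CspA/CspD junction panel (`inst/extdata/chimera_junctions.tsv`) is
editable configuration assuming a uniform −3 offset between CspA and CspD
numbering, not hard-coded truth.

## Trees and monophyly

The package builds distance trees as a desk-scale stand-in for
maximum-likelihood inference: p-distances (mismatches over both-ungapped
sites) on the trimmed alignment, Poisson-corrected as $-\ln(1-p)$ with
saturation capped at $p = 0.95$ (flagged with a warning), then Saitou–Nei
neighbor joining. Externally inferred Newick trees are accepted
everywhere a tree is consumed, so users can reproduce an ML workflow
upstream and only use the typing/monophyly machinery here.

Determinism of `nj_tree()` is part of its contract: Q-criterion ties are
broken by the smallest (i, j) pair in current node order, and a negative
branch length is clamped to zero with the deficit moved to its sibling so
the joined pair's path length is preserved (at the final trifurcation,
negative three-point solutions are clamped to zero). On additive
distances NJ recovers the generating topology and branch lengths exactly,
which the tests exploit as an oracle; the package's NJ is also
cross-checked against an independent implementation (`ape::nj`) on
non-additive matrices.

Monophyly uses the unrooted-tree criterion: a leaf subset is monophyletic
iff it (or its complement) is one side of a bipartition induced by some
edge. `bipartitions()` enumerates internal edges and canonicalizes each
split to the side not containing the lexicographically smallest leaf;
internal node labels (support values) are ignored. Because a strict
verdict can hide a near-miss, `monophyly_gap()` also reports the minimal
number of mismatched leaves between the subset and the best available
split — 0 exactly for monophyletic sets. No support thresholds are
attached to the verdicts.

## Genome distribution statistics

Genomes are split at a Csp-count threshold (default 3: "one or two"
versus "three or more"); genomes with zero Csps are outside the universe
and dropped with a warning. Size and GC are compared with the package's
Mann–Whitney U test:

* `U` is the smaller of the two U statistics from midrank sums;
* **exact mode** fully enumerates all `choose(n+m, n)` group assignments.
  It is used automatically when the smaller sample has ≤ 8 observations
  and there are no ties — the cutoff keeps enumeration at ≤ C(16,8) =
  12,870 arrangements; ties force the approximation (requesting
  `mode = "exact"` with ties is refused rather than silently changed);
* otherwise the **normal approximation** with tie-corrected variance and
  a 0.5 continuity correction is used; if every observation is tied the
  variance vanishes and p = 1.

The comparison is always nonparametric. Normality screening is
deliberately not implemented: genome size and GC distributions fail
normality tests at scale, making the rank test the terminal choice, so
implementing screens whose only role is to justify it would add two tests
that never change the decision. Medians and IQRs are the primary
summaries (matching the rank-based test); means are reported alongside
for comparability with mean-based narratives. An empty group yields an
explicit "not testable" report, never a fabricated p-value.

## Quantitation arithmetic

`relative_levels()` divides each lane's band intensity by the reference
sample's intensity *in the same replicate* (the reference is 1 in every
replicate by construction), optionally after per-lane division by a
loading-control probe (e.g. tmRNA). Loading-control normalization is off
by default because relative levels are defined directly against a
reference lane; a common per-replicate gain factor cancels either way.

The specificity score is the relative efficiency for the CspD-type target
(`baxL` level relative to the CspD reference) minus that for the
CspA-type target (`gdx` level relative to the CspA reference). Scores are
computed **per replicate and then averaged** (mean ± SD); the alternative
— scoring the replicate-averaged levels — gives the same mean but no
replicate error on the score. The per-replicate convention propagates
replicate noise into the reported SD and is labelled in the output
manifest. Readthrough is `100·RT/(T+RT)`; the pull-down enrichment ratio
is the bound-fraction sum over the crude-extract sum of the listed
component bands (full-length plus truncated where applicable), per
replicate, then averaged.

## The synthetic-data generators

`simulate_family()` emulates the structure the analysis assumes, not Csp
evolution in general:

* the ancestor is a canonical CSD core (a CspA-like 65-residue consensus;
  the two motif blocks standing in for RNP1/RNP2 are held invariant);
* one random Yule-style subtree per residue type, joined at the root —
  so the planted K-A members form a true clade and the K-E members a true
  cluster by construction;
* per-site per-edge substitution with probability `sub_prob` (default
  0.05, the upper end of the regime in which clade recovery is expected),
  uniform over the 19 alternative residues;
* loop anchors are overwritten by the planted type after evolution
  (mutation-protected anchors), "other" members drawing their loop pair
  from the variety observed across *E. coli* Csps (F-E, A-E, T-T, N-E,
  I-P, T-E);
* core evolution is indel-free and the type-specific N-terminal
  extensions have fixed lengths (CspA-like tail with K4 on `D-E`
  members; short tail with alanine at position 2 on `K-E` members), so
  the true alignment is known exactly as left gap-padding of the
  extension block.

What this does **not** emulate: indels inside the core (so alignment
inference is never tested — it is out of scope by design), empirical
substitution preferences, rate heterogeneity, and anchor-site mutation.
Passing tests therefore demonstrate that the *pipeline* recovers planted
structure, not that real Csp families are this clean; on real data the
anchors are not protected and typing fidelity degrades with alignment
quality at the anchor columns.

`simulate_genomes()` draws Csp counts on 1..10 with defaults skewed so
about two thirds of genomes carry one or two Csps (matching the observed
low/high ratio), and applies the planted effect — size ×(1+`size_shift`),
GC +`gc_shift`, defaults +30% and +0.05 — to the high-count group before
lognormal/Gaussian noise (σ = 0.2 on log-size, 0.04 on GC, around a
4-Mb/0.50 baseline). `simulate_quant()` plants per-sample relative
efficiencies (defaults: strong target 1.0 vs weak 0.2, a 5-fold
contrast) under multiplicative lognormal noise (σ = 0.15, 3 replicates).
All generators are pure functions of their arguments including the seed.

## Problem sizes and numerical checks

The shipped checks run at desk scale, chosen to make the statistical
assertions sharp while keeping the whole suite interactive: 40-member
families over 50 seeds for clade/typing recovery; 50 random additive
6-leaf trees for NJ exactness (tolerance 1e-9); 200 random (tree, subset)
pairs against exhaustive split enumeration; 2,000 null replicates at
n = 30/30 for Mann–Whitney calibration (rejection expected in
[0.03, 0.07] at α = 0.05); 200 seeds for score-sign recovery at σ = 0.15;
500 randomized gap-insertion/trimming cases for coordinate invariance.
`scripts/acceptance.R` recomputes the same quantities from scratch at any
seed.

## Known limitations

* NJ over Poisson-corrected p-distances is a stand-in; for publication
  trees use external ML inference and feed the Newick tree in.
* Deduplication is exact (100% identity on the ungapped protein);
  similarity clustering below 100% is out of scope.
* The monophyly verdict is strict; use `monophyly_gap()` when a small
  number of intruding or excluded taxa should be tolerated and judged by
  the analyst.
* RefSeq-scale ingestion (GenBank parsing, homology search, MSA
  construction) is outside the package; it consumes sequences,
  alignments and trees that such a workflow produces.
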