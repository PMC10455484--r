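---
title: "CYPome curation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CYPome curation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypome)
```

This vignette documents the scientific procedure the package
implements, the parameters that matter, the numerical conventions, and
the design choices that were genuinely open. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## The curation model

A CYPome survey starts from a candidate list (in practice, the hits of
a P450 InterPro domain search; here, any amino-acid FASTA). Curation is
rule-based:

* **Signature motifs.** Cytochrome P450s carry a K-helix
  Glu-x-x-Arg (ExxR) salt bridge and a heme-binding region whose axial
  cysteine sits in a Cys-x-Gly context near the C-terminus. `scan_motifs()`
  searches ExxR anywhere and CxG only in the C-terminal third of the
  sequence. The window is a deliberate design choice: Cys-x-Gly is a
  weak three-residue pattern (about one spurious match expected per 400
  residues), and the heme ligand is structurally confined to the
  C-terminal region, so the restriction removes essentially all
  spurious matches without losing true ones. Both patterns are
  configurable regular expressions in `cypome_rules()`. An `X` residue
  can occupy a wildcard position but never a fixed one.
* **Triage.** Both motifs and length ≥ 350 residues → `P450`; exactly
  one motif, or both motifs on a shorter sequence → `FRAGMENT`; no
  motifs → `FALSE_POSITIVE` when the candidate still aligns at ≥ 20 %
  identity to a named reference (a degenerate P450-like sequence),
  otherwise `NO_HIT`. The false-positive/no-hit split is a heuristic of
  this package — the published curation protocols distinguish the two
  classes without defining the boundary — and the 20 % threshold is
  exposed in `cypome_rules()` and recorded in the triage report.
* **Nomenclature.** Percent identity to the best named reference
  drives family and subfamily membership with the International P450
  Nomenclature thresholds (40 % / 55 %). The published rule is stated
  as ">40 %" for family *and* "less than 40 %" for a new family,
  leaving exactly 40 undefined; we resolve the boundary conservatively:
  identity ≥ 40 keeps the family, identity > 55 keeps the subfamily.
  Ties between references break to the lexicographically smallest CYP
  name. Queries below the family threshold receive placeholder labels
  `NEWFAM1`, `NEWFAM2`, ... in query order; real CYP numbers are
  allocated by the nomenclature committee and are out of scope.
* **Borderline resolution.** Identities within ± 2 % of the subfamily
  threshold are flagged. Manual curation resolves such calls on a
  phylogeny; `assign_cohort()` automates this by overriding the
  subfamily with that of the nearest named leaf (path length, ties by
  label) when a tree is supplied.

## Alignment and identity conventions

Global Needleman–Wunsch alignment under BLOSUM62 with affine gaps
(open 10, extend 1; a gap of length $L$ costs $10 + L$) is computed by
`Biostrings::pairwiseAlignment()`; the scoring scheme is fixed and
recorded in the rule set. Percent identity is

$$\mathrm{pid} = 100 \times
  \frac{\#\{\text{identical aligned columns}\}}
       {\#\{\text{columns excluding terminal-overhang gaps}\}},$$

i.e. leading/trailing gap runs of either sequence are excluded from the
denominator while internal gaps count. The exclusion approximates the
identity a local aligner (BLAST) would report over its HSP when one
sequence is a sub-fragment of the other — a full-length query against
its own first half is 100 % identical. Because co-optimal global
alignments can differ in column identities, `percent_identity()` feeds
the two sequences to the aligner in canonical (lexicographic) order,
making the measure symmetric by construction. The test suite checks the
aligner's scores against an independent brute-force Gotoh dynamic
program on random pairs.

## Phylogeny

Trees are built by Saitou–Nei neighbor joining (`ape::nj`) on the
identity distance $d = 1 - \mathrm{pid}/100$. Neighbor joining is exact
on additive matrices (verified in the suite to $10^{-9}$ on random 5–8
leaf trees) and fully deterministic, which is all the pipeline needs:
the only consumer is the nearest-named-leaf relation for borderline
calls. Negative branch-length estimates, which NJ can produce on
non-additive input, are clamped to zero. No bootstrap support is
computed. The original workflow aligned with MAFFT and inferred a "best
tree" on a web service with unstated parameters; a deterministic
distance method was chosen here so that results are reproducible from
the package alone.

## Conservation and comparison

The species × family matrix codes presence as 3 and absence as −3, the
convention of MeV-style heatmap viewers (`write_presence_tsv()` emits a
directly importable TSV). Both axes are clustered by average-linkage
(UPGMA) agglomeration on Euclidean distances. Two-valued matrices
produce many exactly tied merge candidates, so determinism requires a
pinned tie rule: the package's agglomerator always merges the closest
pair and resolves ties (grouped within $10^{-9}$ to absorb float
summation-order noise) towards the clusters containing the smallest
original row indices. The merge heights are checked against a
quadratic from-scratch oracle in the suite. The linkage itself was an
open choice — the source heatmaps name only the Euclidean metric — and
average linkage (the common MeV default) was selected; only the leaf
orderings are consumed downstream. Fragments are excluded from all
family-level statistics: the shipped family tables are consistent with
full-length P450 counts only.

Lifestyle comparison is exact set algebra (`venn_partition()`), with
`venn_from_counts()` covering the case where only printed group totals
and the shared count are available. All reported averages round half
away from zero (`round_half_away()`), the convention that reproduces
every printed mean in the packaged tables (e.g. 580/19 → 31); base R's
`round()` would give 30.

## BGC cross-referencing

Cluster predictions enter as a flat TSV (species, cluster index, type,
member genes with 1-based inclusive coordinates) — the minimal contract
any anti-SMASH export can be reduced to; the package never runs cluster
prediction itself. Hybrid types are comma-joined tokens ("NRPS,T1PKS")
that count once in cluster totals but once per token in per-type
tallies. P450 occurrences in clusters are counted per membership row,
not per distinct name (a P450 name recurring in two species counts
twice), matching how the packaged cluster table lists them.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` plants, per species: family members derived from
divergent founder references (pairwise identity < 35 %) by
substitution-only mutation into three identity bands — [60, 75] (same
subfamily), [42, 54] (same family), [20, 35] (new family) — with motif
positions protected; fragments made by truncating below 350 residues or
ablating every ExxR occurrence; decoys drawn from an E/C-free alphabet
(random 20-letter sequences of realistic length almost surely contain
an ExxR by chance, so exclusion of the fixed-position residues is the
only way to guarantee motif-free negatives); degenerate sequences made
by ablating both motifs from a mid-identity member; and BGC tables with
planted P450 member genes. Default sequence lengths are 450–550
residues, the typical span of fungal P450s, and the default lifestyle
split keeps roughly a quarter of species saprotrophic, a class
imbalance like the one in the packaged census. The bands deliberately
stay at least 1 % clear of both nomenclature thresholds, so planted
labels are recoverable without boundary ambiguity — the generator's own
validator enforces this, and the lower edge of the new-family band
stays above the 20 % false-positive heuristic. One founder family is
planted in every species so conservation queries have a known positive.

Substitution-only mutation keeps identity monotone in the number of
changed positions, which makes band targeting a short deterministic
search; indel robustness is exercised separately with hand-built gapped
homologs in the nomenclature tests. What the generator does **not**
emulate: realistic substitution processes (no BLOSUM-weighted
exchanges), gene structure, genomic context, paralog phylogenies inside
a family, or reference sets with multiple subfamilies per family.
Passing the end-to-end recovery tests therefore demonstrates that the
rule engine is implemented correctly, not that the rules themselves are
robust on real, messier proteomes.

## Problem sizes and determinism

Every stochastic test and the acceptance script run under fixed seeds.
The suite uses compact cohorts (3–4 species, 3–4 founder families,
one–two members per planted family) so the full run stays well under a
minute of alignment work; the acceptance script additionally generates
a 19-species cohort whose per-species P450 counts are set to the
packaged census column (668 members) and pushes it through triage and
summary statistics. Alignment of one ~500-residue pair costs a few
tens of milliseconds, which dominates all timings.

## Known limitations

* Only two signature motifs are scanned; some curation protocols also
  use the I-helix threonine. The rule set accepts custom patterns but
  the triage contract is defined for two motif classes.
* Identity is computed on full-length global alignments (with terminal
  overhang exclusion), not on BLAST HSPs; for highly diverged or
  multi-domain sequences the two conventions can differ by a few
  percent around the thresholds — exactly the region the borderline
  flag is designed to catch.
* New-family placeholder labels are assigned per query, not by
  clustering mutually similar new-family queries into shared novel
  families.
* The BGC module consumes cluster predictions; it does not validate
  them or predict boundaries.
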