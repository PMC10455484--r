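# cypome

Curation and comparative analysis of fungal cytochrome P450 complements
(CYPomes) in R.

Cytochrome P450 monooxygenases (CYPs/P450s) are heme-thiolate enzymes
whose genomic complement reflects a species' lifestyle. Surveying the
CYPome of a genome is a manual-curation exercise with well-established
rules, and this package implements that whole workflow as tested,
scriptable functions:

1. **Identification and triage.** Candidate proteins are scanned for the
   two P450 signature motifs — the K-helix ExxR salt bridge and the
   heme-binding CxG motif carrying the axial cysteine, searched in the
   C-terminal third of the sequence. A candidate with both motifs and at
   least 350 residues is a *P450*; one with a single motif, or both
   motifs but a short sequence, is a *P450 fragment*; motif-free
   candidates are split into *false positives* (degenerate P450-like
   sequences, ≥ 20 % identity to a named reference) and *no hits*.
2. **Nomenclature.** Curated P450s are assigned families and subfamilies
   against a named reference set by global-alignment percent identity
   (BLOSUM62, affine gaps), following the International P450
   Nomenclature thresholds: identity > 40 % places a query in the best
   reference's family, > 55 % also in its subfamily, and below 40 % it
   founds a new family (placeholder labels; official numbers are
   committee-assigned). Calls within ± 2 % of the subfamily threshold
   are flagged *borderline* and can be resolved on a phylogeny.
3. **Phylogeny.** Neighbor-joining trees on identity distances
   (d = 1 − identity/100), Newick IO, and nearest-named-leaf queries for
   borderline subfamily resolution.
4. **Comparative analysis.** Species × family presence/absence matrices
   (coded 3/−3, the MeV heatmap convention), deterministic
   average-linkage clustering of both axes, family conservation queries,
   saprotroph (SAP) vs ectomycorrhizal (ECM) Venn partitions, and
   rounded summary statistics.
5. **BGC cross-referencing.** P450s are placed inside secondary
   metabolite biosynthetic gene clusters from simplified cluster tables
   (the flat TSV any anti-SMASH export reduces to), with per-species and
   per-type tallies.
6. **Synthetic cohorts.** A seeded generator plants families at
   controlled identity bands, fragments, decoys and cluster memberships,
   so every stage is testable end-to-end with known ground truth — no
   genome downloads required.

The package also ships transcriptions of a published 19-species
Pezizomycete CYPome census (per-species curation counts, per-family
member counts, per-species family counts, BGC counts) as fixtures, with
all of their headline aggregates recomputed by code.

## Worked example

```r
library(cypome)

# a seeded synthetic cohort with known planted labels
spec <- synthetic_spec(seed = 42, n_species = 3, n_founder_families = 3,
                       fragment_rate = 0.2, decoy_rate = 0.2)
cohort <- generate_cohort(spec)
cohort
#> Synthetic cohort: 3 species, 19 proteins (13 planted P450s), 10 BGCs

# triage one proteome against the named references
sp1 <- cohort$proteins[cohort$proteins$species_id == "SP01", ]
tri <- triage_proteome(sp1, references = cohort$references)
tri$counts
#>      total_hits           p450s       fragments false_positives         no_hits
#>               5               3               1               0               1

# family/subfamily assignment of the curated P450s
p450_ids <- tri$results$protein_id[tri$results$category == "P450"]
asg <- assign_cohort(sp1[sp1$id %in% p450_ids, ], cohort$references)
asg[, c("query_id", "family", "subfamily", "best_ref", "identity")]
#>     query_id  family subfamily  best_ref identity
#> 1 SP01_g0001 CYP9001         A CYP9001A1    67.47
#> 2 SP01_g0002 CYP9001         A CYP9001A1    67.47
#> 3 SP01_g0003 CYP9001       NEW CYP9001A1    47.99
```

The first two members sit above the 55 % subfamily threshold and inherit
`CYP9001A1`'s subfamily; the third sits between 40 % and 55 % and keeps
the family with a `NEW` subfamily — exactly the planted truth.

The packaged census tables work the same way:

```r
summary_stats(load_fixture("table4"), family_counts = load_fixture("table5"))
#> Total 668; mean 35; range 17 (Terfezia claveryi T7) - 58 (Ascobolus immersus RN42)
#>   ECM: total 464, mean 33, range 17-55
#>   SAP: total 204, mean 41, range 28-58
#>   bloomed families: CYP567, CYP6001, CYP52, CYP5959
```

A thin command-line wrapper with `triage`, `assign`, `tree`, `conserve`,
`compare`, `bgc`, `simulate` and `paper-stats` subcommands is installed
at `inst/scripts/cypome.R`.

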