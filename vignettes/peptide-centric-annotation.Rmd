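---
title: "Peptide-centric taxonomic and functional annotation of metaproteomes"
author: "metapep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide-centric taxonomic and functional annotation of metaproteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapep)
```

## The problem

Bottom-up metaproteomics of a microbial community identifies *peptides*.
Each identified peptide is consistent with a whole group of database
proteins (the "protein group" a search engine such as MaxQuant reports),
and those proteins may come from different strains, species, or phyla.
Any taxonomic statement about the peptide must therefore be the most
specific statement consistent with *every* member of its group. When the
reference database is built from cultivated, fully sequenced per-strain
proteomes, every protein carries a complete lineage, and the natural
assignment is the lowest common ancestor (LCA) of the group's lineages.
`metapep` implements this workflow end to end: reference construction,
LCA annotation, intensity-weighted profiling, and consensus functional
annotation with pathway-level enrichment.

## The reference database

`mergeProteomes()` concatenates per-strain proteome FASTAs and attaches a
lineage (and optionally a KEGG ortholog, KO) to every protein.
`deduplicateExact()` then removes duplicate sequences at 100% identity
over the full length. At that threshold, sequence clustering reduces
exactly to string-equality deduplication, so the operation is implemented
as a hash on the raw sequence strings: residue `X` is kept verbatim and
no I/L equivalence is applied. Among duplicates, the retained
representative is the record whose protein id sorts first in the C
locale — an arbitrary but deterministic choice, since no biological
criterion distinguishes identical sequences. Every retired id is recorded
in `dedupMap()`, so search results produced against the pre-deduplication
database still resolve. Deduplication is global (within and across
strains); the combined collection is treated as one sequence space.

## The rank ladder and the LCA

Lineages live on a fixed eight-level ladder: root, superkingdom, phylum,
class, order, family, genus, species. Intermediate unranked nodes are not
modelled — a cultivated-reference annotation table is a flat rank table,
and the ladder is what its columns provide. Two taxa are the same node
iff their (rank, name) pair matches, which avoids any dependence on an
external taxonomy dump; the cost is that name normalization matters, so
legacy/current phylum synonyms (Firmicutes/Bacillota,
Bacteroidetes/Bacteroidota, Actinobacteria/Actinomycetota,
Tenericutes/Mycoplasmatota, Proteobacteria/Pseudomonadota) are mapped to
one canonical vocabulary *before* any comparison. The table ships as an
editable TSV in `system.file("extdata", "phylum_synonyms.tsv", package =
"metapep")`.

`lca()` walks the ladder from the top and stops at the deepest rank on
which all lineages agree. One convention departs from the plain prefix
walk: agreement *only at superkingdom* is reported as `("root", "Root")`.
In a bacterial reference essentially every protein group agrees at
superkingdom, so a superkingdom-level result carries no information;
folding it into Root keeps the rank distribution honest. A consequence
worth stating: annotation coverage is 100% by construction. Every
resolvable peptide gets an assignment — at worst the uninformative Root —
and there is no "N/A" state in this path. An unresolvable protein id is
treated as a database/result mismatch and raises an error rather than a
missing value.

### Duplicates, homologs, and what the LCA can see

Protein-group ids are resolved through `dedupMap()` *before* lineage
lookup. This mirrors what a search against the deduplicated database
would report, and it has a subtle consequence: exact sequence duplicates
collapse to a single representative lineage, so they can never coarsen an
LCA. The multi-strain history of an identical sequence is genuinely lost
at deduplication time — the database no longer knows which other strains
carried it. What does coarsen LCAs in practice are *near-identical
homologs*: proteins that differ somewhere, survive exact deduplication,
and still share most of their tryptic peptides. The synthetic generator
plants both kinds (see below) precisely so that tests exercise both the
resolution machinery and genuine LCA collapse.

## Profiles and ratios

`compositionAtRank()` aggregates peptide intensity by the taxon at a
requested rank. Peptides whose LCA is coarser than that rank go into an
explicit `"Unannotated-at-rank"` bin rather than being dropped silently:
this keeps total intensity conserved, which in turn makes conservation
testable (fractions sum to 1 within 1e-9; totals match within 1e-6
relative). Taxa below `othersThreshold` (default 0.02, i.e. 2% relative
abundance, the conventional cutoff for "others" in family-level gut
profiles) are merged into `"others"`.

`fbRatio()` is the Bacillota/Bacteroidota (Firmicutes/Bacteroidetes)
summed-intensity ratio per sample — undefined, and an error, when the
Bacteroidota intensity is zero. `mhRatio()` divides microbial by host
intensity. Peptides matching both microbial and host proteins are
classed `"ambiguous"` by `classifyOrigin()` and excluded from both sides
of the ratio and from microbial profiling: counting them on either side
would double-count evidence that cannot be attributed. Group-level
summaries (e.g. per-subject means of these ratios) are arithmetic means
over samples.

## Consensus KO and pathway enrichment

`consensusKO()` annotates a peptide with a KO only when every group
member carries the *same* KO. Any disagreement, any member without a KO,
or an empty KO set leaves the peptide unannotated. The partial-agreement
case (some members share a KO, others lack one) is deliberately resolved
conservatively: a missing KO is missing evidence, not agreement.

`gsvaScores()` computes a per-sample, rank-based enrichment score in the
gene-set-variation-analysis family. Intensities are log2(x+1)
transformed, ranked within each sample (average ranks on ties), and the
peptide list is walked in decreasing-expression order (ties broken by
peptide string, for determinism): in-set peptides push a running sum up
in proportion to |rank|^tau (tau = 1 by default), out-of-set peptides
push it down uniformly. The score is the signed maximum deviation of this
Kolmogorov–Smirnov-like walk (`scoreType = "maxdev"`), or the sum of the
largest positive and negative deviations (`"diff"`); both variants are
offered because the field uses both, and both are bounded in [-1, 1].
Because only ranks enter, any strictly monotone per-sample transform of
the intensities leaves the scores unchanged. Two degenerate cases have
fixed conventions: a pathway set sharing no peptide with the matrix is
skipped with a warning, and a set spanning *every* peptide scores exactly
0 — its complement is empty, so the walk has nothing to discriminate
against.

`enrichmentSignificance()` tests each pathway's scores across group
labels with a one-way ANOVA F-test and adjusts with Benjamini–Hochberg.
Pathways with numerically zero score variance get p = 1 (no evidence,
rather than NaN). The default flagging threshold is an adjusted p below
1e-6, the conventional stringency for plotting strongly enriched
pathways; it is a parameter, not a fixed rule. Pathway sets smaller than
5 peptides (configurable) are dropped before scoring, as tiny sets make
rank walks unstable.

## The synthetic data generator

`simulateReference()` and `simulatePeptideTable()` produce a miniature
cultivated-reference study with complete ground truth, so that every
stage is testable without any download. The defaults are chosen once as
a realistic miniature: 4 phyla from a fixed pool of real gut phylum
names (so phylum-level statistics such as the F/B ratio are meaningful),
64 species/strains, ~30 proteins per strain of 120–300 residues from a
uniform residue model with K/R elevated to 8% (so tryptic peptide yields
are realistic), tryptic digestion with up to 2 missed cleavages and a
7–30 residue length filter (typical search settings), 1,000 identified
peptides across 8 samples in two groups, 10% host peptides, 5% decoy and
2% contaminant rows, log-normal intensities (meanlog 16, sdlog 1.5 —
median ~9e6, the scale of MS1 peptide intensities) with 20% dropout.

A fraction (default 15%) of proteins is copied into another strain: half
the copies verbatim (planting exact duplicates that exercise
deduplication and retired-id resolution), half with two point
substitutions (homologs that survive deduplication and genuinely coarsen
LCAs). Half of the copies stay within the donor's genus, mirroring the
family/genus-dominated LCA distributions seen in real gut data; the rest
go anywhere, producing the Root tail. Ground-truth LCA and KO for every
simulated peptide are computed by generator-local code (a plain prefix
walk and a direct all-identical check) under the same
representative-resolution convention as the annotator — independent code
paths that must agree exactly, and do in the tests.

What the generator does *not* emulate: sequence homology beyond planted
point mutants (real proteomes share peptides through deep evolutionary
conservation), non-tryptic and modified peptides, spectrum-level noise
and FDR behaviour, compositional abundance structure beyond a shared
log-normal, or chimeric/contaminant complexity. Passing tests therefore
demonstrate the correctness of the algorithms under known ground truth,
not the field performance of any particular reference database.

## Numerical conventions, in one place

* Dedup representative: lexicographically smallest protein id (C locale).
* LCA at or above superkingdom: reported as `("root", "Root")`.
* Phylum synonyms normalized before LCA and before the F/B ratio.
* Composition: fractions sum to 1 within 1e-9; "Unannotated-at-rank" is
  never merged into "others".
* Zero and missing intensity are both "not quantified" (0).
* GSVA walk: average ranks on ties; walk order ties broken by peptide
  string; whole-matrix set scores 0; `tau = 1`.
* ANOVA on zero-variance scores: p = 1.
* Row and map orders are radix-sorted so results are locale-independent.

## Validation sizes

The test suite validates against independent oracles at deliberately
modest sizes chosen to keep a full run around a minute: 1,000-group LCA
oracle comparisons, 1,000-record deduplication against an all-pairs
oracle, 100 random 200-residue proteins against exhaustive digestion
enumeration at 0–2 missed cleavages, the full consensus-KO truth table
over all KO patterns up to size 4, a 20 x 4 enrichment-score fixture
against a step-by-step walk at 1e-9, and 200 replicates of a 100-pathway
null for type-I calibration of the group test.

## Limitations

Name-based rank matching stands or falls with the consistency of the
annotation tables; the flat ladder cannot express unranked intermediate
clades; exact deduplication discards the strain history of identical
sequences (see above); the strict consensus rule forgoes KOs for
peptides whose groups are only partially annotated; and the enrichment
score is a faithful member of the GSVA family rather than a re-export of
any specific implementation, so scores are comparable within this
package, not across tools.
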