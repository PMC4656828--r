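---
title: "Reconstructing aromatic degradation networks from metagenomic screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing aromatic degradation networks from metagenomic screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aromnet)
```

## The model

`aromnet` treats a community's aromatic-degradation potential as a directed,
weighted compound graph. Nodes are chemical compounds (pollutants and their
degradation intermediates); an edge is a catalogued enzymatic transformation
substrate → product, labelled with an enzyme-class code (e.g. `Cat` for
catechol 2,3-dioxygenase) and weighted by the number of genes in the sample
assigned to that transformation. The underlying assumptions are:

* a gene detected by homology to a curated catabolic family indicates the
  *potential* for the corresponding reaction — presence of genetic
  signatures, not measured activity;
* each ORF encodes one catabolic function (no multi-domain genes): every
  gene contributes to exactly one edge, so edge weights are conserved —
  their sum equals the number of unambiguously assigned genes;
* gene counts are comparable between two samples sequenced to similar
  depth; the package compares raw counts and count ratios and leaves
  depth normalisation to the user when that assumption fails.

## Screening parameters

| parameter | unit | default | role |
|---|---|---|---|
| `min_identity` | % amino-acid identity | 50 | minimum homology to a reference family |
| `min_aln_len` | amino acids | 50 | minimum alignment span |
| `strict` | logical | `TRUE` | strict (`>`) vs inclusive (`>=`) comparison |

Both thresholds are strict by default: a hit at exactly 50.0% identity or
exactly 50 residues is rejected. Homology annotation of short, diverged
metagenomic ORFs is dominated by false positives just below these values,
and a sharp, documented boundary keeps the screen reproducible. `strict =
FALSE` is provided for sensitivity analysis only; none of the packaged
results use it.

Best-hit selection keeps, per ORF, the highest bitscore, breaking ties by
lower e-value and then lexicographically smallest family id. Tie-breaking
order is not scientifically meaningful — bitscore ties between families are
rare and usually paralogous — but a total order makes the assignment table
byte-deterministic, which the test suite asserts.

## The reaction catalog

The catalog is the package's data contract with whatever curated family
resource produced the hits. It has four tables: compounds (lowercase
canonical names plus a synonym list, so that e.g. `3,5-dihydroxytoluene`
joins as `orcinol`), enzyme classes (19 codes in the packaged default, each
tagged with a structural superfamily), reactions (one per code in the
default), and a family map from reference-family ids to codes.

Three modelling choices deserve note:

* **Multi-step segments are one edge.** Where a conversion proceeds through
  several enzymatic steps that the catalog does not resolve individually
  (e.g. biphenyl → 2,3-dihydroxybiphenyl via dioxygenation plus
  dehydrogenation), the catalog stores a single reaction with
  `step_kind = "multi"`; exporters draw it dashed. Enumerating
  intermediates would claim more resolution than the family-level
  annotation supports.
* **Root pollutants are encoded, not derived.** Each reaction carries the
  initial pollutant of its pathway explicitly. A purely graph-derived root
  (e.g. "any source node upstream") would misclassify compounds like
  gentisate, which is both a central intermediate of naphthalene
  degradation and a pollutant in its own right; the catalog states the
  intended pathway membership per reaction.
* **Ambiguity is catalog-driven.** Families that resolve only to a
  superfamily are mapped to `nonspecific:<superfamily>`; their genes are
  counted (they still indicate Rieske-oxygenase or extradiol-dioxygenase
  capacity) but never placed on an edge. An override table (ORF id →
  enzyme code or `"ambiguous"`) stands in for expert curation, applied
  last and logged in the `overridden` column.

Two on-disk dialects exist: a TSV directory for human editing and a JSON
file for lossless round-trips. Write-then-load identity is tested field by
field in both.

## Numerical and degenerate-input conventions

* Relative abundance is `100 × assignments / total ORFs`, rounded half-up
  to two decimals (45/27,893 → 0.16%); half-up matches how such
  percentages are conventionally reported, where R's default banker's
  rounding would surprise.
* Empty inputs are legal where they are meaningful: an empty hit table
  screens to an empty profile, an empty assignment list builds an empty
  network with all-zero summary statistics. A zero total ORF count is an
  error (the abundance denominator), as is a non-positive initial peak
  area in assay tables.
* DOT line thickness is `penwidth = 1 + weight − min(weight)` — linear,
  minimum 1. Only monotonicity in the gene count is intended; absolute
  thickness is presentational.
* All exports (GraphML via igraph, DOT, SIF) write nodes and edges in
  sorted order, making repeated exports byte-identical.
* Assay residuals are `100 × max(final − drift, 0) / initial` with
  `drift = control_final − initial`, a subtractive control correction:
  abiotic loss seen in the control is credited back, abiotic gain is
  subtracted, and the result is clamped at complete degradation (0%). The
  correction is deliberately simple and can be bypassed by setting
  `control_final = initial`. Residuals are invariant to rescaling one
  compound's areas, so arbitrary-unit peak areas are safe.

## The two comparison levels

Substrate-level and root-pollutant-level Venn partitions are both
first-class because they answer different questions: the substrate level
counts every compound a community can attack (intermediates included, nine
shared between the packaged microcosms), while the root level rolls each
reaction up to the pollutant whose pathway it serves (six shared), which is
the unit a remediation decision cares about. Fold changes in the
per-enzyme table are reported as B/A with sample labels embedded in the
column names, to prevent the classic 2-fold vs 0.5-fold direction mistake;
a fold against a zero baseline is flagged undefined rather than infinite.

## Taxonomic attribution

Lineages mix ranks on one axis — proteobacterial families alongside the
phyla Actinobacteria and Firmicutes — because family-level resolution is
not achievable for all groups and forcing one rank would either discard
the phylum-level signal or fabricate families. The contribution matrix is
presence/absence (a cell is present iff ≥1 unambiguous gene of that code
is attributed to that lineage): per-cell counts are retained in the output,
but presence is the claim the data supports, since per-lineage gene counts
at this scale are dominated by assembly and binning noise. ORFs without a
taxonomy row stay in the analysis as `"unassigned"` — they count in the
catabolic-share denominator (shares sum to 100%) but not in the matrix.
16S profiles are read from TSV with automatic decimal-comma detection,
since community tables are commonly exported in the European dialect.

## What the synthetic generator does and does not emulate

`generate_truth()` + `emit_dataset()` produce hit tables with one passing
hit per planted gene (identity uniform on (50, 100), length uniform on
(51, 400) — uniform because nothing constrains these nuisance shapes, and
uniform straddles the thresholds maximally), zero to two sub-optimal
secondary hits per gene (exercising best-hit selection), and decoy hits
constructed to fail exactly one threshold each. Lineages are drawn from a
stated composition; every random draw is governed by one recorded seed, and
emission is byte-deterministic given the truth.

The generator emulates the *statistical* structure of an annotated
metagenome: counts per family, threshold-straddling score distributions,
ambiguous clusters, taxonomic composition. It does **not** emulate
sequence-level reality — no reads, assembly chimeras, fragmented ORFs,
correlated paralog hits, or abundance-dependent detection. Exact recovery
of planted counts therefore validates the screening/assignment logic, not
the upstream annotation: on real data the thresholds trade sensitivity for
specificity in ways only the homology search can reveal.

## The packaged two-microcosm fixture

`build_ancona_fixture()` constructs the uric-acid (UA) vs ammonium (AMM)
enrichment bundle used throughout the tests. Only aggregate quantities of
these microcosms are on record — per-sample totals (45 and 65 screened
genes among 27,893 and 32,180 ORFs), ambiguity splits (35+4+6 and
48+11+6), per-code counts (catechol 17/14, gentisate 1/10), superfamily
fold changes (Rieske ×2, cupin-fold extradiol ×4), the shared substrate
and root-pollutant sets, and the lineage presence patterns. The fixture is
an explicit *aggregate-preserving disaggregation*: per-gene rows are
invented, every aggregate constraint is recomputed after the build by
running the pipeline, and the result ships in `manifest.json` with a
per-constraint status.

Choices made where the record under-determines the bundle:

* The recorded constraint set is internally inconsistent in one place: a
  single benzoate/2-chlorobenzoate gene in UA cannot produce both of those
  substrates in the shared set. The fixture plants one gene per code
  (total 2, not 1) — preserving the nine-substrate and six-root shared
  sets, which are the structurally meaningful quantities — and the
  manifest marks `ua_bzt_2cb_total` as a documented deviation.
* The superfamily base counts behind the ×2/×4 fold changes are not on
  record; the fixture uses Rieske 10 → 20 and cupin 3 → 12, the values
  forced by the known per-code counts once the ambiguous genes (which
  carry a superfamily but no reaction) are included.
* The catechol lineage union is fixed at eight, of which six lineages are
  determined; Halomonadaceae (UA) and Aeromonadaceae (AMM) fill the two
  free slots, both being abundant community members that plausibly carry
  ring-cleavage genes.
* The default seed (20151124) controls only nuisance draws — identities,
  lengths, scores, ORF-id interleaving. Rebuilding with any seed yields
  the same aggregates, which the acceptance script exploits.

## Problem sizes

The packaged analyses are deliberately desk-scale: per sample the fixture
holds 45–65 catabolic genes, ~25–30 decoys and up to two secondary hits
per gene (~100–150 hit rows). Property tests run the brute-force
filter/best-hit oracle on random tables of up to 100 rows and exact
recovery on 20 independently seeded synthetic datasets; these sizes
exercise every rule (ties, boundaries, decoys) while keeping the whole
suite in seconds.

## Known limitations

* One assignment per ORF: genuinely multi-domain catabolic genes are
  under-counted.
* The 50% screen is applied to percent identity; if an upstream search
  reports a composite homology score instead, the threshold semantics
  shift with it.
* Presence/absence attribution ignores copy number within a lineage.
* The comparison stage assumes two samples; multi-sample designs need
  pairwise runs.
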