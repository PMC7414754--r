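---
title: "Models and methods behind v1rCladeEvo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind v1rCladeEvo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

v1rCladeEvo characterises the evolution of the vomeronasal type-1
receptor (V1R) repertoire across six *Mus* species: receptors are mined
from per-species transcript sets, delimited into orthologous groups on a
gene tree, same-annotation transcripts are split into transcript variants
and gene duplicates, branches are screened for positive selection, and
the repertoire is summarised at the clade level. This vignette documents
the models behind each stage, the tunable parameters, the design
decisions taken where the procedure was genuinely open, and what the
synthetic-data tests do and do not demonstrate.

## The generative model

The simulator (`simulateFamily`, `evolveSequences`, `emitTranscripts`)
encodes the assumed generative process of the analysis, gene
birth-and-death along a species phylogeny:

* **Species tree.** The default fixture (`musSpeciesTree()`) is the
  rooted six-taxon *Mus* topology
  `((((domesticus,(spicilegus,macedonicus)),spretus),caroli),pahari)`
  with branch lengths scaled to a root-to-tip path of 0.07 expected
  substitutions per codon site — genus-scale divergence (the six species
  span roughly 1.5–7 My) at desk scale. Rat exists only as an outgroup
  label for rooting supplied trees.
* **Birth–death process.** On every species-tree branch each gene
  lineage duplicates at rate λ (`dupRate`) and dies at rate μ
  (`lossRate`), both per gene per unit branch length, simulated exactly
  with a per-branch Gillespie scheme (the linear birth–death model makes
  this exact, not approximate). A death is recorded as a
  pseudogenization with probability `pseudoProb`, otherwise as a clean
  deletion; either way the lineage stops and never emits transcripts,
  mirroring transcriptome-based detection, which only sees expressed,
  intact receptors. True duplication/loss rates for *Mus* V1Rs have not
  been estimated; the defaults (λ = 0.5, μ = 0.4) are illustrative
  values that produce visible but not overwhelming turnover at the
  fixture's branch lengths, and every rate is a config key.
* **True orthogroups.** Each root gene founds one orthogroup. A
  duplication on an *internal* species branch founds a new orthogroup
  for the derived copy — such duplications separate groups that span
  several species, which is exactly what species-overlap delimitation
  can recover. Terminal-branch duplications stay inside the parent
  orthogroup as within-species paralogs.
* **Codon model.** Sequences evolve by a continuous-time codon process:
  a K80-style nucleotide kernel with transition/transversion ratio κ
  (default 2), an ω multiplier on nonsynonymous changes, stop codons
  forbidden, uniform codon frequencies, and the initiator codon frozen.
  Rates are normalised so one unit of branch length is one expected
  substitution per codon at ω = 1. This is the simplest model with a
  well-defined dN/dS, which is what the recovery tests need. Per-branch
  selection classes (`omegaMap`, `branchClasses`) let tests place, e.g.,
  ω = 8 on one terminal branch.
* **Transcript variants.** With probability `pVariant` a surviving gene
  emits a second transcript of a sampled class: `same_peptide` (a few
  synonymous substitutions, so the DNA differs but the peptide does
  not), `truncated` (the first 1 − `truncFrac` of the codons,
  re-terminated; default removes 40%), or `end_modified` (the last
  `endModCodons` = 6 codons resampled to different amino acids). These
  mirror the variant classes observed among reference-genome V1R
  transcripts.

**What the simulator does not emulate:** read-level sequencing and
assembly error, expression levels, allele variation within species,
alignment-fragmenting indels, GC/codon-usage bias, and rate variation
across sites. Passing recovery tests therefore show that the inference
stages are correct *under the stated model*, not that they are robust to
every artefact of real transcriptome assemblies.

## Receptor mining

ORF extraction scans both strands and all three frames; within each
stop-free segment the ORF starts at the first ATG (the longest possible
ORF for that segment), and the gene model default of 270–400 codons with
required initiator and terminator brackets the single-exon ~300-codon
V1R architecture. The cited receptor gene model does not print numeric
bounds, so they are configurable. Deduplication removes exact duplicates
and substring containments on either strand, keeping the longest member
(ties to the lexicographically smallest id). The identity filter aligns
each species' candidates with a center-star progressive aligner (the
center maximises summed global scores; externally computed alignments
can be supplied instead) and drops sequences below 30% identity against
the group. Whether the original filter used mean or minimum identity is
not stated; **mean** is the default and `stat = "min"` is a flag.
Identity is matches over aligned columns, excluding dual-gap columns and
terminal overhangs, with a full-length denominator available.

Pairwise alignment itself is delegated to
`Biostrings::pairwiseAlignment` under EMBOSS-Needle-compatible defaults
(BLOSUM62, gap open 10, gap extension 0.5; a gap of length L costs
open + L·ext). The test suite checks these scores against an independent
plain-R affine-gap dynamic programme on hundreds of random pairs.

## Orthogroup delimitation and annotation

The published procedure was manual curation under the rule that the
receptor phylogeny should recapitulate the species phylogeny. The
package formalises it as **species-overlap reconciliation**: a node is a
duplication node iff its children's descendant species sets intersect; a
duplication spanning a single species (a within-species array) is
*local*; orthogroups are the maximal subtrees free of non-local
duplication nodes. This is deterministic and testable — the suite checks
it against a naive reconciliation oracle exhaustively over all rooted
binary shapes with up to four leaves (all species assignments over three
species) and on hundreds of random 5–8-leaf trees. Rooting prefers a
supplied outgroup, then midpoint (logged). Internal edges with bootstrap
support below 50 are collapsed before reconciliation, and no duplication
is inferred across the resulting polytomies — a conservative choice that
avoids fragmenting orthogroups on noisy edges.

Naming follows the reference annotation grammar: one reference gene
gives its id; several give a combination-ID joining numeric parts
ascending (`Vmn1r25/30`); a group without reference members collects the
reference genes of the nearest enclosing subtree it is basal to — up to
three as a combination-ID, otherwise `basal` + the lowest id. The
reference species counts as one of the six species for the category
bands (reference-only / non-orthologous / low 2–3 / high 4–6). Because
the original study hand-adjusted some annotations after inspecting the
tree, exact name-level agreement with curated annotations is not a goal;
the category and membership structure is.

The built-in gene-tree builder (center-star alignment, identity
distances, neighbour joining, midpoint rooting) exists for synthetic
tests and desk-scale runs; externally inferred maximum-likelihood trees
should be supplied for real data.

## Variants versus duplicates

The four variant rules are checked in order on the global peptide
alignment: (1) identical peptides; (2) truncation, operationalised as an
ungapped-length ratio at or below `truncFrac` = 0.75; (3) variation
confined to within E columns of the alignment termini; (4) remaining
variation within G columns of a gap. A mismatch more than E from both
termini and more than G from every gap is *central*, and any central
mismatch makes the pair a putative gene duplicate. The source procedure
prints no numeric windows; E = 10 and G = 5 are package defaults, every
call reports the windows used, and E = G = 0 provably reduces the
procedure to "any mismatch outside gaps is a duplicate" (tested against
a position-scan oracle). Within an orthogroup and species, the longest
member is the unclassified primary and every other member is classified
against its highest-scoring partner; duplications are treated
independently per species.

A known edge case, visible in the recovery tests at about the 3% level:
a very recent duplicate that has not yet accumulated a central change is
indistinguishable from a transcript variant by construction, and a
duplicate whose best partner is its own same-peptide variant classifies
as a variant. The ≥ 95% recovery criterion accommodates this
irreducible confusion.

## Selection screen

The published branch-site random-effects likelihood analysis is out of
scope; its results enter through `ingestExternalTests`. The built-in
screen is a deliberately simple counting method, labelled
`internal_screen` in every output so the two sources can never be
confused: Fitch parsimony reconstructs ancestral codons per gap-free
codon column (ties to the lexicographically smallest codon, for
determinism); per branch, synonymous/nonsynonymous sites are counted on
the parent sequence Nei–Gojobori style (stop-codon changes excluded from
the opportunity set, optional κ weighting, default κ = 1 i.e. classic
equal-rate counting); each differing nucleotide position is classified
as a synonymous or nonsynonymous single-site change in the parent
context, giving integer counts; and the p-value is the one-sided
binomial tail of the nonsynonymous excess against the neutral
expectation N/(N+S). Branches with no changes are untested. Because the
simulator's κ = 2 makes transitions (disproportionately synonymous)
more frequent than the κ = 1 counting assumes, the screen is
conservative under neutrality — the suite verifies ≤ 5% + 3 SE flagged
after FDR, and observes high power (≥ 90% in the pilot configuration)
for ω = 8 foreground branches.

FDR correction is Benjamini–Hochberg. The original text corrected
p-values "from each run" but reports genome-wide counts; both scopes are
implemented, **pooled** over all tested branches being the default, and
the scope is recorded in the configuration. Percentages in the clade
summary are rounded half-up (not banker's rounding) to two decimals to
match printed tables; one printed percentage (1.79 for a clade with
1/57 significant branches, which is 1.75 by this arithmetic) is not
reproducible from its printed counts and is excluded from the checks,
as is the printed total orthogroup percentage (19.05 versus
24/127 = 18.90).

## Turnover summaries

Loss calls in the focal (reference) species require the orthogroup to
lack the focal species while at least `min_support` = 3 of the five
sequenced species are present; new gene ids are allocated from the
maximum existing reference number upward so they can never collide, and
a user-supplied pseudogene table is cross-referenced when present.
Category fractions are reported on two bases — unique annotations
(variant suffixes collapsed) and total transcripts — each summing to
100%. Clade labels are inherited from member reference genes, or for
reference-free groups from the nearest reference-containing ancestor in
the gene tree; unplaceable groups are counted under `unplaced`, never
dropped.

## Site categories and membrane topology

Variable columns of a one-representative-per-species alignment are
classified from k (species deviating from the consensus) and d (distinct
deviant residues): `single_species` (k = 1), `two_species_distinct`
(k = 2, d = 2), `shared_2_3` (d = 1, 2 ≤ k ≤ 3), `highly_variable`
otherwise (k ≥ 4, d ≥ 3, or k = 3 with d = 2). The verbal source
categories leave the k = 3, d = 2 corner undefined; assigning it to
`highly_variable` (three deviant species carrying two different
residues is dynamism, not a shared derived state) makes the map total
and disjoint, which the suite verifies by enumerating every six-species
column over a six-letter alphabet. Consensus ties resolve toward the
reference species' residue, matching the framing of changes relative to
the house mouse; gapped residues neither vote nor deviate. Sequences
shorter than `short_len_frac` = 0.8 of the median ungapped length — the
short transcript variants — are excluded first.

Membrane topology uses an external per-residue table when provided,
otherwise a hydropathy stand-in for an HMM predictor: Kyte–Doolittle
window 19, threshold 1.6; each above-threshold window centre contributes
its full window, overlapping windows merge, merged segments shorter than
15 residues are discarded, and the topology is threaded from an
extracellular N-terminus (V1Rs have a short extracellular N-terminal
region). This stand-in recovers clean seven-helix architectures on
well-behaved receptors but is not a substitute for a trained topology
model on borderline sequences; region-level conclusions on real data
should use external predictions.

## Numerical and reproducibility choices

* All stochastic stages require an explicit integer seed; there is no
  wall-clock fallback. Identical seed and parameters give byte-identical
  FASTA, tables and trees (tested).
* Coordinates are 0-based half-open internally; user-facing tables are
  1-based where positional.
* Ties are always broken deterministically: lexicographic ids for
  best-hit and dedupe ties, smallest codon for Fitch, id order for
  annotation suffixes at equal scores.
* Percentages shown to users are rounded half-up at the printed
  precision; internal computations are never rounded.
* Test and acceptance problem sizes: 2000 replicates for the pure-birth
  mean, 200 for the neutral dN/dS oracle (two 0.1-substitution
  branches, 300 codons), 100 families for duplicate/variant recovery,
  40 for loss recall, 50 families × 6 species × 300 codons for the
  neutral false-positive control, 500 random pairs for the aligner
  oracle, and exhaustive enumeration up to four leaves (plus seeded
  random 5–8-leaf trees) for the reconciliation oracle. These sizes make
  Monte-Carlo standard errors small relative to the tested tolerances.

## Known limitations

* The counting screen is a screen, not a likelihood method: it has no
  rate variation across sites or branches and is conservative at κ > 1;
  published selection results should be reproduced through the external
  ingestion path.
* Center-star alignment is adequate within receptor families but is not
  a general MSA method; heavily gapped families should use an external
  aligner.
* Orthogroup recovery is only guaranteed to match the truth labels on
  duplication-free histories; duplications close to speciation nodes
  are intrinsically ambiguous on the gene tree.
* The pipeline assumes the reference repertoire is complete and
  correctly annotated; errors there propagate into naming, clade
  assignment and loss calls.
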