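---
title: "Methods: comparative evolution of Notch pathway gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative evolution of Notch pathway gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notchtrace)
```

## Overview

`notchtrace` re-implements, as a tested and reusable pipeline, the chain of
comparative analyses used to study the evolution of the Notch signalling
pathway across metazoans, with emphasis on lophotrochozoans and the
duplicated mollusc ligand *Delta*:

1. **Architecture classification** — assign genes to pathway families from
   protein domain-hit tables.
2. **Gain/loss reconstruction** — place each family's origin and losses on
   a rooted species tree by Dollo parsimony.
3. **Truncation typing** — identify the mutational mechanism behind the
   premature termination of a derived paralog (the *Delta2* phenomenon).
4. **Paralog-clade phylogenetics** — distance/NJ trees with bootstrap
   support and monophyly tests.
5. **Expression comparison** — similarity/complementarity of developmental
   stage profiles.

Upstream heavy lifting — homology search, HMM scanning, multiple sequence
alignment, read mapping and quantification — is out of scope: the pipeline
consumes their tabular products (domain-hit tables, aligned FASTA,
RPKM/FPKM matrices).  Because the original genome and transcriptome
downloads are external, the package ships a synthetic-data module that
plants known truth for every stage; all quantitative claims made by the
test suite are claims about recovery of planted truth, not about real
genomes (see *What the synthetic data do and do not show*).

## Family signatures

Families are defined as domain-architecture signatures over HMMER/Pfam-style
hits:

| family | requirements | notes |
|---|---|---|
| Notch | ≥2 EGF, exactly 3 LNR, ≥1 TM, ≥2 ANK | "several" = 2 by default |
| Delta | 1 MNLL, ≥1 DSL, ≥1 EGF | |
| Jagged | Delta's domains + ≥1 VWC | outranks Delta by specificity |
| Presenilin | ≥1 Presenilin | |
| SuH | ≥1 LAG1-DNAbind (BTD) | |
| Hes / Hey / Helt / Cwo | ≥1 bHLH + ≥1 Orange | shared superfamily architecture |

Decisions worth making explicit:

* **"Several" repeats.** The field's verbal definition gives no numeric
  floor for "several" EGF or ANK repeats.  We operationalise it as
  `several_min_count` (default 2) — the weakest defensible reading — and
  keep it configurable.  Canonical Notch receptors carry 29–36 EGF repeats,
  but that describes the canonical protein, not a filter, so EGF has no
  upper bound.
* **Specificity tie-breaking.** The most specific satisfied signature wins,
  specificity being the number of required domain types; that is what makes
  a Jagged gene (which necessarily satisfies Delta's requirements too)
  classify as Jagged.  Equal-specificity conflicts across superfamilies are
  an error, surfaced to the caller, never silently resolved.
* **Fallback verdicts.** A DSL-bearing gene failing the full Delta
  signature is *Delta-like* (`Dll`) — ligands that lost EGF repeats or
  other motifs.  A bHLH-bearing gene is routed to the `HesHey` superfamily
  label: the four bHLH families share one architecture, and subtype is a
  phylogenetic, not architectural, question — `assign_subtype_by_clade()`
  answers it from the clade a query nests in on a bHLH-domain tree.
* **Domain order** is recorded in the signatures but not enforced by
  default (nothing in the family definitions requires it).
* **Overlap policy.** Upstream domain scanners can emit overlapping hits;
  we retain a greedy best-E-value selection in which no two kept hits
  overlap by more than 50% of the shorter hit, with deterministic
  tie-breaks (E-value, then leftmost start, then domain name).

Hits are pre-filtered at `e_value_threshold` (default 1e-5, the
conventional low cut-off for domain screening).

## Dollo gain/loss reconstruction

Family presence/absence over species is explained under Dollo parsimony: a
gene family arises exactly once and can only be lost thereafter.  The gain
edge is the edge above the MRCA of the present leaves; the losses are the
maximal wholly-absent subtrees below it.  This is provably the unique
minimal single-gain history, and the test suite checks optimality
exhaustively against a brute-force enumeration of all internal-state
assignments on trees of 4–7 leaves.  When the presence MRCA is the root the
gain is reported on a virtual root edge and flagged "origin at or before
the root of the sampled taxa" — with no outgroup evidence, deeper origins
are indistinguishable.  Unrooted trees are rejected rather than auto-rooted
(rooting is a scientific claim the caller must make); polytomies are
accepted, each child treated independently.

## Truncation mechanism typing

Given a reference paralog (a clean ORF) and a derived paralog, the derived
CDS's first in-frame stop is located and attributed to the nearest upstream
edit in a global pairwise alignment that is *capable* of producing it:

* insertion inside the stop codon → `insertion_stop` (e.g. an inserted G
  creating a terminal TGA);
* substitution inside the stop codon → `substitution_nonsense` (e.g. the
  sense codon TTA becoming TGA);
* upstream frameshifting deletion → `deletion_frameshift`;
* upstream frameshifting insertion → `insertion_frameshift`.

Numerical and representational choices:

* **Alignment scoring** is fixed and documented — match +2, mismatch −1, a
  gap of length L costs 5 + L — with the optimum verified in tests against
  an independent full-matrix affine DP.  The original analysis presented
  alignment views from interactive software without stating parameters, so
  the scheme here is the package's own, chosen as a conventional
  nucleotide-level scheme that keeps single-base edits as single columns.
* **Indel left-normalization.** Within a homopolymer run, deleting or
  inserting any copy yields the same sequence; both the planting generator
  and the classifier report the leftmost equivalent coordinate (VCF-style),
  making "exact causal-coordinate recovery" well defined.
* **Search window.** The causal edit is sought within 30 codons upstream of
  the stop, widening to the whole alignment only if that window is empty;
  when several edits precede the stop the nearest is called causal and the
  rest are reported as alternates rather than discarded — for real paralog
  pairs, with many accumulated differences, the call is a best attribution,
  not a certainty.
* **Anchor window.** Derived stops are located relative to the last
  upstream anchor residue of the reference (default arginine, the conserved
  residue upstream of mollusc *Delta2* stops); offsets inside
  `[window_lo, window_hi]` (default 1–10 amino acids) are flagged as
  falling in the canonical termination window.  Whether offsets of exactly
  0 or 11 should count is genuinely unstated in the source material, so the
  bounds are configuration, not fact.  A reference with no upstream anchor
  yields an *indeterminate* flag, never `FALSE`.
* Translation uses the standard genetic code only; codons containing N
  translate to X and never terminate.

## Phylogenetics

The original study built ML trees (WAG+CAT) on trimmed ClustalW
alignments and reported that NJ, ML and Bayesian topologies were
consistent; this package therefore implements the distance/NJ route as its
desk-scale surrogate, keeping MSA construction and ML/BI inference out of
scope.

* **Trimming** replaces heuristic automated trimmers with an explicit rule:
  drop columns whose gap fraction exceeds `gap_fraction_trim` (default
  0.5).  The rule is reproducible and configuration-visible.
* **p-distance** excludes columns gapped in either row; a pair with zero
  comparable columns is flagged missing rather than set to 0.
* **Neighbor joining** is the standard Q-criterion agglomeration with two
  pinned details: deterministic tie-breaking (earliest pair in label
  order), and negative branch lengths clamped to zero with the deficit
  moved to the sister branch so the pair's summed length is preserved.  NJ
  consistency on additive matrices is tested on 100 random 8-leaf trees and
  cross-checked against an independent NJ implementation.
* **Bootstrap** resamples columns with replacement; support is reported per
  internal *bipartition* (edge-based, avoiding rooting ambiguity) as the
  percentage of replicates containing it.  The seed-to-replicate mapping is
  documented (one `sample()` call per replicate in order), so supports are
  bit-exact reproducible.
* **Subtype assignment** walks from a query leaf rootward to the first
  ancestor containing reference leaves; a pure single-subtype reference set
  decides the subtype, anything mixed is `ambiguous` — queries basal to all
  references are never forced into a clade.

Only monophyly claims are formalised; relative-age claims (which paralog
"appeared later") mix topology with branch-length reasoning and are not
asserted by this module.

## Expression comparison

RPKM/FPKM are within-sample measures, so only *trends* are compared.
Profiles are compared by Spearman rank correlation by default (invariant
to per-gene positive affine transforms, hence immune to RPKM-vs-FPKM unit
mixing — property-tested).  "Complementary expression" has no standard
quantitative definition; we operationalise it as correlation ≤
`complementarity_threshold` (default −0.5) and "similar" as ≥
`similarity_threshold` (default +0.5), with both thresholds surfaced in
every report.  Correlations need at least 4 stages (rank correlation is
degenerate below).  Constant profiles are flagged and excluded, never
silently zeroed.  Peak-stage enrichment uses a pseudocount of 1 on raw
values to avoid division by zero for mostly-silent genes.  Genes whose
median raw value falls below a configurable floor get a low-expression
flag with no biological claim attached.

## What the synthetic data emulate — and what they do not

The generator plants: domain architectures exactly matching the family
signatures (as coordinate annotations, not sequence motifs — the HMM
scanning stage is out of scope, so "detection" starts from hit tables);
single-base termination mutations of all four mechanisms in clean random
ORFs (sense-codon sampling precludes incidental in-frame stops);
single-gain/multiple-loss presence patterns on trees; two-or-more-clade
alignments whose signal columns separate the planted groups; and profile
pairs built as positive/negative affine transforms plus Gaussian noise.

The mollusc case-study fixture encodes the qualitative pattern of the
motivating analysis: *Delta2* present in bivalve, cephalopod and two
gastropod taxa, absent from the chiton-like outgroup, lost in three
gastropod taxa.  Two deliberate fixture choices: the gastropod subtree
places each lost taxon sister to a lineage retaining the gene, so the
three-independent-loss history is the unique Dollo optimum (had the three
lost taxa formed a clade, one clade loss would be more parsimonious and
the "three losses" reading would not be recoverable from
presence/absence alone); and the topology is a synthetic convention — the
real gastropod topology the original inference assumed is not stated in
the source material.

What passing tests therefore show: the classification grammar, Dollo
algorithm, alignment-based mechanism typing, NJ/bootstrap machinery and
correlation calls are each correct against independent oracles and recover
planted truth under the stated noise.  What they do not show: robustness
to real-data pathologies — fragmented gene models, chimeric hits, HMM
false positives, alignment error in deep divergences, or expression
batch effects.  Real analyses should treat the package's verdicts as
first-pass calls to be inspected, exactly as the original study inspected
its alignments by eye.

## Problem sizes and determinism

The shipped analysis scripts and acceptance checks use: 200 planted genes
for classification recovery; 10,000-hit tables for filter checks; 500
planted terminations (125 per mechanism) plus 10,000 random CDS
translations; exhaustive Dollo verification on 100 random trees of 4–7
leaves over all nonzero presence vectors; 100 additive 8-leaf matrices for
NJ consistency; 200 bootstrap replicates on planted alignments; and 1,000
noisy expression pairs (noise sd 0.25 on a 1–10 RPKM-like scale, 8
stages).  These sizes make every recovery statement exact or tightly
Monte-Carlo-bounded while keeping a full run in the minutes range on one
CPU.  Every generator is a pure function of its seed, the bootstrap
seed-mapping is pinned, and two pipeline runs from the same manifest are
byte-identical — outputs carry the config hash and seed in their headers
so provenance survives file shuffling.

## Known limitations

* Architecture cannot separate Hes/Hey/Helt/Cwo (by design; phylogeny
  does), and does not model domain order or spacing.
* Dollo parsimony has no loss-rate model: a family that is easy to lose
  will have its origin pulled tipward by missing data; absence in a single
  poorly-assembled genome reads as loss.
* The NJ surrogate is consistent on additive distances but is not an ML
  reconstruction; supports are NJ-bootstrap supports.
* Mechanism typing assumes a single dominant causal edit; heavily diverged
  paralog pairs yield an attribution plus alternates, not a proof.
* Expression relations are correlation calls over few stages; they carry
  no differential-expression statistics.
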