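---
title: "Methods: rule-based analysis of RING-type E3 ligase gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based analysis of RING-type E3 ligase gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringminer)
```

`ringminer` re-implements, as a tested and reusable pipeline, a genome-wide
characterization workflow for RING-type E3 ubiquitin ligase gene families of
the kind used to screen candidate regulators of starch (amylose) biosynthesis
in developing wheat grain. The pipeline runs entirely on synthetic inputs
with planted ground truth, so every stage is verifiable without any download.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic data do and do not demonstrate.

## The RING domain model

A RING domain is modelled as a chain of eight zinc-coordinating metal-ligand
residues (ML1..ML8) with constrained residue identities and constrained gaps
(residue counts) between consecutive ligands. The shipped default rules use
the canonical cross-brace consensus

```
C-x2-C-x(9-39)-C-x(1-3)-H-x(2-3)-[H|C]-x2-C-x(4-48)-C-x2-C
```

which gives a minimum feasible span of 30 residues (8 ligands + 22 gap
residues) and, with the default `max_domain_span = 102`, an allowed span
range of 30-102 residues. Subtype identity is decided by the residue at the
ligand positions, most importantly ML5: His gives RING-H2 (C3H2C3), Cys
gives RING-HC (C3HC4). Two further rules ship as *editable placeholders*:
RING-v as C4HC3 (Cys/His swapped at ML4/ML5, with relaxed ML4-ML5 and
ML6-ML7 spacing) and RING-G (Gly accepted at ML5). Where these two variant
subtypes matter for a real analysis, their signatures should be taken from
the domain-classification scheme the study adopts and edited into
`extdata/ring_rules.yaml`; the classifier honours whatever rules the config
declares, in declared priority order. An RBX variant is expressed as a
per-rule substitution (by default Asp in place of Cys at ML8 for RING-H2):
a chain whose only deviation from a rule is its RBX substitution is assigned
that subtype with the `RBX` flag.

Scanning searches the *union envelope* of all rules (union residue sets per
slot, widest gap ranges), then classifies each chain against the individual
rules. A chain that matches the envelope on at least `min_ligand_matches`
(default 6) of the 8 slots, with all gaps satisfied, is emitted as an
`INCOMPLETE` candidate; the published workflows report incomplete domains
without stating an algorithmic rule, so the >= 6-of-8 rule is a documented,
configurable stand-in. The ambiguity code `X` never matches a ligand.

Numerical/design choices in the scanner:

* **Overlap resolution** is greedy: leftmost start first, shortest span on
  ties, then ligand positions, so results are fully deterministic. Complete
  chains are resolved before incomplete candidates; an incomplete chain that
  happens to start earlier can therefore never shadow a complete domain.
* **Coordinates** are 1-based inclusive in every report (protein residue
  convention).
* Proteins with several accepted domains get `a`, `b`, `c` ... suffixes in
  start order; group percentages are computed over classified (complete)
  domains only and rounded half-up to 2 decimals. Half-up rounding (not R's
  default round-half-even) is used for every reported percentage because it
  is what printed tables in this literature use.

## Duplication classes

Every family gene receives exactly one of five classes by a strict priority:

1. member of a collinear anchor block -> `WGD_segmental`;
2. else a same-chromosome homolog within `tandem_max_rank_gap` (default 1,
   i.e. adjacent genes) -> `tandem`;
3. else within `proximal_max_rank_gap` (default 10) -> `proximal`;
4. else any homolog pair -> `dispersed`;
5. no pair -> `singleton`.

Rank gaps are counted over *all* genes on the chromosome, not only family
members, mirroring the convention of standard duplicate-gene classifiers;
the synthetic gene-map generator therefore emits filler genes. Collinear
blocks are maximal chains of anchor pairs, strictly increasing in rank on
one chromosome and monotonic on the other, with consecutive anchors within
`max_anchor_rank_gap` (default 25) on both sides and at least `min_anchors`
(default 5) pairs; extraction is greedy longest-chain-first with each anchor
consumed once, and agrees with an exhaustive search oracle on small
instances. The window defaults are stated as defaults only - the classifier
they mirror does not publish universal values - and all are arguments.

The mean inter-gene distance is computed start-to-start between consecutive
family genes per chromosome, in Mb to one decimal. The alternative reading
(chromosome span divided by gene count) is a near-equivalent for dense
families; the start-to-start definition was chosen because it is the direct
reading of "distance between two genes" and is exactly recomputable.

## Expression analysis

Expressed calls use a strict threshold (`value > threshold`, default 0.5
TPM). The source workflows never state their cutoff; 0.5 TPM is a common
low-expression floor and the boundary convention (strictly greater) is
asserted by test. The three-stage Venn partition is exact set algebra over
the call matrix; its seven regions always sum to the expressed total.

Hierarchical clustering uses the uncentered Pearson correlation distance

$$d(x, y) = 1 - \frac{\sum_i x_i y_i}{\sqrt{\sum_i x_i^2 \sum_i y_i^2}} \in [0, 2]$$

with complete linkage, the combination classic expression-heatmap tools
apply. Unlike centered Pearson, the profiles are not mean-centered, so
overall expression level participates in similarity. Zero-norm profiles get
distance 1 with a warning. Rows are sorted by name before clustering so tie
merges are deterministic. Major groups come from cutting at k = 4; groups
III and IV are sub-cut in two (labels A/B ordered by the expression-weighted
mean stage), matching the I / II / IIIA-B / IVA-B structure such heatmaps
are usually read into.

Differential expression is *consumed*, not computed: the filter takes a
precomputed per-gene fold-change/p table (the upstream DE engine is out of
scope) and keeps records with `|log2FC| > 1` (strict) and `p <= 0.05`
(inclusive), exactly as such criteria are conventionally printed. No
multiple-testing correction is applied, mirroring the stated criteria.

## qPCR candidate screen

Fold changes use the Livak delta-delta-Ct identity

$$\log_2 FC = -\left[(Ct_{target,mut} - Ct_{ref,mut}) - (Ct_{target,ctl} - Ct_{ref,ctl})\right]$$

with technical replicates averaged within each biological replicate, then
biological replicates averaged; the SD is taken over per-biological-replicate
ddCt values. Efficiency correction is not applied (the efficiency-corrected
variant was not derivable from the source description; the plain Livak form
is the stated baseline).

A gene is a candidate when its four stage fold-changes are consistent in
sign *and* reach `magnitude_min` (default 2, i.e. four-fold) at at least
`min_strong_stages` (default 2) stages. The published up-regulated candidate
rule is narrative rather than formulaic; the implemented rule is the
symmetric magnitude rule above, documented as a reconstruction, with both
parameters exposed.

## Variant-effect categories

A variant's category is the precedence-ordered compound of every genomic
zone its affected bases overlap (coding > splice donor > acceptor > region >
UTR > intron > upstream > downstream > intergenic), which reproduces
compound labels such as `splice_donor&intron` and `missense&splice_region`.
Window defaults follow annotator conventions: 5 kb up/downstream of
TSS/TES, splice donor/acceptor = first/last 2 intron bases, splice region =
intron bases 3-8 or the 3 exon bases adjacent to a junction; all are
configurable. Coding effects come from local codon comparison on the
strand-corrected CDS: SNP/MNP by translating affected codons (synonymous /
missense / start-stop disruptions), indels by length mod 3 (frameshift vs
inframe) with inframe split conservative/disruptive by codon-boundary
alignment. A 5'UTR SNP that creates a new ATG upstream of the start codon
becomes `5_prime_UTR_premature_start_codon_gain`. Impact tiers map from the
primary category: HIGH (frameshift, splice donor/acceptor, start/stop
disruptions), MODERATE (missense, inframe indels, premature start gain),
LOW (synonymous, splice region), MODIFIER (intron, UTR, up/downstream,
intergenic). Coordinates follow VCF convention (1-based, indels left-anchored
with an anchor base).

Known limitations: an inframe insertion that happens to introduce a stop
codon is still labelled inframe (the generator never plants such a case);
indels spanning a CDS-intron boundary take the compound of the overlapped
zones without attempting a combined coding call; and the strand-symmetry
guarantee is asserted for substitutions (reverse-complementing anchored
indel records also inverts the anchoring convention, which is a
representation change rather than an annotation property).

## Correlation screen

Pearson r between each panel gene and each target (GBSSI, SBEIIa) is
computed over per-stage means, with the two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ at n - 2 df. Following the source methods the
screen runs on the four stage means (n = 4, 2 df) despite the low power;
the code warns when n < 5. Strength bins are on r^2 as printed
(`>= 0.80` very strong, `>= 0.60` strong, inclusive bounds). Selection
requires `p <= 0.05` *and* `r^2 >= 0.60`; at n = 4 the p-criterion alone
already forces r^2 >= 0.9025, so the strength bound only becomes the
binding constraint for longer stage series. This also means the published
examples of "strong, significant" correlations at r^2 = 0.60-0.81 could not
be significant at n = 4 under the stated test - an internal tension of the
source description that the implementation surfaces but does not resolve.
The planted correlation panel therefore places in-set genes on exact linear
combinations of the two target profiles (single-target genes proportional to
one target; both-target genes on the bisector of the two, whose correlation
with each target is $\sqrt{(1+r_{uv})/2} \approx 0.975$ at the default
target-target correlation 0.9) and out-set genes exactly orthogonal to both,
so the screen's outcome is determined by geometry rather than by sampling
luck.

## The synthetic-data generators

The generators define the study conditions; they are first-class, tested
code, not fixtures.

* `gen_proteome()` plants RING domains satisfying the generating rules at
  known positions. Background residues are uniform over the 20 amino acids
  with Cys/His down-weighted (x 0.3); gap residues inside a domain avoid
  ligand letters; and a rescan-and-redraw loop removes any spurious complete
  chain, so at `decoy_rate = 0` the planted truth is exactly what the
  scanner must report. Decoys are near-miss chains (one ligand replaced by
  Ala) that can only surface as incomplete candidates.
* `gen_gene_map()` lays planted duplication structures (collinear blocks,
  tandem/proximal/dispersed pairs, singletons) among filler genes, separated
  by `max_anchor_rank_gap + 1` fillers so no unplanned relation can arise;
  odd class counts attach the odd gene to a donor of strictly higher
  priority, which leaves the donor's class unchanged. Intergenic spacing is
  drawn at 50-500 kb so adjacent-gene distances land on the Mb scale of a
  large cereal genome.
* `gen_expression()` realizes a 7-region Venn specification exactly:
  expressed entries Uniform(threshold + 0.5, 100), silent entries
  Uniform(0, threshold/2), so calls are unambiguous by construction.
* `gen_qpcr()` uses the Livak-invertible Ct model
  `Ct = ref_ct + offset(gene) - log2FC(gene, genotype, stage)` plus Gaussian
  replicate noise; with zero noise the ddCt round trip is exact to
  floating-point precision.
* `toy_gene_models()` / `gen_variants()` build multi-exon genes (30-bp
  UTRs, 300-bp CDS over four exons, 60-bp GT..AG introns, alternating
  strands, 13-kb spacers) and sample variant sites per requested category
  from enumerated site pools, without footprint overlaps, erroring when a
  category is unrealizable or its pool is exhausted.

All generators take explicit seeds and are byte-deterministic given the
seed; no hidden global RNG state is used (the global seed is saved and
restored).

What passing tests show - and do not show - about real data: planted-truth
recovery demonstrates that the implementations compute their stated
definitions exactly and compose correctly end to end. The synthetic data do
not emulate hexaploid homeologue structure, real codon usage,
sequencing-level noise, or the fuzziness of real domain boundaries, so
recovery rates here say nothing about sensitivity against real proteomes or
real variant calls; on real data the rule set and windows are the parts a
user should expect to tune.

## Problem sizes and determinism

The test suite and the acceptance script run the generators at the study
scales: 1272 planted domains in 1255 proteins, a 1238-gene family map over
21 chromosomes (108 collinear blocks of 5+ anchors), a 1255 x 3 expression
matrix, a 36-gene qPCR panel over 4 stages, and 457 + 667 planted variants
on twelve toy genes. Property suites use brute-force oracles on reduced
sizes (sequences <= 200 aa against exhaustive chain enumeration, <= 20
anchor pairs against exhaustive chain search, 300-bp CDS against full
translate-and-diff) plus randomized conservation fuzzing across hundreds of
seeds. A complete run of the numbered `analysis/` scripts takes on the
order of a minute, dominated by the proteome scan.
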