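---
title: "Marker discovery and array design in allo-polyploids: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker discovery and array design in allo-polyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyArray)
```

# The setting

polyArray targets marker discovery and array design for an
allo-polyploid whose subgenomes are collapsed onto a single diploid
reference by short-read alignment. We model four subgenomes (AABBCCDD),
so a reference coordinate superimposes eight homoeologous copies. Two
variant populations coexist at such coordinates:

* **homoeologous sequence variants (HSVs)** — fixed differences between
  a subgenome and the reference, carried by every accession, useless as
  markers but invaluable as probe *destabilisation sites*;
* **marker variants** — segregating within one subgenome among panel
  accessions; under bivalent pairing they inherit disomically, like a
  diploid locus embedded in the polyploid.

All downstream machinery follows from needing to (i) separate these two
populations using only per-accession VCFs, and (ii) genotype the
surviving markers on a two-channel array despite the constant signal
contributed by the non-segregating subgenomes ("cluster compression").

# Discovery pipelines and their thresholds

Filters are shared primitives (`readCountFilter`, `presenceAbsenceFilter`,
`atGcFilter`, `genicFilter`, `flankSafety`) combined into eight
category pipelines. The defaults in `pipelineConfig()` are the values
used for the array design this package re-implements:

| parameter | default | meaning |
|---|---|---|
| `min_reads_snp` / `min_reads_indel` | 3 / 2 | supporting reads summed across all panel files; removes sequencing-error variants |
| `min_present` / `min_absent` | 2 / 2 | presence/absence on the filtration subpanel; a variant present in **all** members is HSV-like and excluded from marker candidacy |
| `snp_up`/`snp_down` | 24/24 bp | flank windows free of any other panel variant (probe-site conservation) |
| `indel_up`/`indel_down` | 24/30 bp | the extra 6 bp downstream covers the candidate indel's own 3–6 bp length |
| `snpsnp_max_offset` | 6 bp | SNP-SNP haploSNP: destabilising HSV SNP within 6 bp of the marker |
| `indelsnp_max_offset`, `indelsnp_size_range` | 14 bp, 4–6 bp | indel-SNP haploSNP pairing rule |
| `insertion_size_range` | 3–6 bp | SNP-in-insertion: the marker base rides inside a fixed insertion |
| `clean_window` | 24 bp | around a haploSNP marker, no variant other than its destabiliser |

The haploSNP pipelines run in two phases: destabilisation candidates
are mined first (variants present in *every* subpanel member), then
marker SNPs (present ≥ 2, absent ≥ 2) are paired with them under the
distance/containment rules, the clean window is checked with the
destabiliser as the single permitted exception, and finally a coupling
check requires every file carrying the marker allele to also carry the
critical destabilising form. Because read-level phasing is not
available from VCFs, coupling is checked at accession (file) level — an
approximation we document rather than hide.

Decisions where the method description left the convention open:

* **Offsets** are measured between the marker base and the left-aligned
  normalised position of the destabiliser, in reference coordinates.
  Deletions whose span would remove the marker base itself are excluded
  from pairing.
* **Flank windows for haploSNPs** are checked on *both* sides of the
  marker (24/24) with the destabiliser as the only exception, the
  stricter of the two readings of the clean-window rule.
* **mSNP presence/absence** is evaluated per non-reference allele; a
  site qualifies when at least one allele behaves as a segregating
  marker. Sites with two to three alternate SNP alleles (three or four
  alleles total) are mSNP territory; single-alternate sites route to
  the di-allelic pipeline.
* **Indels** are filtered on Minimum Absence (plus read count, size and
  windows) but not Minimum Presence, following the stated scope of the
  presence filter for SNP variants.
* **Presence is counted per file**, not per accession: a twice-sequenced
  accession contributes two files, as in the 20-file discovery panel the
  defaults emulate.
* **Codon-based sites**: coding sequence is scanned for proline codons
  (CC\*) and the strand-corrected third (4-fold degenerate) position is
  emitted wherever the flanks are clean. No variant evidence is used —
  the category exists to test whether the array itself can discover
  polymorphism. The speculative polymorphism is recorded as reference
  base versus its transition partner, which can never form an A/T or
  G/C pair, so the A/T-G/C screen passes by construction.
* **`spreadSelection`** removes coordinate duplicates by category
  priority (ploidy-reducing > other octoploid > diploid-derived >
  codon-based) and then solves the per-chromosome max–min spacing
  problem *exactly* (binary search over achievable gaps with a greedy
  feasibility scan) rather than by an approximate greedy heuristic;
  ties break toward lower coordinates, making selection deterministic.

# Probe design and accounting

Probe geometry is not dictated by the accounting, so we fixed a
consistent convention: a non-allele-specific probe is 30 bases of the
tiled strand ending immediately 5′ of the interrogated position;
allele-specific probes append the interrogated base at the 3′ terminus.
HaploSNP probes are built on the destabilised template (the critical
HSV form substituted into the reference flank), and SNP-SNP/indel-SNP
sites are single-strand by construction: only the strand whose probe
extends across the destabiliser is tiled.

Accounting rules per site and tiled strand: one probe and one probeset
for a standard non-A/T-G/C marker; two allele-specific probes for an
A/T or C/G marker; four probes for an mSNP (all four bases designed at
the position) forming **six** probesets — one per unordered base pair,
C(4,2). The pairwise mSNP probeset rule is a reconstruction chosen
because it exactly reconciles the published totals
(1,414 × 12 + 347 × 6 = 19,050); note it makes mSNP probesets exceed
mSNP probes, so "probes ≥ probesets" holds for every category *except*
mSNPs. Whether an A/T-G/C allele-specific pair collapses into one
probeset is a per-category convention: it does for the indel category
(9,528 sites → 10,558 probesets) but not for indel-SNP and
SNP-in-insertion (1,177 → 1,206 and 2,843 → 3,376, probeset = probe),
matching the published per-category counts; `accountDesign()` exposes
the convention as an argument. Features are counted as two replicates
per probe; the published chip-level feature total is not fully
reconstructible from the stated plans and is reported with that caveat.

The external probe-quality score (a random-forest model trained on
human array data) is **not** re-trained here: `classifyScore()` treats
it as a pluggable input, and an unscored candidate counts as neutral —
admissible for ploidy-reducing categories, not for standard ones.

# The cluster model

Cluster centres follow the linear intensity model
`A = nA·a + b`, `B = nB·a + b` (defaults `a = b = 100`), transformed to
`contrast = log2(A/B)` and `size = (log2 A + log2 B)/2`. The method
description never defines contrast/size; this standard log-ratio /
mean-log (MvA) form was chosen because it reproduces every stated
qualitative behaviour: the diploid AB and tetraploid AABB clusters sit
at contrast exactly 0, B-fixed octoploid clusters are negative, and
homozygous-null (∅∅) samples — which receive background-only signal in
both channels — drop by 1–2 size units, forming the off-target-variant
(OTV) cluster.

`HomRO = min(contrast_AA, −contrast_BB)` over the homozygous clusters
present reconstructs the verbal definition "displacement from zero
contrast of the homozygous cluster closest to it" with the stated sign
behaviour (flanking clusters positive, same-side clusters negative or
near zero); the threshold 0.3 separates diploid-like from
polyploid-like clustering. Empirical cluster means are used as centres.

`callGenotypes()` is a simplified, documented caller — a stand-in for
proprietary array-calling software, not a numerical reimplementation.
Samples whose size falls more than `otv_size_delta = 1.0` log2 units
below the panel median are set aside as the putative null cluster; the
remaining contrasts are fit by a one-dimensional Gaussian mixture
(quantile-initialised EM, variance floor 1e-6, component count by BIC
over k ≤ 3), which makes the fit deterministic for given data. Exactly
repeated contrast values — noise-free simulations — bypass EM and are
resolved exactly. Labels follow contrast order (AA > AB > BB); a
two-cluster marker is labelled AA/BB, which the quality classifier
treats as "no minor homozygote" regardless of labelling. Confidence is
one minus the posterior of the assigned component; the stringent
default NoCall threshold is 0.01 (the permissive setting being 0.15),
so lowering the threshold can only add NoCalls.

`classifyQuality()` applies the class decision order: call rate < 97%
→ CRBT; one cluster → MHR; an extra low-intensity cluster → OTV; two
clusters → NMH; three clusters → PHR subject to the post-filters
(100% technical-replicate reproducibility, ≥ 3 minor homozygotes, and
four cluster-variance filters AB.varY / AA.varY / BB.varY / AB.varX).
The variance filters' thresholds are not published; we flag a cluster
whose variance exceeds `var_mult = 4` times the panel median
same-genotype variance (the Y dimension is size, X is contrast, per the
filter names), calibrated on synthetic data and configurable.
`otvRecall()` recodes the null cluster to ∅∅ and, when a null allele
segregates, homozygotes to A∅/B∅ — so a four-cluster AA × BB family
becomes A∅ × B∅ with progeny classes {A∅, AB, B∅, ∅∅}.

# Validation statistics

Concordance treats the null allele as transmissible: a progeny call is
concordant iff producible by one allele from each parent. Markers with
parental NoCalls are discarded; > 5% non-concordant informative progeny
discards the marker, while a smaller non-zero fraction converts the
offending calls to missing (attributed to individual-sample genotyping,
not the parents). Sequence-derived genotypes use a one-sided lower
binomial tail at the boundary null minor-allele frequency 1/8 — the
least favourable point of the composite null "MAF ≥ 1/8", which is what
makes a point-null implementation faithful — with α = 0.05 and a
20-read minimum; ties (k = n/2) are heterozygous by construction. MAF
is computed from dosage-collapsed calls with null alleles as an allele
class; polymorphism classes are monomorphic (0), low (< 0.10),
polymorphic (≥ 0.10) and highly polymorphic (≥ 0.35).

# The synthetic panel generator

`generatePanel()` emulates the discovery conditions: 19 accessions
represented by 20 VCF files (the first accession sequenced twice), file
coverages spanning 4–31× so that ten files reach 16× (HD-16, including
both duplicate files) and eight reach 20× (HD-20, excluding the
lower-coverage duplicate); four subgenomes; deletion blocks of fixed
subgenome loss producing locally reduced depth and effective ploidy;
and planted variants of every category with ground truth. Specifics
worth knowing before interpreting test results:

* **Inter-subgenome divergence is a free parameter.** No empirical HSV
  density is asserted; the default `hsv_rate = 2`/kb simply provides a
  dense HSV background at desk scale.
* **Placement uses non-overlapping slots** (≥ 160 bp apart), so planted
  markers are flank-clean *by construction*; deliberate decoys (a
  marker with a neighbour 10 bp away, a single-carrier variant, an A/T
  pair, an 8 bp indel, a haploSNP pair at offset 7) supply the
  filter-failure cases. Real data violate spacing constantly; passing
  recovery tests therefore demonstrates filter correctness, not
  robustness to clustered variation.
* **Read counts**: a carrier's supporting reads are Poisson
  (mean = copies × coverage/8) truncated below at `min_alt_reads = 2`,
  reflecting that a caller only emits a record where it saw the minimum
  alternate observations; non-carrier copies contribute Poisson depth.
  This guarantees planted carriers are observed, making "100% recovery
  of constraint-satisfying planted markers" a well-defined property
  under stochastic depths.
* **Intensities** are exact model centres times multiplicative
  log-normal noise `exp(N(0, noise_sd²))`, which keeps channels
  positive; `noise_sd = 0` gives exact centres. ∅∅ samples get
  background only. Effective ploidy per marker is taken from the truth
  table (deletions and haploSNP destabilisation), not re-derived.
* **Gene models** are uniformly spaced two-exon genes (CDS 2 × 399 bp,
  frame 0, alternating strand) covering a configurable fraction of the
  reference — enough to exercise CDS/genic filtering and proline-codon
  mining, with no attempt at realistic gene architecture.
* What the generator does **not** emulate: read-level errors and FASTQ
  simulation, alignment artefacts, PCR duplicates, paralogous (PSV)
  copies at non-identical coordinates, population structure, and
  linkage disequilibrium.

Coordinates are 1-based inclusive throughout (the Bioconductor
convention), matching emitted VCF/GFF3 directly.

# Problem sizes and determinism

The package-scale property tests run the full stack on a 500 kb,
two-chromosome, 19-accession panel with ~280 planted markers across all
eight categories plus several thousand codon sites (about 90 s
end-to-end); unit tests use 30–60 kb panels. All stochastic components
are seeded — the generator byte-identically, the EM via deterministic
quantile initialisation — so every reported number is reproducible.

# Known limitations

* The caller is one-dimensional in contrast; genuine two-dimensional
  cluster shapes (rotated ellipses, heteroscedastic size) are outside
  its model, which is why the variance post-filters act on simple
  per-cluster variances.
* Coupling of marker and destabiliser is accession-level, not
  read-level; a rare recombinant haplotype within an accession would
  not be detected from VCFs.
* The published chip-level feature count is not exactly reproducible
  from the stated tiling plans; `accountDesign()` reports features as
  2 × probes and documents the discrepancy rather than tuning to it.
* Indel flank interference is judged by left-aligned indel position,
  not by the full edited span.
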