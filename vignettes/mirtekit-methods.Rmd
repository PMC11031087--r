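---
title: "mirtekit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirtekit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtekit)
```

## What this package models

`mirtekit` is a desk-scale toolkit for the comparative analysis of a
transposon-derived, X-linked, testis-expressed miRNA family: where the
family came from (a DNA-transposon consensus that can fold into the
hairpin required for miRNA biogenesis), how its target repertoire looks
across species, whether its target sites sit under purifying selection,
and whether its loss measurably degrades sperm competitiveness. Every
analysis stage accepts either user data in standard formats or input from
the built-in synthetic generator, which produces all inputs with known
ground truth so the full pipeline is testable end to end.

## Seed-match target prediction

A mature miRNA recognises a 3'UTR chiefly through its seed, nucleotides
2–7. The scanner finds every UTR position whose sense strand pairs
antiparallel with the seed and assigns the canonical site classes: 6mer
(seed match only), 7mer-m8 (additional Watson–Crick match to miRNA
position 8), 7mer-A1 (adenine on the UTR opposite miRNA position 1), and
8mer (both). Coordinates are 0-based half-open in UTR space and span the
full matched element, so lengths are 6, 7, 7, and 8 respectively.

Design choices that were genuinely open:

* **Site classes.** Published analyses of this family delegate target
  prediction to external databases without stating their site rules,
  so we adopt the standard canonical taxonomy and expose *tiers* —
  scanning configurations of different stringency whose union defines the
  predicted target set, mirroring the union-of-databases rule. The
  defaults are a stringent tier (class ≥ 7mer, no wobble) and a
  permissive tier (6mer allowed, one G:U wobble). Tier labels travel with
  every site so downstream users can see which stringency produced it.
* **G:U wobble.** Wobble pairs are permitted only within the seed duplex
  (positions 2–7), never at the m8 match, and the A1 position must be a
  literal adenine — consistent with how the canonical classes are defined
  in the target-prediction literature. Each site records how many wobbles
  it used.
* **Collapsing.** At one seed locus the highest class wins; ties break by
  smallest start. Ambiguity codes never match. T is normalised to U on
  ingestion.

The scanner is verified exhaustively against a naive per-window
enumeration oracle on tens of thousands of random (UTR, miRNA) pairs; the
two implementations share no code.

## Differential expression and DET selection

The DE engine is intentionally lightweight: median-of-ratios size
factors, per-gene Welch tests on log2(normalised count + 0.5), and
Benjamini–Hochberg adjustment. It is *not* a DESeq2 reimplementation —
the scientific content here is the selection logic, and an ingestion path
for externally computed DE tables exists for users with full pipelines.
Reported log2 fold changes are ratios of group means (the pseudocount
enters only when a mean is zero), so exact count ratios give exact fold
changes.

DEGs are genes with |fold change| ≥ 2 and FDR strictly below 0.05, in
either direction — the family's validated targets include genes that go
*down* when the miRNAs are lost, so the rule is deliberately
direction-agnostic. A DET (differentially expressed target) is a DEG that
is also a predicted target of any family member. The pool collects DETs
supported by at least two knockout lines; whether the original analysis
also required a consistent direction across lines is unstated, so we pool
by gene identity and report per-line signs.

A caution that matters at n = 3: the Welch test has ≈ 4 degrees of
freedom, which puts a hard floor under attainable p-values. BH recall is
therefore extremely sensitive to the biological coefficient of variation;
see the dispersion note below.

## Cross-species target statistics

Orthology is an explicit input table, never inferred — gene-symbol
matching is a silent failure mode we refuse to guess at. A reference gene
is "shared" with another species when any family miRNA of that species
targets its ortholog; venn counts partition the reference set exactly.
Targets-per-miRNA means are restricted to a caller-supplied gene universe
(the original analysis restricted to a shared human–mouse target set),
and two species are compared by a Welch test on the per-miRNA count
vectors. Transposon-containing 3'UTRs are found by interval overlap
(≥ 1 bp), with a `max_distance` parameter approximating closest-feature
semantics.

## Conservation and population statistics

Per-base conservation scores (signed PhyloP-like or [0,1]
PhastCons-like) are mapped into UTR coordinates block by block; minus
strands are reversed so index 1 is always the UTR 5' end (score values
are strandless). Missing positions stay missing — never imputed.

The site-versus-non-site contrast computes, per gene, the mean score over
the union of site bases against the mean over the rest of the UTR, then a
paired t-test across genes. Whether the original cumulative-distribution
test used per-gene means or pooled bases is ambiguous, so the per-gene
paired test is primary and a pooled-bases Welch test is always reported
alongside; a Wilcoxon alternative sits behind a flag. Feature-class
summaries use one mean per feature as the test unit (per-base mode is a
switch) to avoid pseudoreplication, with Kruskal–Wallis omnibus and Dunn
post hoc under Holm adjustment — the post hoc procedure is our choice;
the source names only "adjusted p-values".

Nucleotide diversity uses MND = 2·DAF·(1−DAF), the expected
heterozygosity contribution of a biallelic site: zero at fixation,
maximal (0.5) at frequency 0.5, symmetric under allele relabelling.

## Transposon-origin screen

BLAST is replaced by exact Smith–Waterman with affine gaps (Gotoh; a gap
of length L costs `gap_open + L·gap_extend`), with defaults near BLASTN
scoring (+2/−3, −5/−2). Libraries at desk scale are small enough that
exactness is free. The screen keeps (transposon, locus) pairs at
≥ 94% identity over ≥ 50 aligned columns on either strand; the span and
strand policy are our parameters, surfaced explicitly, because the
original threshold was stated without coverage or strand detail.

Hairpin capability replaces thermodynamic folding: miRNA biogenesis
requires a stem-loop, not a particular free energy, so we maximise
Watson–Crick + G:U pairs (Nussinov recursion, minimum loop 3) over
sliding windows and call a sequence hairpin-capable when the best window
has ≥ 18 pairs, pairs ≥ 30% of its bases, and the traceback is a single
stem-loop with no multiloop. The 18-pair and 30% thresholds are our
defaults, not literature values; they pass miRNA-precursor-like perfect
inverted repeats and reject shuffled controls in the suite's specificity
check.

Substitution spectra tally directional reference→member substitutions per
alignment column. The reference defaults to the majority consensus
(ties broken alphabetically); a designated outgroup — e.g. the
transposon consensus itself — is available because the original polarity
convention is unstated.

## Competition statistics

Offspring counts by sire genotype are tested against the expected sperm
mix by Pearson chi-squared goodness of fit, df = 1, without Yates
correction: at the assay sizes in view (n ≈ 100–180) the correction is
immaterial and plain Pearson is the common default; an exact binomial
alternative is provided and advised whenever an expected count falls
below 1. A helper reconstructs integer counts from printed
(percentage, total) pairs with a sum-preservation check, which is how the
published assay statistics are re-derived exactly. Sired fractions carry
95% Wilson intervals. The litter-size trend is OLS of mean litter size
per genotype on the number of family miRNAs inactivated, with the
F-test for the slope; two-cell-rate comparisons use a paired t-test with
a signed-rank sensitivity check, and constant nonzero differences return
an explicit degenerate status rather than a fabricated p-value.

## The synthetic world

The generator emulates, under one master seed with per-stage sub-streams
(adding a stage never perturbs earlier draws):

* a 120-nt transposon-like ancestor built as an inverted repeat (hence
  hairpin-capable) from which each species' precursor loci descend by
  biased substitution at ~3% divergence — chosen so descendants sit above
  the 94% identity screen, as the recovered family did. U→C and A→G carry
  double weight, reflecting ADAR-style editing pressure; seed positions
  mutate at 0.2× the background rate, reflecting the observed seed
  conservation. Both weights are round, defensible stand-ins — the source
  reports a qualitative dominance, not rates;
* per-species 3'UTR sets (uniform lengths 200–500 bp, uniform base
  composition — configurable because seed-match null rates depend on it)
  with an 80% ortholog fraction, in the vicinity of the reported
  cross-species target sharing;
* implanted 8mer elements at non-overlapping positions ≥ 2 nt apart so
  per-site truth stays unambiguous, with optional single G:U wobbles;
* negative-binomial counts, 3 replicates per group, expected library
  size 10⁶, dispersion 0.01 — biological CV 0.1, the standard rule of
  thumb for genetically identical model organisms, which the inbred
  knockout/wild-type design is. (An early working guess of 0.1
  corresponded to human-cohort variability and was corrected on that
  domain ground; with df ≈ 4 Welch tests this single parameter dominates
  DE power, which is worth knowing before trusting any green recall
  test.) Perturbed targets are multiplied by 2^(±2) with per-gene signs;
* conservation tracks as Normal(base mean, SD 1) noise plus a +0.5
  elevation inside true sites;
* per-class derived-allele frequencies from Beta distributions; and
* binomial paternity counts.

What a green test does **not** establish: the generator has no 5'UTR/CDS
context, no GC heterogeneity, no length-dependent conservation structure,
no mean–dispersion trend, no linkage between variants — so recovery
results certify the *logic* of the pipeline, not its performance on real
genomes. Effect-size magnitudes for target perturbation are free
parameters, not measured values.

## Reproducibility

All randomness flows from explicit seeds; `run_pipeline()` writes
per-stage manifests with parameter blocks and output checksums, and its
report contains no timestamps, so a fixed seed reproduces a
byte-identical report (this is asserted in the acceptance suite). The
published headline counts that depend on external database versions
(thousands of DETs, specific venn counts, ~1268 vs ~1068 targets per
miRNA) are out of scope by design: the package reproduces the
*statistics*, and the only published numbers re-derived exactly are the
competition assay tests, which are fully determined by printed
percentages and totals.
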