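---
title: "Methods: the sRNA landscape pipeline and its synthetic validation"
author: "srnascape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the sRNA landscape pipeline and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnascape)
```

## Scope and model

`srnascape` analyses the small-noncoding-RNA landscape of a compact
prokaryotic genome from four inputs: a gene annotation with optional
UTR sub-features, assembled single-exon transcripts, replicate read
counts under two conditions, and the genome sequence. The archetype is
an archaeal oxidative-stress experiment — five replicate cultures per
condition, strand-specific size-selected libraries — but nothing in the
package is organism-specific.

Only single-exon (unspliced) transcripts are modelled: archaeal and
bacterial transcripts are not spliced, and multi-exon input is rejected
rather than silently flattened. UTRs are taken from the annotation, not
predicted; genes lacking them (leaderless mRNAs, the majority in
haloarchaea) simply have zero-length UTRs for all downstream logic.

All internal coordinates are 0-based half-open, so the overlap of two
intervals is `max(0, min(ends) - max(starts))` with no ±1 corrections;
GFF3/GTF I/O converts to and from the formats' 1-based inclusive
convention at the boundary, and round-trip identity is property-tested.

## Classification

A transcript is **antisense** when it overlaps at least `min_overlap`
(default 8) nt of one or more genes on the opposite strand and no gene
on its own strand, **intergenic** when it overlaps no gene on either
strand. Two populations are excluded rather than classified:
same-strand overlaps (indistinguishable from the gene's own
transcription in coverage data) and opposite-strand overlaps of 1–7 nt.
Design choices made where the convention was genuinely open:

* "Gene" means the annotated gene span including UTRs, with no
  additional flank: UTRs are the only regulatory elements the
  annotation carries.
* Antisense takes precedence over intergenic for transcripts that
  overlap a gene and also extend into intergenic space.
* Intergenic requires only zero gene overlap; it does not require both
  flanking neighbours to be annotated genes.

Each antisense sRNA is paired with every opposite-strand gene it
overlaps by ≥ `min_overlap` nt (an sRNA spanning the gap between two
adjacent genes legitimately yields two pairs); the pair with maximal
overlap is the primary target. The binding region of a pair is the gene
region (5′ UTR, CDS, 3′ UTR) holding the maximal share of the overlap.
Ties are broken 5′ UTR > 3′ UTR > CDS — UTR contact is the
mechanistically informative call — which keeps the three bins mutually
exclusive and exhaustive. Overlap summary statistics (median, mean,
range, 50-nt histogram) are computed over primary-target overlaps only,
since one distribution per sRNA is the useful readout.

Classification is implemented with interval-indexed queries
(GenomicRanges) and is required by the test suite to agree exactly with
a naive per-base membership count on a thousand random genomes, and to
be invariant under coordinate translation and global strand flip.

## Quantification and filtering

TPM is the standard length-normalised measure; its per-sample sum is
10⁶ by construction (checked to a relative tolerance of 10⁻⁹), and
all-zero samples produce all-zero columns with a warning rather than
NaNs. TPM is used (rather than RPKM/FPKM) because sRNAs are
systematically shorter than mRNAs and cross-library comparison should
not depend on the mean expressed transcript length.

The candidate filter is two-pronged and per condition: presence
(nonzero TPM) in at least `min_replicates` (default 4) of the
condition's replicates, and a class-specific expression threshold —
40 TPM for antisense, 14 TPM for intergenic sRNAs — applied to the
condition mean. Whether such thresholds should bind per replicate or on
the mean is ambiguous in general practice; the mean is the default
(matching a threshold stated as "average with standard deviation from
replicates") and `on = "per_replicate"` exposes the alternative. An
sRNA may pass under one condition only, which is why per-condition sRNA
totals differ.

## Paired cis-pair tests

For each primary pair the per-replicate TPM difference d = sRNA −
target is tested with a two-sided paired t statistic, t = d̄/(s_d/√n)
on n − 1 df. Degenerate inputs have defined limits: all-zero
differences give t = 0, p = 1; constant nonzero differences give p = 0.
The wording "pairwise t test" could also mean an unpaired comparison,
so a Welch option is exposed (`paired = FALSE`), with paired-by-
replicate as the default. The test runs on raw TPM by default because
expression ratios are the quantity of interest; `log_transform = TRUE`
tests log2(TPM + 1) instead. No multiple-testing correction is applied
at this stage — the raw p < α flag mirrors how per-pair significance is
conventionally reported for this analysis, while FDR control is
reserved for the genome-wide DE stage. Calibration is enforced by test:
on null NB pairs (5 + 5), the rejection rate at α = 0.05 must lie
within two Monte-Carlo standard errors of 0.05, and swapping the two
vectors must exactly negate t and preserve p.

## Differential expression

The DE stage is a deliberately transparent NB pipeline rather than a
wrapper around a full shrinkage-based package: its contract is
statistical correctness (calibration and recovery, enforced by the
acceptance tests), not replication of any particular tool's estimator.

* **Size factors** are median-of-ratios against a per-feature geometric
  mean reference (features containing any zero are excluded from the
  reference), rescaled to geometric mean 1. When every feature contains
  a zero the function errors and points at the pseudo-reference option
  rather than guessing.
* **Dispersion** is per-feature method-of-moments,
  α̂ = (s² − μ̂)/μ̂², pooled across conditions by degrees of freedom and
  floored at 10⁻⁸ (the Poisson limit). No shrinkage: at n = 5 the
  estimates are noisy, which the Wald test's calibration tests account
  for.
* **The Wald test** uses log₂((m₂ + ½)/(m₁ + ½)) with the ½
  pseudo-count applied both in the fold change and inside the
  delta-method variance (Var(mean) = (μ + αμ²)/n evaluated at the
  shifted mean), so standard errors stay finite at zero counts. Two-
  sided p-values come from the normal reference.
* **BH adjustment** is the step-up procedure with monotonicity
  enforcement, and the FDR threshold is inclusive (q ≤ 0.05 is called).

Enforced operating characteristics: on complete-null simulations the
false-call fraction at FDR 0.05 stays ≤ 0.07 averaged over 50 seeds; on
planted |log₂FC| = 2 at high expression (5 vs 5) at least 80% of
features are called with the correct sign; size factors recover planted
library depths to a mean relative error below 5%.

## Regulatory effects

Cross-tabulation assigns each primary pair the combination of its
sRNA's and its target's DE calls; the discordant cells (up/down,
down/up) flag candidate negative regulation. Pairs missing a DE call
for either member are warned about and listed, never silently dropped.

Functional enrichment replaces non-reproducible web services with a
one-sided hypergeometric upper tail, P[X ≥ k] for X ~ Hypergeom(N, K,
n), BH-adjusted across categories. The universe defaults to genes with
a DE call — the set actually eligible to appear in the target list —
rather than all annotated genes, and is configurable. The
implementation must match exhaustive enumeration of the pmf for all
N ≤ 30 in the acceptance suite.

## Promoter motifs

Windows run 100 nt up- and downstream of the sRNA TSS, reported 5′→3′
in transcription direction (reverse-complemented for minus-strand
sRNAs) with TSS-relative coordinates: the TSS parameter is the
transcript's 5′ boundary in half-open coordinates, position 0 is the
first transcribed base, upstream is negative. Windows truncate at
replicon edges with the truncation recorded.

Scanning is a deterministic log₂-odds PWM slide in the given
orientation only (basal promoter elements are directional), reporting
the best-scoring offset at or above the model threshold; ties go to the
most-upstream position, and a hit's position is its motif centre. The
default models are built from IUPAC consensus strings with the
threshold set to the minimal consensus-match score, so a hit is exactly
an IUPAC match. The shipped defaults are high-information octamers
around the purine-rich BRE core and the A/T-rich TATA box
(`CGAAAGTT`, `TTTATATA`) with expected centroids −38 and −29 nt: real
archaeal BRE/TATA consensus are shorter and more degenerate, and a
production analysis of a real genome should supply organism-specific
matrices; the octamer defaults trade biological looseness for a
per-offset chance-match rate of ~1.5 × 10⁻⁵, which keeps centroid
estimates meaningful on 200-nt windows.

The promoter fraction counts sRNAs whose **both** motifs hit within
each model's tolerance (default ±3 nt) of its expected centroid;
"relaxed" widens each tolerance by 3 nt on both sides, read as a
widened tolerance rather than a shifted window, and can therefore never
fall below the strict fraction.

## The synthetic-data generator

The generator defines the study conditions the tests run under; its
defaults are fixed once and are not dials:

* 60 non-overlapping genes on a 200-kb replicon, CDS 300–1500 nt, UTRs
  20–60 nt where present, 60% of genes leaderless, ≥ 80 nt intergenic
  gaps. These mirror a gene-dense prokaryotic chromosome at roughly
  its natural coding density.
* 40 antisense sRNAs (binding regions drawn 7% / 26% / 67% for
  5′ UTR / 3′ UTR / CDS), 15 intergenic sRNAs, 8 sense-overlap decoys
  and 8 sub-8-nt-overlap decoys; sRNA lengths 50–1000 nt. An asRNA's
  overlap is confined to its intended region, with any length excess
  extended away from the gene and clipped clear of neighbouring genes,
  so the intended binding region is recoverable by construction.
* Counts are NB(μ, α) with α = 0.05 (variance μ + αμ²), base
  expressions log-uniform over 20–2000 abundance units, expected counts
  proportional to feature length so TPM normalisation is exercised, and
  per-sample library depths drawn log-uniformly over a 2-fold range so
  size-factor estimation is non-trivial. Five replicates per condition.
* 25% of asRNA cis pairs are planted anti-correlated (sRNA +2, target
  −2 log₂ units) at high expression; 20% of the remaining features get
  a ±2 log₂ fold change; 15% of planted sRNAs are set to sub-threshold
  expression and must be removed by the filter.
* 30% of planted sRNAs receive both promoter motifs, centred at −38
  (BRE) and −29 (TATA). A recipient's motifs are only planted where
  they fall into no other candidate's scan window: without that
  constraint a motif planted for one sRNA can appear, mispositioned, in
  a neighbour's window, and the recorded truth would be ambiguous.
  Chance background matches of the octamers in the 200-kb random
  genome (~3 expected genome-wide) remain, which is why positional
  recovery is asserted on multi-genome averages (±1 nt) rather than
  per window.

Every generator is deterministic under its seed (`withr::with_seed`;
sub-stages use fixed offsets from the base seed). What the synthetic
data does **not** emulate: read-level artefacts (coverage unevenness,
mapping ambiguity, strand bleed-through), overlapping genes, operons,
multi-replicon genomes, and correlated counts between an asRNA and its
target arising from shared sequencing signal. Passing tests therefore
demonstrate correctness of the analysis logic under the stated model,
not robustness to upstream artefacts.

## Problem sizes and numerical choices

The test and acceptance workloads are sized for a laptop-class single
CPU: 1000 random genomes for the classification oracle, 2500 null pairs
for paired-test calibration, 50 seeds for DE calibration and
discordant-pair recovery, 30–50 genomes for motif recovery. Tolerances
follow the estimator's Monte-Carlo standard error, never the other way
around. Fixed tie-breaks (most-upstream motif hit, 5′ UTR-first region
precedence, gene-id ordering for equal overlaps) make every output
byte-reproducible; `run_pipeline` is deterministic given its config,
and repeated runs are verified identical by checksum.

## Known limitations

* The DE stage's method-of-moments dispersion is inefficient at n = 5;
  it is calibrated (null false calls ≤ 7%) but less powerful than
  shrinkage estimators for weakly expressed features.
* The paired t test on raw TPM inherits TPM's compositionality: a few
  extremely expressed features shift everyone else's TPM.
* Binding-region bins describe overlap geometry only; no hybridisation
  energetics or accessibility model is attempted, and no targets are
  predicted for intergenic sRNAs.
* The default promoter models are synthetic stand-ins for
  organism-specific PWMs, as discussed above.
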