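---
title: "Classifying colorectal tumors by broad copy number aberrations"
author: "bcnascore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying colorectal tumors by broad copy number aberrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcnascore)
```

## The problem

Colorectal cancers vary enormously in aneuploidy. Microsatellite-instable
(MSI) tumors are near-diploid, while microsatellite-stable (MSS) tumors
typically show many broad copy number aberrations (BCNAs) — gains or
losses covering more than a quarter of a chromosome arm, or whole
chromosomes. A minority of MSS tumors, however, have an almost normal
karyotype, and this low-aneuploidy MSS subset is biologically distinct
(enriched for mucinous histology, with a secretory expression program
partly shared with MSI tumors). `bcnascore` implements the full analysis
that identifies that subset: BCNA calling from marker-level copy-number
tracks, a per-sample BCNA score, MSI typing, a quartile-based low-BCNA /
high-BCNA (LB/HB) split of the MSS samples, and tumor-group versus normal
expression contrasts with a specific/shared DEG cross-classification.

Because the per-sample data behind the original cohort are not bundled,
the package ships a synthetic-cohort generator with known ground truth;
every stage is exercised against implants whose recovery can be verified
exactly.

## Copy-number model and the calling procedure

Each marker carries a log2 ratio $r$ of sample intensity to the reference
median. Ratios are **calibrated** to a copy-number-like scale anchored at
the diploid value 2:

$$c = 2 \cdot 2^{r}.$$

A marker is a *gain* when $c > 2.21$ and a *loss* when $c < 1.74$
(mean ± 2 SD of a diploid control group on autosomes and the female X;
male X and Y use 1.24 and 0.81 because a single copy is the baseline).
All comparisons are strict: a marker at exactly 2.21 is neutral.

Calling proceeds in three steps per sample:

1. **Isosegments** — maximal runs of at least 50 contiguous markers with
   the same direction, confined to one arm. Any neutral or
   opposite-direction marker breaks a run, as does an arm boundary.
   Markers in centromeric gaps or on unassigned scaffolds are removed
   before run detection.
2. **Joining** — same-arm, same-type isosegments are chained transitively
   whenever the base-pair distance from the last marker of one to the
   first marker of the next is below the intersegment-gap limit. The
   limit is not part of the published threshold set; the default here is
   1 Mb and it is configurable (`default_thresholds()`).
3. **Filtering** — a candidate span is retained only if (a) its mean
   calibrated value over *every* marker in the span, gap markers
   included, strictly passes the direction's threshold, and (b) the span
   covers strictly more than 25% of the arm.

Whether the span mean should include opposite-direction markers inside
gaps is not specified by the method's description; this implementation
includes all span markers, which makes the mean a property of the
genomic interval rather than of the segment subset. The brute-force
oracle used in the tests makes the same choice, so the equivalence
checks validate the chaining/maximality logic, not this convention.

A whole-chromosome event is deliberately represented as one call per
arm: the 25% condition is defined per arm, and consolidation to a
whole-chromosome unit happens in scoring, where the rules operate on
per-arm coverage percentages.

## The p-q-w score

For each chromosome and aberration type, let $\%p$ and $\%q$ be the
percentages of each arm covered by retained calls. The attribution rules:

* one involved arm only (including the q arm of an acrocentric
  chromosome, which has no usable p arm): score 1 to that arm;
* both arms involved and $\%p + \%q > 150$: score 1 to the whole
  chromosome (unit "w");
* both arms involved and $\%p + \%q < 150$: score 1 to each arm.

The per-sample **BCNA score** is the sum of attributions. The rules are
silent about $\%p + \%q = 150$ exactly; since consolidation is phrased
as "greater than 150", this implementation attributes the tie to both
arms (total 2). Gains and losses are scored independently — a gain on p
and a loss on q are two arm attributions, never a "w".

Under the alternative **p-q** system a whole-chromosome aberration counts
2 (one per arm) instead of 1. `total_score()` supports both; all
attributions are always derived under the p-q-w rules first.

### LB/HB classification

MSI samples are set aside (their status comes from the microsatellite
panel, not the score). The remaining MSS scores are split at their first
quartile: strictly below is LB, otherwise HB. The quartile estimator is
linear interpolation at plotting position $(k-1)/(n-1)$
(`stats::quantile` type 7): with 28 MSS scores whose 7th and 8th order
statistics are 5 and 6, Q1 is $5 + 0.75 \times 1 = 5.75$, which
reproduces the published threshold and the 7/21 LB/HB split. The
estimator is configurable because the published value constrains but
does not uniquely determine it.

Two degenerate behaviours of the strict-< rule are worth knowing. With
identical scores Q1 equals the common value, nothing is strictly below
it, and every sample is HB. With a half-low/half-high bimodal sample
such as {0,0,0,0,10,10,10,10} the type-7 Q1 is 0, so the zero-score
samples are *not* LB; an estimator that interpolates between the modes
would classify them LB. The tests pin the implemented behaviour.

### Is the split robust to the scoring system?

For a cohort with no whole-chromosome attributions the two systems give
identical scores, hence identical membership. When "w" events are
present, the p-q system adds one point per whole chromosome, which can
reorder samples around Q1; the property tests search random cohorts for
such counterexamples, and the analysis scripts report whether membership
moved for the concrete cohort analysed. On cohorts emulating the
published composition membership is usually, but not provably always,
preserved.

## MSI typing

A sample is MSI if at least 30% (inclusive) of its informative
microsatellite markers are unstable; the default panel is the Bethesda
five (D2S123, D5S346, D17S250, BAT25, BAT26) plus BAT40, so 2/6
unstable markers already qualify. Failed assays are excluded from the
denominator by default — a failed marker carries no instability
information — with `failed_as_stable = TRUE` available because the
original description does not say how failures were handled.

## Expression contrasts

Inputs are RMA-like log2 expression values. Genes are first filtered on
annotation: no symbol, placeholder "OTTHUMG" symbols, sole descriptions
beginning "uncharacterized LOC", small-RNA classes (snoRNA, scaRNA,
snRNA, NF90-associated, 5S/5.8S rRNA (pseudo)genes, Y RNA,
mitochondrial rRNA, microRNA), olfactory receptor and histone cluster
genes, and 23 unplaced/haplotype scaffolds. The patterns ship as an
editable TSV (`inst/extdata/gene_exclusion_rules.tsv`).

For each tumor group $g$ and gene, with group means $m_g$ and $m_N$ on
the log2 scale and $\Delta = m_g - m_N$, the signed linear fold change is

$$\mathrm{FC} = \begin{cases} 2^{\Delta} & \Delta > 0 \\ -2^{-\Delta} & \Delta < 0 \\ 1 & \Delta = 0, \end{cases}$$

so a halving is −2 and no value lies strictly inside (−1, 1). The
equal-means case is reported as 1 by convention (the published formula
covers only the strict inequalities). Significance comes from a one-way
ANOVA of the two groups — implemented as the algebraically identical
pooled-variance F test, vectorised across genes and cross-checked
against `oneway.test` — with Benjamini–Hochberg adjustment across all
retained genes *within each contrast* (the conventional reading;
adjusting across contrasts jointly is the other defensible choice).
Zero-within-variance genes are flagged `degenerate` and given p = 1 when
the groups are identical rather than raising an error. A two-group
ANOVA was chosen over a four-group ANOVA with post-hoc contrasts
because each published comparison is a single group against normal
colon; the contrast surface takes a `tumor_groups` argument, so a
different family can be assembled.

DEGs are cross-classified by the literal threshold grids: a gene is
"specific" to group set $S$ (up direction) iff FC > 2 and FDR < 0.05 in
every group of $S$ while FC < 2 and FDR ≥ 0.05 in every other group;
down-regulation mirrors with −2. FDR exactly 0.05 is non-significant
(significance is defined as FDR < 0.05); FC exactly at the cut matches
neither side of the grid and leaves the gene unassigned — the grids'
rows are mutually exclusive but not exhaustive. Top-ranked lists order
significant genes by FC with FDR-then-symbol tie-breaks.

## The synthetic cohort

The generator emulates the study's inputs, not its biology:

* **Marker tracks** — markers every 100 kb (≈30k genome-wide; dense
  enough that any event above a quarter of an arm far exceeds the
  50-marker rule), Gaussian noise on the log2 scale (default SD 0.1 — a
  fixture, since no platform noise magnitude is published), implants
  shifted so the expected calibrated value equals the event magnitude
  (3 for a one-copy gain, 1 for a one-copy loss). Arm boundaries are a
  bundled hg19-like table; acrocentric chromosomes (13, 14, 15, 21, 22)
  carry no usable p arm. Tumor purity is not modelled: magnitudes are
  effective, possibly contamination-attenuated values.
* **Cohort preset** — `published_cohort_config()` reproduces the published
  composition: 33 tumors (21 HB, 7 LB, 5 MSI) and 25 normals. LB
  samples carry 0–5 implanted events, HB samples 6–21 (centred near
  13), MSI samples few. Each event sits on its own chromosome, either a
  single arm (fraction 0.35–1) or a whole chromosome, so the
  ground-truth score equals the implant count under p-q-w. Because LB
  is exactly a quarter of the MSS samples and LB scores (≤5) sit below
  HB scores (≥6), the first-quartile rule lands strictly between the
  two blocks and reproduces the generator's labels — the same
  self-consistency the published 7-of-28 split exhibits.
* **Microsatellite panel** — MSI samples draw 2–6 unstable markers of
  6, MSS samples 0–1.
* **Histology/site labels** — drawn with the published group
  compositions as weights (e.g. mucinous enrichment in LB).
* **Expression** — per-gene baseline ~N(7, 1.5²), plus ±2 log2 in the
  affected group(s) for a panel of genes covering all fourteen
  specific/shared truth categories, plus N(0, 0.3²) noise.

What passing tests on this cohort do **not** show: robustness to wavy
baselines, GC artefacts, purity dilution, segmental noise correlation,
or annotation messiness of real arrays. The generator is a correctness
harness for the rules, not a platform simulator.

## Numerical choices and degenerate inputs

* Strict inequalities at every calling threshold and at the 150 rule's
  w-clause; ties documented above.
* Intersegment distance is measured marker-to-marker in base pairs;
  joining chains gaps transitively (each gap individually under the
  limit, not the end-to-end distance).
* Coordinates are 1-based inclusive in all TSV/SEG outputs; the arm
  table is BED-like 0-based half-open on disk, converted explicitly.
* Fewer than 4 MSS scores: classification refuses (quartile unstable).
  Samples with zero calls are absent from SEG files by construction;
  `score_cohort(samples = ...)` re-admits them with score 0 so reruns
  from intermediates match the end-to-end run.
* All randomness flows from a single integer seed; identical
  configurations are bit-identical.

## Problem sizes used in the checks

The bundled verification runs use cohorts of 14–58 samples, tracks of
up to ~30k markers, oracle comparisons on 200 random tracks of up to
2,000 markers, 100 noisy implant-recovery samples, and expression
studies of ~500 genes at n = 10 per group — sizes chosen so the whole
suite re-runs in about a minute while every rule is exercised at the
scales its definition cares about (runs of 50, quarters of arms,
quartiles of 28).

## Known limitations

* No focal-CNA calling, no allele-specific copy number, no CBS/HMM
  segmentation alternatives; the caller is the rule set above.
* The intersegment-gap default stands in for a threshold published
  elsewhere; conclusions sensitive to it should sweep it.
* Consensus-molecular-subtype assignment, raw-array processing and
  functional enrichment are out of scope.
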