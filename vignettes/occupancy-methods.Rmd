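---
title: "Methods: CpG-island promoter occupancy and TrxG co-occupancy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CpG-island promoter occupancy and TrxG co-occupancy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trxgtools)
```

## The analysis in one paragraph

CFP1 (CXXC1) is a CxxC zinc-finger protein that reads unmethylated CpG
dinucleotides and anchors SET1A/B H3K4-methyltransferase complexes of
the Trithorax group (TrxG). A genome-wide occupancy study of such a
factor asks a chain of quantitative questions: where do its ChIP peaks
fall relative to CpG islands (CGIs), TSSs and gene bodies; how does
occupancy differ between housekeeping and tissue-specific promoters;
is it present at accessible non-promoter elements (enhancers); is it
mutually exclusive with Polycomb (H3K27me3) chromatin; which other
TrxG subunits co-occupy its sites; and how much of its ChIP signal is
explained, additively, by CpG density, H3K4me3 and SET1A. `trxgtools`
implements that chain as nine reusable stages operating on standard
file formats, plus a synthetic-epigenome generator that plants ground
truth for every stage.

## Coordinate conventions

On disk the package speaks the field's formats: BED, bedGraph and
narrowPeak are 0-based half-open; GTF is 1-based inclusive. In memory
all intervals are `GRanges` (1-based, closed — the Bioconductor
convention) and all point features (TSSs, summits, window centres) are
1-based positions; readers and writers perform the conversion. A peak
file without a summit column gets the floored interval midpoint.
Distances between intervals are gaps in bases: 0 for overlapping or
book-ended intervals, and undefined (`NA`) across chromosomes, so a
caller can never mistake a cross-chromosome pair for a far one.

## Signal tracks

Coverage is binned at 50 bp. `normalize_1x()` divides a track by its
genome-wide mean bin value, which makes the mean exactly 1 ("1x"
coverage) — on binned input this is algebraically the same
normalisation as scaling read counts to one-fold genome coverage, but
requires no read-level data. `subtract_input()` then removes the
similarly normalized input track; negative values are kept because
depletion below input is informative, and only the display transform
`threshold_log()` (log2(1 + max(x, floor))) clips them.

CpG density is expressed in percent-of-positions units: a bin's value
is 100 × (number of CG dinucleotide starts in the bin) / bin width, so
five CpGs in a 50-bp window score 10%. A CG straddling a bin boundary
belongs to the bin containing its C — a deterministic rule that keeps
the genome-wide count exact. Dinucleotides containing ambiguous bases
never match.

Window statistics (`window_means()`, `build_signal_matrix()`) average
the bins whose *midpoints* fall in the half-open window around a
centre. Because midpoints form a lattice with the bin spacing, a
window of width 2·flank always selects exactly 2·flank/bin bins, so
heatmap matrices have a fixed column count and their row means agree
with `window_means()` bin for bin. Windows truncated at chromosome
ends average only existing bins; heatmap cells beyond the end are `NA`
and excluded from summaries. How a window at a chromosome edge should
be treated is genuinely a convention, and this truncate-and-pad choice
is ours.

## Gene classes

Housekeeping calls use three clauses on the multi-tissue RPKM profile:
expression everywhere (RPKM ≥ 0.1 in every tissue), stability
(sd of log2 RPKM < 1, sample denominator) and no outlier tissue
(|log2(RPKM / mean RPKM)| ≤ 2, i.e. all ratios below 4 in either
direction, with an arithmetic mean). "Thresholded at 0.1" is read as
flooring: clause 1 tests the raw values, while logarithms are taken on
values floored at 0.1 so they stay finite; the floor is a parameter
for users who prefer filtering. Tissue-specific calls are two-step: a
gene is *normally non-expressed* when all reference RPKMs are ≤ 0.1 or
strictly more than half of the tissues sit at or below 10% of its
maximum ("more than half" of 16 means at least nine), and such a
candidate is tissue-specific in a target cell whose (replicate-
averaged) expression reaches half the maximum. The two labels are
mutually exclusive by construction, and the tissue-specific call is
monotone in the cell's expression. Gene class is a per-gene property
propagated to all of a gene's TSSs, while CGI and accessibility flags
are per-TSS.

## Feature calls

A TSS is *accessible* when any ATAC bin with midpoint within 1 kb
exceeds 10 on the normalized, subtracted track. *Putative enhancers*
are runs of bins jointly exceeding ATAC > 10 and Pol II > 5 whose
midpoints lie more than 2 kb from every TSS. The thresholds come from
the analysis this package reimplements; whether they apply per bin or
per region mean was not specified there, so per-bin is the default and
the merge gap (0 bins) and minimum width (1 bin) are exposed as
parameters. Region midpoints (floored) serve as locus centres
downstream, and every emitted call carries its midpoint-to-TSS
distance so the > 2 kb invariant can be asserted on output.

## Co-occupancy statistics

Two peaks are *colocalised* when the gap between their intervals is at
most 1 kb. Multi-set counting is component-based: peaks of all sets
are nodes, near-pairs are edges, and each connected component is one
region labelled by the subset of peak sets present — so chained peaks
are counted once and every peak belongs to exactly one component.
Whether published Venn counts treat chains this way is typically
unstated; transitive closure is the deterministic choice and is
cross-checked against a brute-force union-find oracle in the tests.

*High-confidence regions* keep, per peak set, the most enriched tenth
(scores at or above the 90th percentile, linear interpolation, ties
included so the top decile is never truncated), then merge the union.
*Over-representation* of k of n peaks in regions covering a fraction f
of the genome is fold = (k/n)/f with a one-sided upper binomial tail
P(X ≥ k) summed in log space (log-sum-exp over `dbinom` log terms), so
p-values far below double underflow remain usable via `log10_p`.
*Mutual exclusivity* of two signals at loci uses 2-kb window means
split at per-track thresholds — the 75th percentiles over the loci by
default, since the original presentation is a density plot without
stated cutoffs — and summarises the quadrants by the odds ratio with
the Haldane–Anscombe +0.5 correction when a cell is empty. 2×2
contingency tables get the sample odds ratio ad/bc and the exact
conditional (hypergeometric) two-sided p. Complex allocation assigns
each representative peak the first matching category — CGI TSS,
non-CGI TSS, enhancer, other — and reports Poisson standard errors
√k/n on the category proportions, reflecting counting noise in peak
numbers; a binomial SE is available as an option.

## The signal model

The locus set is the union of TSS points and enhancer midpoints with
exact duplicates removed; each locus carries 2-kb window means of
every track plus CpG density. Chromatin accessibility combines DNase
and ATAC by z-scoring each across loci (sample SD) and averaging,
giving both assays equal weight; the score is invariant to affine
rescaling of either input. Restricting to the top accessibility decile
(ties included), the variance decomposition fits OLS of the target
signal on CpG density, H3K4me3 and SET1A with an intercept and reports
the coefficient table, each feature's single-feature R², the joint
multiple R² (multiple, not adjusted — our reading of the original
"fraction of signal explained"), and the ANOVA partition both
sequentially in the stated feature order and as each feature's
contribution when added last, since the original table's convention is
not fully recoverable. Motif-occurrence scanning matches an IUPAC
consensus exactly on both strands (overlapping matches counted,
palindromes once per strandless position) and reports the fraction of
match starts inside CGIs together with the fraction of genomic CpGs
inside CGIs as the natural baseline.

## The synthetic epigenome

The generator emulates the statistical structure the analysis needs,
at desk scale: two 1-Mb chromosomes; 300 genes at 3-kb spacing with
jitter, half with a CGI planted over the TSS and half more than 1 kb
from any CGI; 90 housekeeping, 30 ERY- and 30 EBV-specific, 90 silent
Polycomb-marked and 60 unclassified genes; 50 enhancers per cell type
planted in a gene-free zone more than 3 kb from every TSS; and 40
gene-free CGIs. Background sequence carries ~1% CG dinucleotide
starts (iid bases with CG thinning); island segments are GC-rich with
16% of positions planted as CG starts, comfortably above the 10%
definition of a high-CpG island. These sizes were chosen so that the
top accessibility decile holds ~35 loci mixing TSSs and enhancers —
enough leverage to identify three regression coefficients — while the
whole suite runs in minutes on one CPU; the vignette states them as
the package's study conditions and the tests and acceptance checks use
them unchanged.

Signals are Gaussian bumps on bins: sd 150 bp for TSS marks, 100 bp
for accessibility and Pol II, 300 bp for the broad H3K27me3 mark, and
two bumps at ±500 bp for the bimodal H3K4me1 enhancer signature.
Amplitudes are drawn per site in normalized, input-subtracted units;
enhancer ATAC and Pol II amplitudes are three times their calling
thresholds (30 and 15) over background noise of unit scale. The target
track is the planted linear model CFP1 = 0.05·CpG% + 0.15·H3K4me3 +
0.20·SET1A + ε per bin. Two generator choices matter for honest
validation:

* **Back-transform.** The model is planted in normalized-subtracted
  units, but files are raw coverage. Each raw track is
  depth × (K·clean + 1 + |N(0, σ)|) with K = (1 + E|noise|)/(1 − mean
  clean), and the input track is depth × (1 + |N(0, σ)|). Running
  `normalize_1x()` and `subtract_input()` on these files returns the
  planted clean signal up to a constant offset (absorbed by intercepts
  and percentile thresholds) plus noise. The construction requires the
  planted signal mass to stay below 1x mean coverage; the generator
  checks this and rejects configurations that violate it.
* **Half-normal noise.** Both the background noise and the CFP1 model
  noise ε are half-normal, so raw coverage is non-negative without
  clamping. Clamping at zero would bias low-signal windows upward and
  leak into the regression's coefficient recovery; a non-negative
  noise term instead shifts only the intercept. The regression noise
  scale (σ = 0.5 per bin) leaves clear separation between active and
  silent promoter windows while keeping coefficient standard errors
  (≈ 3–8% of the planted values) well above the residual biases of
  normalization (≈ 0.5%).

Expression matrices are constructed to satisfy or violate the
gene-class clauses *provably*: housekeeping genes are log-uniform
around a base ≥ 2 with deviations bounded at ±0.8 log2 (so sd < 0.8
and ratios < 2^1.6 hold for any draw); tissue-specific genes put one
home tissue at 20–60 RPKM with all others at most 9% of it; silent
genes stay below 0.08 RPKM everywhere with cell expression below 40%
of their maximum; and filler genes are bimodal with the low mode at
11–15% of the maximum, which forces the log-SD above 1 while keeping
every tissue above the 10% candidate cutoff. Label recovery is
therefore exact by design, and the tests assert zero errors.

What the generator does **not** emulate: realistic nucleotide
composition and repeat structure, read-level sampling noise,
fragment-size effects, copy-number and mappability artefacts,
antibody-efficiency differences between ChIPs, and enhancer–gene
regulatory assignment. Passing the planted-recovery tests shows the
*operations* are correct at realistic signal-to-noise, not that the
thresholds would be optimal on any particular real data set.

## Numerical choices and degenerate inputs

Percentile thresholds use R's default type-7 quantile (linear
interpolation) with ties kept at or above the threshold. The binomial
tail is summed in log space; tests require agreement with exact
enumeration for n ≤ 20 at 1e-12 and with the library tail for n ≤
1000 at 1e-10 relative error, with deep-tail cases compared in log
space. Odds ratios apply +0.5 only when a cell is zero. OLS is
delegated to `stats::lm` and cross-checked against hand-rolled normal
equations at 1e-8; rank-deficient designs, all-zero tracks, constant
vectors, zero-variance accessibility signals, empty region sets and
windows entirely off-chromosome raise immediate errors rather than
propagating NaNs. All generator outputs are pure functions of
(configuration, seed), and the pipeline itself is deterministic, so
reports are byte-identical across reruns; the run summary excludes
volatile fields (such as the output directory) for exactly this
reason.

## Pipeline problem sizes

The default end-to-end run — 13 tracks × 40,000 bins, 300 genes, 350
loci, six peak sets — completes in a few seconds; the full test suite,
including 1000 brute-force colocalisation trials and 100 regression-
recovery replicates, runs in a few minutes on one CPU. Those sizes are
the package's chosen study conditions for validation, not limits of
the implementation: all operations are linear or near-linear in bins
and peaks, and the same code paths accept genome-scale inputs.

## Known limitations

The interfaces are deliberately file-based and in-memory; very large
genomes would warrant Rle-compressed tracks and streaming bedGraph
I/O. Peak calling, read alignment and de-novo motif discovery are out
of scope — peaks and tracks are consumed as inputs, and motif scanning
covers only occurrence counting for a given consensus. The
mutual-exclusivity odds ratio is a quantitative proxy for a
density-plot observation and depends on the chosen quadrant
thresholds, which is why they are reported alongside the statistic.
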