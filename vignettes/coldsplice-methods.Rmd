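---
title: "Methods: quantifying cold-repressed poison-exon splicing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cold-repressed poison-exon splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldsplice)
```

## The biological problem

Poison exons (PEs) are alternative cassette exons that carry in-frame
premature termination codons. When a PE is included, the transcript is
degraded by nonsense-mediated decay (NMD), so PE inclusion acts as a
post-transcriptional rheostat on gene output. In the cold-shock gene RBM3,
moderate hypothermia (32&nbsp;°C) represses PE inclusion and thereby
stabilizes the productive mRNA; splicing factors such as HNRNPH1 drive the
switch through G-rich elements in and around the PE. Measuring this
regulation requires several independent quantifications — junction reads,
gel densitometry, exon-specific qPCR, RIP enrichment, pooled-screen guide
counts, compartmental imaging, and crosslink tracks — and this package
implements each of them with a matching synthetic-data generator, so every
estimator can be validated by parameter recovery rather than by downloading
deposited data.

## PSI estimators

### Junction-read PSI

For a cassette event with upstream, cassette and downstream exons
(0-based, half-open coordinates throughout; junctions are half-open gaps
between the last base of the left exon and the first base of the right
exon), `extract_junction_counts()` counts reads whose alignment gap matches
a junction exactly with at least `min_anchor` aligned nucleotides on both
sides. The estimator in `junction_psi()` is the standard
effective-length-normalized inclusion level

$$\Psi = \frac{(I_{up}+I_{down})/\ell_{inc}}
  {(I_{up}+I_{down})/\ell_{inc} + S/\ell_{skip}},
  \qquad \ell_{inc} = 2\,\ell,\ \ \ell_{skip} = \ell,
  \qquad \ell = L - 2(m-1)$$

with read length $L$ and anchor $m$: an included transcript exposes two
junctions and therefore twice the spanning positions of a skipped one.
Choices made here, because the tools this mirrors do not document them
fully:

* `min_anchor` defaults to 6 nt and is configurable; it is declared, not
  inferred from any external tool's settings.
* Reads are counted once per junction; secondary and supplementary
  alignment records are ignored.
* Undefined PSI (all counts zero) is an explicit flagged state, never a
  silent 0.
* Counting is unstranded by default (RT-PCR assays are unstranded); a
  strand filter is opt-in.

### NMD coupling

The simulator draws each molecule PE-included with probability $p$
(`psi_true`); included molecules survive decay with probability $\nu$
(`nmd_survival`), giving the post-decay molar inclusion fraction

$$p' = \frac{p\nu}{p\nu + 1 - p}.$$

Reads are then drawn i.i.d. from the junction pool with inclusion-read
probability $2p'/(1+p')$ — the factor 2 is the included isoform's doubled
effective length — which makes `junction_psi()` unbiased for $p'$. This is
also why an NMD-blocked condition (SMG1-inhibitor analogue,
$\nu = 1$) is the right arm for comparing estimators against the
synthesis-level truth, and why apparent PE fractions shrink when NMD is
active.

### Gel PSI

Intercalating dyes stain double-stranded DNA proportionally to mass
(moles × length), so `sim_gel()` renders band intensity as
`molar_amount * length_bp * gain` and `gel_psi()` divides each intensity by
its fragment length before forming the inclusion fraction. The estimator
generalizes to any number of inclusion bands by summing their
length-normalized intensities, reducing exactly to the one- and two-band
formulas, and is invariant to detector gain. Background subtraction of
band intensities is assumed to have happened upstream (densitometry
software); intensities are taken as given.

### qPCR relative PE inclusion

`relative_expression()` collapses technical replicates by the arithmetic
mean of Ct, then computes $E^{(Ct_{ref} - Ct_{target})}$ against a loading
control (e.g. 18S rRNA). Amplification efficiency $E$ is fixed at 2
(perfect doubling) in both simulation and estimation — no standard curves
are modelled — and is configurable per call. Outlier dropping (technical
replicates more than 0.5 cycles from the group median) is opt-in and off
by default. `pe_inclusion_ratio()` divides the PE amplicon's relative
expression by a constitutive-exon denominator; because published analyses
use both a geometric mean and a plain mean of two constitutive amplicons,
the mode is an explicit required parameter (`geometric_mean` default,
`arithmetic_mean`, `single`), and the geometric mode equals the geometric
mean of the two single-denominator ratios.

### Group comparison

`delta_psi()` reports `mean(a) - mean(b)` with a two-sided
label-permutation p-value using the add-one correction
$p = (b+1)/(m+1)$. All $\binom{n}{n_a}$ assignments are enumerated when
that count fits the permutation budget (the observed assignment counts in
$b$); otherwise random assignments are drawn. With two replicates per
group the minimum attainable p is therefore $3/7$ — small designs can
show direction but not significance.

## RIP normalization

The cooling-induced change in pulled-down target mRNA is confounded by the
change in total target mRNA and by the pulldown efficiency of the protein.
`rip_fold_change()` divides both out:

$$FC = \frac{ip_{32}/ip_{37}}{input_{32}/input_{37}}
  \Big/ \frac{\eta_{32}}{\eta_{37}},
  \qquad \eta = \frac{\text{protein}_{ip}}{\text{protein}_{input}}$$

making the result invariant to independent rescaling of RNA and protein
units, and exactly 1 when IP enrichment and efficiency move together.

## Pooled-screen guide counting and scoring

Counting follows the exact-match rule: the 20-mer at a fixed offset of
each read (21-nt reads, guide at offset 0 by default) is looked up in a
hash of library sequences; any read without an exact library match —
including a single substitution — is discarded and tallied, and
`matched + discarded = total` always holds. An optional ±1-nt offset scan
(off by default) rescues cassette slippage. Counts are scaled to reads per
million matched reads; guide log2 fold changes between sorted pools use a
0.5 pseudocount.

Gene scoring is deliberately simple, documented plumbing rather than a
robust-rank-aggregation reimplementation: guide lfc values are
standardized against the non-targeting-guide distribution
(median/MAD), gene score is the mean guide z, significance comes from
drawing size-matched random targeting-guide sets (two-sided, add-one
correction) and Benjamini–Hochberg adjustment across genes. Fewer than 10
non-targeting guides triggers a warning and an all-guide null. The count
table exports in a MAGeCK-compatible layout for users who want the
original ranking tool.

The simulator draws negative-binomial counts (dispersion 0.1 by default)
around library-proportional means — overdispersion is the realistic
regime for pooled screens — and applies the effect multiplier in the
designated pool.

## Image quantification

Single-cell images are segmented with Otsu's global threshold on the
background-removed channel (binary closing, radius 2 px by default,
largest connected component retained, consistent with one cell per
cropped image). The soma uses a threshold at a configurable fraction
(default 0.5) of the Otsu level so dim cytoplasm is captured, plus hole
filling, and the nucleus is united in so containment always holds. The
cytoplasm is defined as soma minus nucleus, and the partition identity is
bit-exact by construction. Mean intensity per unit area is the mean of
the background-removed channel over each mask.

Background removal defaults to subtracting the median of pixels outside a
coarse triangle-threshold foreground mask, clipped at zero. One numerical
guard matters: when sensor clipping piles pixels into the lowest histogram
bin, that spike is not the background mode, so the peak search skips a
boundary bin that towers over its neighbour. Morphological radii,
threshold fractions and the background method are recorded/configurable.

The synthetic generator renders disk geometry (nucleus strictly inside
soma) with per-compartment means, a background plane with optional linear
gradient, and Gaussian noise. It emulates intensity structure, not real
morphology — no neurites, no texture, no 3-D — so passing recovery tests
demonstrates correctness of the measurement pipeline, not robustness to
irregular cell shapes.

## Crosslink tracks and G4 scanning

Crosslink counts over a window are normalized to crosslinks per million
library crosslinks and smoothed with a centered rolling mean (window 5 by
default). Edge handling uses the truncated (shrinking) window — the
convention is stated here because upstream plotting tools do not state
theirs; it preserves constant inputs exactly and never exceeds the input
maximum. Tracks are strand-specific; antisense positions are never mixed.

`scan_g4()` enumerates quadruplex-forming G-rich sequences: four equal
G-tracts of at least `min_tract` (default 2) G's within `max_len`
(default 30) nt, loops of length ≥ 0. Overlapping candidates resolve
greedily to the highest-scoring non-overlapping set (ties: leftmost, then
shortest). The score,
`40*(tract_len - 2) + (max_len - span) - (max(loops) - min(loops))`,
is QGRS-style — longer tracts dominate, compact and even loops are
rewarded — but is not a reproduction of any published score; motif
presence and tract structure, checked against a brute-force enumerator,
are the validated surface. Zero-length loops are permitted without limit,
which means a long G-run can be parsed as two adjacent minimal tracts;
consequently deleting a G-tract from a motif abolishes the call only when
no such sub-tract parse survives, and otherwise demotes the motif to a
lower tract length.

## Pipeline, reproducibility and problem sizes

`run_pipeline()` executes named stages from a validated config (unknown
keys rejected by name), writes a JSON manifest with package version, seed,
parameters and MD5 checksums, and is byte-reproducible from config + seed.
All generators take explicit seeds and leave the caller's RNG state
untouched.

The recovery experiments in the test suite and the acceptance script use
problem sizes chosen to make the statistical guarantees sharp while
remaining desk-scale: 1,000 random gel lanes; 200 seeded junction
simulations at each of 15 depth × inclusion-level combinations (depths
10³–10⁵, inclusion 0.001–0.5, spanning the warm/cold regime 0.023 → 0.002);
decay-algebra checks at n = 10⁵; a 220-gene × 4-guide + 100 non-targeting
screen at 10⁵ reads per sample with ten 8× spiked genes; and 100 seeded
image geometries at signal-to-noise 10 (noise SD one tenth of the dimmest
compartment mean above background).

## Limitations

* The synthetic read model emits single-junction spanning reads only — no
  exon-body reads, paired ends, sequencing errors beyond single
  substitutions in screen reads, or PCR duplicates.
* Gene scoring is a calibrated substitute for robust rank aggregation,
  suitable for spike recovery and null calibration, not a drop-in for the
  original tool's rankings.
* qPCR efficiency is assumed, not estimated; multi-reference stability
  selection is out of scope.
* The full-data junction-PSI benchmark on deposited alignments is
  desk-independent: the same `extract_junction_counts()` path applies to
  any coordinate-matched BAM/SAM, but no external data is fetched here.
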