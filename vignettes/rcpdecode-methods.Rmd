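---
title: "Methods: spot calling, barcode decoding and cell quantification for in situ sequencing"
author: "rcpdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spot calling, barcode decoding and cell quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcpdecode)
```

## The measurement problem

In situ sequencing detects transcripts in tissue as rolling circle products
(RCPs): sub-micron DNA amplicons labelled with fluorophores, each appearing
as one diffraction-limited spot. An acquisition is a grid of overlapping
tiles, each a z-stack per channel, repeated over one or more hybridization
rounds. Gene identity is carried either by *which* round×channel a spot
appears in (sequential readout, one gene per slot) or by the *sequence of
channels* the same physical RCP lights up across cycles (combinatorial
readout). The analysis task is to turn these stacks into a per-cell
expression table: find the spots, link and decode them, segment cells from
the DAPI channel, and aggregate.

This package implements that pipeline, plus a generative simulator of the
whole acquisition so every stage can be validated against ground truth.

## Image processing model

**Projection and stitching.** Each z-stack is collapsed by maximum intensity
projection — correct for a signal that is in focus on one plane and
near-absent elsewhere. Tiles are stitched by translation only: for each
adjacent pair, the normalized cross-correlation (NCC) of the nominal overlap
strip is maximized over integer offsets within a bounded search margin
(default ±8 px), and global positions are composed along a
maximum-confidence spanning tree anchored at the first tile. Pairs whose
peak correlation falls below a floor (0.2 inside the estimator, 0.3 for the
tree) fall back to their nominal grid offset and are counted in the
diagnostics. Overlap pixels are blended by per-pixel maximum, which
preserves the peak of an RCP that straddles a seam (averaging would dim it).
Offsets are estimated once per experiment on the *composite* of all
channels of the reference round (per-pixel maximum over channels): overlap
strips then contain both nuclei and RCP texture, whereas DAPI alone can
leave a strip featureless. Rounds are aligned to the reference round by the
same NCC machinery applied to the nuclear channel, and the recovered
integer shift is applied to all channels of that round. Sub-pixel
registration is deliberately out of scope: the decoding stage tolerates
residual misalignment of a pixel through its distance penalty.

**Spot calling.** Background is removed with a white top-hat (image minus
its morphological opening with a disk, default radius 3 px), which deletes
structures larger than the disk and keeps point-like signals. Detection is
thresholding at a per-channel intensity level, 8-connected component
labelling, and an area filter (defaults 2–100 px); each surviving component
is reported at its intensity-weighted centroid with its peak intensity.
Thresholds are configuration values set per experiment, mirroring how such
pipelines are operated in practice (inspection of one field, then applied
globally); no auto-thresholding is built in.

**Channel-purity quality.** Each spot gets
$q = I_{\text{detected}} / \max(\sum_{c \ne \text{detected}} I_c,\ \varepsilon)$,
where the sum runs over the other *signal* channels (never DAPI), all
intensities are read at the spot's centroid pixel on the top-hat filtered
canvases, and $\varepsilon$ (default 1 intensity unit) keeps perfectly pure
spots finite. $q$ is invariant to a common intensity scale whenever the
floor is inactive. The measurement support (centroid pixel rather than
component mean, peak rather than integrated intensity) is a choice this
package fixes and documents; either reading is defensible and the
difference is small for diffraction-limited spots.

## Decoding

Sequential panels are a lookup: a spot at (round, channel) is the gene
assigned to that slot, and spots at unassigned slots are retained as
`unassigned` so that downstream totals remain auditable.

Combinatorial decoding links each first-cycle spot to its nearest
second-cycle spot within a search radius (default 5 px); with more than two
cycles the chain extends greedily from the previous member. Linking is
one-directional by design. Each candidate barcode is scored

$$Q = \prod_{i=1}^{n-1}\left(q_i\,q_{i+1} - k\,d_{i(i+1)}\right),$$

with $d$ the inter-cycle distance in pixels and $k$ (default 0.2 px⁻¹) the
distance penalty; for the two-cycle case this is exactly
$q_1 q_2 - k\,d_{12}$. The product is taken over the whole bracketed term —
the only reading that reduces to the two-cycle form while remaining
well-defined for $n > 2$. Candidates with $Q \le 0$ are dropped; with the
default $k$ and typical $q \approx 1$, this rejects links stretched beyond
about 5 px. When two surviving candidates share a member spot, the higher-Q
candidate wins (ties: smaller total distance, then input order) — a
one-to-one resolution this package imposes because many-to-one chains would
double-count RCPs in the expression matrix. Surviving channel sequences are
looked up in the codebook; non-matching sequences are excluded from the
expression path and counted as invalid barcodes in the diagnostics.

Default $k = 0.2$ and search radius 5 px were fixed by the geometry of the
problem (a correct link under ≤1 px registration error is ≪1 px long;
crowding makes links ≥5 px untrustworthy), not by tuning against outcomes.

## Cell segmentation and assignment

Nuclei: threshold the DAPI canvas at a configured level, fill holes, remove
objects below a minimum area (default 20 px), and split touching nuclei by
watershed on the distance transform. Cells: grow each nucleus outward by
seeded propagation on spatial distance, capped at a maximum expansion
(default 15 px) so territories stay local; fronts from different nuclei
meet at the equidistant ridge. The cap compensates for the absence of a
membrane marker — without it, isolated nuclei would claim unbounded
territory. A decoded spot belongs to the cell label under its rounded
centroid; label 0 leaves it unassigned but retained, so
|assigned| + |unassigned| always equals the number of decoded spots.

## Expression analysis

The count matrix has one row per segmented cell and one column per codebook
gene (zero columns retained); its total equals the number of cell-assigned,
gene-called spots — a conservation property asserted by the tests. Cells
are filtered before genes (minimum total counts, then minimum expressing
cells), removals recorded in a provenance slot. Counts are normalized per
cell to a common total — the median of per-cell totals by default — then
log(1+x) transformed. Clustering builds a kNN graph (Euclidean, default 15
neighbours, after an optional PCA to 20 components or fewer) and partitions
it with the Leiden algorithm; the seed is fixed, making labels reproducible.

**Density mode.** At low magnification individual RCPs are not resolvable,
so per-cell signal is quantified as the fraction of the cell's pixels at or
above a density threshold on the gene's filtered canvas, divided by cell
area. This is the minimal operational reading of density-based
quantification with cell-size adjustment; the area division happens exactly
once, tracked by a flag, and density matrices skip count normalization
because the area division *is* their size adjustment. The package emulates
a lower-magnification acquisition from a higher one by 2×2 block-averaging
the canvases and stride-sampling the label mask, and compares the two
quantifications by per-gene Pearson correlation over shared cells.

## The simulator and what it does (not) capture

The generator renders: non-overlapping nuclei (disks, radius ~N(6, 1) px)
into the DAPI channel of every round; per cell×gene Poisson(rate ×
efficiency) RCPs uniform in a cytoplasmic disk (default radius 16 px)
around the nucleus, each an isotropic Gaussian (σ = 1.2 px, peak 6000) in
the channel(s) the codebook dictates — at the same stitched position in
every cycle for combinatorial panels; optional linear crosstalk between
signal channels (default 5%); tiling with 10% overlap and integer stage
jitter (default ≤2 px) recorded in the ground truth; z-expansion with the
full signal on the in-focus plane; constant background (500) plus additive
Gaussian noise (σ = 300), clipped to 16-bit. Everything is bit-reproducible
under the config seed.

Default rates (2 RCPs per cell per gene over a 4-gene panel) keep spot
spacing above the optical merging distance, the regime in which sequential
readout is the appropriate design; the defaults model a scaled-down field
(hundreds of cells per canvas) rather than a full tissue section, and cell
disks are disjoint by default so ground-truth spot ownership is
unambiguous — the generator's geometry is chosen to make the watershed and
assignment assumptions literally true. Consequences to keep in mind:
passing tests demonstrate correctness of the algorithms under this model,
not robustness to tissue autofluorescence, optical aberrations, chromatic
shifts, z-dependent PSFs, irregular cell shapes or densely packed
cytoplasm. Poisson shot noise is omitted (amplitude-dominated regime),
which keeps the per-spot signal-to-noise ratio analytically equal to
spot amplitude / noise σ and lets the SNR estimator be validated against a
known value. Jitter is integer-valued so stitching recovery can be asserted
exactly.

## Numerical choices and degenerate inputs

* NCC offset search is exhaustive over the integer margin — no FFT
  approximation — so the argmax is exact; constant or uncorrelated strips
  (peak below 0.2) return the nominal offset, never an unreliable argmax.
* Top-hat runs on intensities rescaled to [0, 1] around the morphological
  opening (the grayscale morphology backend clips outside that range) and
  results are clamped to be nonnegative.
* Detection thresholds sit roughly midway between the top-hat noise floor
  and the spot amplitude; the default (2500) matches the simulator's
  default amplitude/noise. The minimum component area rejects the
  single-pixel exceedances pure noise produces.
* The quality floor ε = 1 intensity unit makes pure spots finite while
  leaving q scale-invariant elsewhere.
* Ties in shared-spot resolution and in linking are broken
  deterministically (Q, then total distance, then index), so decoding is a
  pure function of its inputs.
* Empty inputs (no spots, no nuclei, zero-count matrices) flow through as
  empty results; errors are reserved for contract violations (missing
  files, shape mismatches, spots outside the canvas, everything filtered
  out), and name the offending object.

## Validation fixtures and problem sizes

The test suite validates each stage against independent oracles: brute-force
morphology for the top-hat, hand-computed centroids for detection,
exhaustive nearest-neighbour search for linking, a two-pass reference filter
for the matrix, planted-population mixtures for clustering, and the
simulator's ground truth for everything end-to-end. Problem sizes are a few
hundred cells on canvases up to ~1000 px — large enough that recall,
precision and slope estimates are statistically meaningful at the asserted
tolerances, small enough to run routinely.

The headline recovery experiment mirrors a two-chemistry benchmarking
design: three regions of interest, a 4-gene panel read in one cycle, two
conditions sharing cell geometry whose true per-gene rates differ by
exactly 5.13-fold, reference-condition totals of a few hundred calls per
(ROI, gene). The recovered through-origin slope lands within ~10% of the
planted ratio; it sits a few percent *below* it systematically, because the
denser condition loses proportionally more spots to optical merging — the
same crowding bias a real spot-counting comparison of a high-efficiency
chemistry against a low-efficiency one would carry. ROI base rates were
chosen at the lower end of the target count band precisely to keep that
bias small.

## Known limitations

Translation-only registration (no rotation, scaling or nonrigid
deformation); no illumination flat-fielding; greedy (not globally optimal)
cross-cycle linking; no error-correcting barcodes; density mode assumes the
segmentation transfers to the downsampled canvas by point sampling; cluster
labels are arbitrary integers requiring external annotation.
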