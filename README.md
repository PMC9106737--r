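# rcpdecode

Image analysis for **hybridization-based in situ sequencing (HybISS)**
experiments, in which transcripts are detected in tissue as rolling circle
products (RCPs) — diffraction-limited fluorescent spots read out over one or
more imaging cycles — and quantified per cell. The package covers the whole
path from raw tile stacks to a clustered cell×gene expression matrix, and
ships a synthetic-experiment simulator with full ground truth so that every
stage is testable without microscopy data.

## What it does

Given multi-round, multi-channel, multi-tile fluorescence z-stacks (DAPI
plus ≥4 signal channels, tiles overlapping by a configurable fraction,
default 10%):

1. **Project & stitch** — maximum intensity projection per stack;
   translation-only stitching of the tile grid by normalized
   cross-correlation of the nominal overlap strips, composed along a
   maximum-confidence spanning tree; rounds aligned to a reference round on
   the nuclear channel.
2. **Detect spots** — white top-hat background removal (disk structuring
   element), per-channel intensity and size thresholds, 8-connected
   components, intensity-weighted centroids. Each spot gets a
   **channel-purity quality**
   `q = I_detected / Σ I_other-signal-channels` (DAPI excluded).
3. **Decode** — *sequential* panels (one gene per round×channel) by direct
   lookup; *combinatorial* panels by linking each first-cycle spot to its
   nearest neighbour in the next cycle and scoring the resulting barcode

       Q = ∏_{i=1}^{n−1} ( q_i · q_{i+1} − k · d_{i(i+1)} )

   where `d` is the inter-cycle distance in pixels and `k` a tunable
   penalty (default 0.2 px⁻¹); only barcodes with **Q > 0** are kept, and
   spots shared between candidates go to the higher-Q barcode.
4. **Segment & assign** — DAPI threshold → fill holes → watershed split of
   touching nuclei → distance-capped expansion to approximate cell
   territories; each decoded spot is assigned to the cell label under its
   centroid.
5. **Quantify & cluster** — cell×gene count matrix (or, for
   low-magnification imaging, per-cell **density**: thresholded-pixel
   fraction divided by cell area), cell/gene filtering, median-count
   normalization with log(1+x), and Leiden clustering on a kNN graph.

## Worked example

```r
library(rcpdecode)

# a 2x2-tile, single-cycle experiment with a 4-gene panel
layout <- acquisition_layout()                      # 2x2 x 256 px, 10% overlap
panel  <- codebook_sequential(c("Cd24a", "Lamp5", "Slc17a7", "Mbp"),
                              rounds = rep(1, 4), channels = 2:5)
sim <- simulate_experiment(simulation_config(layout = layout, seed = 101), panel)
res <- process_experiment(sim$tiles, panel, default_run_config())

nrow(sim$truth$spots)        # 287   true RCPs rendered
nrow(res$decoded)            # 272   spots detected and gene-called
nrow(res$cells$cells)        # 40    nuclei segmented (40 simulated)
sum(res$quant$matrix)        # 272   all calls fell inside cell territories
res$stitch_layout$offsets    # tile offsets (match truth up to translation)

summarize_rcps_per_cell(res$quant)$Mbp$mean   # 1.55 RCPs/cell for Mbp
```

The numbers above are what the code prints for seed 101: detection recovers
95% of true spots at the default amplitude/noise settings (the remainder are
pairs closer than the optical merging distance), the stitched tile offsets
match the jittered ground truth exactly up to a global translation,
segmentation finds all 40 nuclei, and every called spot lands in a cell
because simulated cell disks are disjoint by default.

The same pipeline runs from the shell, stage by stage or end to end:

```sh
Rscript inst/cli/rcpdecode.R run_all --dir runs/demo --seed 101
# or: simulate / stitch / detect / decode / segment / quantify / cluster
```

Each stage reads and writes documented artifacts in the run directory
(`tiles/` TIFFs named `t{tile}_r{round}_c{channel}.tif`, spot-table CSVs,
a MatrixMarket expression matrix with `cells.csv`/`genes.csv` sidecars) and
`run_all` writes a `manifest.json` recording stage order, config hash and
per-stage diagnostics.

## Coordinate and format conventions

Pixel coordinates are 0-based, `row = y`, `col = x`, origin at the stitched
canvas top-left; tile rectangles are half-open. Images are 16-bit unsigned
TIFF (8-bit inputs are upcast); spot tables are CSV with the fixed header
`spot_id,round,channel,y,x,intensity,area,quality,gene,cell_id,Q`; floats
are written at full precision so round-trips are lossless.
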